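#' Construct a 2 x K DOOR count table
#'
#' The 2 x K table of category counts (rows = arms, columns = categories in
#' desirability order, most desirable first) is the sufficient statistic for
#' every unweighted analysis in the package.
#'
#' @param counts Matrix-like with 2 rows (experimental first, control second)
#'   and K >= 2 columns of nonnegative integer counts.
#' @param arms Character vector of length 2 naming the arms, experimental
#'   first.
#' @param scheme Optional [door_scheme()]; defaults to the column names of
#'   `counts`, or generic labels.
#' @return An object of class `door_table`: an integer matrix with a `scheme`
#'   attribute and arm row names.
#' @examples
#' door_table(rbind(c(263, 93, 16, 1, 1), c(253, 111, 9, 1, 0)),
#'            arms = c("doripenem", "levofloxacin"))
#' @export
door_table <- function(counts, arms = c("experimental", "control"),
                       scheme = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L)
    stop("a DOOR table has exactly 2 rows (experimental, control)", call. = FALSE)
  if (ncol(counts) < 2L)
    stop("a DOOR table needs at least 2 categories", call. = FALSE)
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) < 1))
    stop("both arms must contain at least one participant", call. = FALSE)
  if (is.null(scheme)) {
    scheme <- if (!is.null(colnames(counts))) door_scheme(colnames(counts))
              else default_scheme(ncol(counts))
  }
  if (scheme$K != ncol(counts))
    stop("scheme has ", scheme$K, " categories but counts have ",
         ncol(counts), " columns", call. = FALSE)
  if (length(arms) != 2L || anyDuplicated(arms))
    stop("`arms` must be two distinct arm names", call. = FALSE)
  dimnames(counts) <- list(arms, scheme$labels)
  structure(counts, scheme = scheme, class = c("door_table", "matrix"))
}

#' @export
print.door_table <- function(x, ...) {
  cat("DOOR table (", ncol(x), " categories, most -> least desirable)\n",
      sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

door_scheme_of <- function(table) attr(table, "scheme")

arm_counts <- function(table) {
  list(a = as.numeric(table[1L, ]), b = as.numeric(table[2L, ]),
       n1 = sum(table[1L, ]), n2 = sum(table[2L, ]))
}

#' Swap the arms of a DOOR table
#'
#' Returns the table with the roles of experimental and control exchanged;
#' useful for direction-symmetry checks.
#'
#' @param table A [door_table()].
#' @return A `door_table` with rows swapped.
#' @export
swap_arms <- function(table) {
  door_table(unclass(table)[2:1, , drop = FALSE], arms = rownames(table)[2:1],
             scheme = door_scheme_of(table))
}

#' Read a patient-level DOOR data table
#'
#' Reads a delimited text file with one row per participant and validates it
#' into a patient-level dataset. The category column may hold either the
#' integer category index (1 = most desirable) or the category label from the
#' scheme. Component flags are kept as 0/1/NA; records with a missing DOOR
#' category are retained here and excluded (with a warning) only when
#' tabulated.
#'
#' @param path Path to a CSV file with a header row.
#' @param scheme A [door_scheme()], or an integer K for a generic scheme.
#' @param experimental Arm label to treat as experimental. Defaults to the
#'   arm of the first row.
#' @param columns Named list mapping roles to column names: `id`, `arm`,
#'   `category`, and optionally `components` (character vector), `weight`,
#'   `propensity`.
#' @return An object of class `door_data`; see [door_data()].
#' @export
read_patient_table <- function(path, scheme, experimental = NULL,
                               columns = list()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  defaults <- list(id = "id", arm = "arm", category = "door_category",
                   components = NULL, weight = NULL, propensity = NULL)
  columns <- utils::modifyList(defaults, columns)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(columns$id, columns$arm, columns$category, columns$components,
              columns$weight, columns$propensity)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.numeric(scheme)) scheme <- default_scheme(scheme)

  cat_raw <- raw[[columns$category]]
  category <- rep(NA_integer_, length(cat_raw))
  suppressWarnings(as_int <- as.integer(as.character(cat_raw)))
  is_int <- !is.na(as_int)
  category[is_int] <- as_int[is_int]
  by_label <- match(as.character(cat_raw)[!is_int], scheme$labels)
  category[!is_int] <- by_label
  bad <- which(!is.na(cat_raw) & (is.na(category) | category < 1 |
                                    category > scheme$K))
  if (length(bad))
    stop("row ", bad[1L], ": DOOR category ", sQuote(cat_raw[bad[1L]]),
         " is not a valid index or label under the ", scheme$K,
         "-level scheme", call. = FALSE)

  comp <- NULL
  if (length(columns$components)) {
    comp <- raw[columns$components]
    for (nm in columns$components) {
      v <- comp[[nm]]
      if (!all(v %in% c(0, 1, NA)))
        stop("component flag ", sQuote(nm), " must be 0, 1 or missing",
             call. = FALSE)
      comp[[nm]] <- as.integer(v)
    }
  }
  weight <- if (!is.null(columns$weight)) as.numeric(raw[[columns$weight]])
  propensity <- if (!is.null(columns$propensity))
    as.numeric(raw[[columns$propensity]])

  door_data(id = raw[[columns$id]], arm = raw[[columns$arm]],
            category = category, scheme = scheme,
            experimental = experimental, components = comp,
            weight = weight, propensity = propensity)
}

#' Construct a patient-level DOOR dataset
#'
#' @param id Vector of unique participant identifiers.
#' @param arm Vector of arm labels (exactly two distinct values).
#' @param category Integer DOOR category per participant (1 = most
#'   desirable), `NA` allowed.
#' @param scheme A [door_scheme()].
#' @param experimental Which arm label is the experimental arm; defaults to
#'   `arm[1]`.
#' @param components Optional data frame of 0/1/NA component-event flags.
#' @param weight Optional nonnegative analysis weights (IPTW or design).
#' @param propensity Optional propensity scores in (0, 1).
#' @return An object of class `door_data`: a list with `records` (data
#'   frame: `id`, `arm` as an experimental/control-ordered factor, `category`,
#'   component columns, `weight`, `propensity`), `scheme`, `components`
#'   (component column names) and `arms` (original labels, experimental
#'   first).
#' @export
door_data <- function(id, arm, category, scheme, experimental = NULL,
                      components = NULL, weight = NULL, propensity = NULL) {
  if (anyDuplicated(id))
    stop("participant ids must be unique (duplicate: ",
         sQuote(id[duplicated(id)][1L]), ")", call. = FALSE)
  arm <- as.character(arm)
  arms_seen <- unique(arm)
  if (length(arms_seen) != 2L)
    stop("expected exactly 2 arms, found ", length(arms_seen), call. = FALSE)
  if (is.null(experimental)) experimental <- arm[1L]
  if (!experimental %in% arms_seen)
    stop("experimental arm ", sQuote(experimental), " not present in data",
         call. = FALSE)
  arms <- c(experimental, setdiff(arms_seen, experimental))
  category <- as.integer(category)
  if (any(!is.na(category) & (category < 1 | category > scheme$K)))
    stop("DOOR categories must lie in 1..", scheme$K, call. = FALSE)
  if (!is.null(weight)) {
    if (any(is.na(weight) | weight < 0))
      stop("weights must be nonnegative and non-missing", call. = FALSE)
    for (g in arms)
      if (sum(weight[arm == g]) <= 0)
        stop("weights in arm ", sQuote(g), " are all zero", call. = FALSE)
  }
  if (!is.null(propensity) &&
      any(!is.na(propensity) & (propensity <= 0 | propensity >= 1)))
    stop("propensity scores must lie strictly in (0, 1)", call. = FALSE)
  records <- data.frame(id = id,
                        arm = factor(arm, levels = arms,
                                     labels = c("experimental", "control")),
                        category = category, stringsAsFactors = FALSE)
  comp_names <- character(0)
  if (!is.null(components)) {
    comp_names <- names(components)
    records <- cbind(records, components)
  }
  records$weight <- if (is.null(weight)) rep(1, nrow(records)) else weight
  if (!is.null(propensity)) records$propensity <- propensity
  structure(list(records = records, scheme = scheme,
                 components = comp_names, arms = arms),
            class = "door_data")
}

#' @export
print.door_data <- function(x, ...) {
  n <- table(x$records$arm)
  cat("Patient-level DOOR dataset: ", nrow(x$records), " participants (",
      x$arms[1], " n1=", n[["experimental"]], ", ", x$arms[2], " n2=",
      n[["control"]], "), ", x$scheme$K, " categories", sep = "")
  if (length(x$components))
    cat(", components: ", paste(x$components, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Tabulate a patient-level dataset into a DOOR table
#'
#' Records with a missing DOOR category are excluded with a warning giving
#' the count; no imputation is performed.
#'
#' @param data A [door_data()].
#' @return A [door_table()] with the original arm labels.
#' @export
tabulate_door <- function(data) {
  stopifnot(inherits(data, "door_data"))
  rec <- data$records
  n_miss <- sum(is.na(rec$category))
  if (n_miss > 0) {
    warning(n_miss, " record(s) with missing DOOR category excluded from ",
            "tabulation", call. = FALSE)
    rec <- rec[!is.na(rec$category), , drop = FALSE]
  }
  counts <- t(sapply(c("experimental", "control"), function(g)
    tabulate(rec$category[rec$arm == g], nbins = data$scheme$K)))
  door_table(counts, arms = data$arms, scheme = data$scheme)
}

#' Expand a DOOR table into a patient-level dataset
#'
#' Inverse of [tabulate_door()] up to participant identity: produces one
#' record per counted participant with synthetic ids and unit weights.
#'
#' @param table A [door_table()].
#' @return A [door_data()].
#' @export
expand_door_table <- function(table) {
  ac <- arm_counts(table)
  K <- ncol(table)
  cat1 <- rep(seq_len(K), times = ac$a)
  cat2 <- rep(seq_len(K), times = ac$b)
  door_data(id = paste0("P", seq_len(ac$n1 + ac$n2)),
            arm = rep(rownames(table), c(ac$n1, ac$n2)),
            category = c(cat1, cat2), scheme = door_scheme_of(table),
            experimental = rownames(table)[1L])
}

#' Read a 2 x K DOOR count table from CSV
#'
#' Expects one row per arm (experimental first unless `experimental` names
#' the row), an `arm` column, and one column per category in desirability
#' order.
#'
#' @param path CSV path.
#' @param experimental Optional arm label to place first.
#' @return A [door_table()].
#' @export
read_door_table <- function(path, experimental = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"arm" %in% names(raw)) stop("count table needs an `arm` column",
                                   call. = FALSE)
  counts <- as.matrix(raw[setdiff(names(raw), "arm")])
  rownames(counts) <- raw$arm
  if (!is.null(experimental)) {
    if (!experimental %in% raw$arm)
      stop("experimental arm ", sQuote(experimental), " not found",
           call. = FALSE)
    counts <- counts[c(experimental, setdiff(raw$arm, experimental)), ,
                     drop = FALSE]
  }
  door_table(counts, arms = rownames(counts))
}

#' Packaged example fixtures
#'
#' Returns the packaged cUTI/pyelonephritis trial counts (doripenem vs
#' levofloxacin, 374 participants per arm, five DOOR levels) used in
#' examples and tests.
#'
#' @param name One of `"dori05_door"` (the 2 x 5 DOOR table),
#'   `"dori05_components"` (named list of per-component 2 x 2 tables, no
#'   event first), or `"dori05_patients"` (patient-level expansion of the
#'   DOOR table).
#' @return A `door_table`, list of `door_table`s, or `door_data`.
#' @examples
#' door_fixture("dori05_door")
#' @export
door_fixture <- function(name) {
  extdata <- function(f) system.file("extdata", f, package = "doorstats",
                                     mustWork = TRUE)
  switch(name,
    dori05_door = read_door_table(extdata("dori05_door.csv"),
                                  experimental = "doripenem"),
    dori05_components = {
      raw <- utils::read.csv(extdata("dori05_components.csv"),
                             stringsAsFactors = FALSE, check.names = FALSE)
      out <- lapply(split(raw, factor(raw$component,
                                      levels = unique(raw$component))),
        function(d) {
          d <- d[match(c("doripenem", "levofloxacin"), d$arm), ]
          door_table(cbind(d$no_event, d$event),
                     arms = d$arm,
                     scheme = door_scheme(c("No event", d$component[1L])))
        })
      out
    },
    dori05_patients = expand_door_table(door_fixture("dori05_door")),
    stop("unknown fixture ", sQuote(name), "; available: dori05_door, ",
         "dori05_components, dori05_patients", call. = FALSE)
  )
}
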