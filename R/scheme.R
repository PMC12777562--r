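#' Define an ordered DOOR category scheme
#'
#' A DOOR scheme is the ordered list of outcome categories, from most
#' desirable (index 1) to least desirable (index K). Most schemes end in
#' death as the least desirable category.
#'
#' @param labels Character vector of unique category names, ordered from most
#'   to least desirable.
#' @return An object of class `door_scheme` with elements `labels` and `K`.
#' @examples
#' door_scheme(c("Alive with no events", "Alive with 1 event",
#'               "Alive with 2 events", "Alive with 3 events", "Death"))
#' @export
door_scheme <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a DOOR scheme needs at least 2 categories", call. = FALSE)
  if (anyDuplicated(labels))
    stop("DOOR category labels must be unique", call. = FALSE)
  if (anyNA(labels))
    stop("DOOR category labels must not be missing", call. = FALSE)
  structure(list(labels = labels, K = length(labels)), class = "door_scheme")
}

#' @export
print.door_scheme <- function(x, ...) {
  cat("DOOR scheme with", x$K, "categories (most -> least desirable):\n")
  cat(paste0("  ", seq_len(x$K), ". ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

# default numeric scheme when only K is known
default_scheme <- function(K) door_scheme(paste("Category", seq_len(K)))

#' Construct a grading key for partial-credit analysis
#'
#' A grading key assigns a grade on the 0--100 scale to each DOOR category,
#' like an academic test: 100 for the most desirable category, 0 for the
#' least desirable (death), partial credit in between. Keys whose
#' intermediate grades are not monotone nonincreasing are accepted with a
#' warning, since sensitivity sweeps deliberately visit non-monotone keys.
#'
#' @param grades Numeric vector of length K with grades in \[0, 100\];
#'   `grades[1]` must be 100 and `grades[K]` must be 0.
#' @return Numeric vector of class `grading_key`.
#' @examples
#' grading_key(c(100, 75, 50, 25, 0))
#' @export
grading_key <- function(grades) {
  grades <- as.numeric(grades)
  if (length(grades) < 2L || anyNA(grades))
    stop("a grading key needs at least 2 non-missing grades", call. = FALSE)
  if (grades[1L] != 100)
    stop("the most desirable category must receive grade 100", call. = FALSE)
  if (grades[length(grades)] != 0)
    stop("the least desirable category must receive grade 0", call. = FALSE)
  if (any(grades < 0 | grades > 100))
    stop("grades must lie in [0, 100]", call. = FALSE)
  if (is.unsorted(rev(grades)))
    warning("grading key is not monotone nonincreasing; proceeding", call. = FALSE)
  structure(grades, class = "grading_key")
}

as_grading_key <- function(key, K) {
  if (!inherits(key, "grading_key")) key <- grading_key(key)
  if (length(key) != K)
    stop("grading key has ", length(key), " grades but the scheme has ",
         K, " categories", call. = FALSE)
  key
}
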