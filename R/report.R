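#' Run the full recommended DOOR analysis bundle
#'
#' Assembles the standard analysis surface for a two-arm DOOR comparison:
#' the distribution table, the expected gain/loss table, the overall,
#' cumulative and component DOOR probability estimates (forest table), and
#' one partial-credit contrast per supplied grading key.
#'
#' @param table A [door_table()] (or a [door_data()], which is tabulated).
#' @param components Optional named list of 2 x 2 component [door_table()]s.
#' @param keys Optional (named) list of grading keys.
#' @param level Confidence level; default 0.95.
#' @param alpha Significance threshold recorded in the bundle; default
#'   0.05.
#' @param standard_n Cohort size for gain/loss standardization; default
#'   1,000.
#' @return Object of class `door_report`: list with `distribution`,
#'   `gain_loss`, `component_gain_loss` (when components are given),
#'   `forest` (a [door_forest()] data frame), `partial_credit` (named list
#'   of `door_effect`s), `metrics` (from [convert_metrics()]), and
#'   `settings`.
#' @examples
#' door_analyze(door_fixture("dori05_door"),
#'              components = door_fixture("dori05_components"),
#'              keys = list(even = c(100, 75, 50, 25, 0)))
#' @export
door_analyze <- function(table, components = NULL, keys = NULL,
                         level = 0.95, alpha = 0.05, standard_n = 1000) {
  if (inherits(table, "door_data")) table <- tabulate_door(table)
  out <- list(
    distribution = distribution_table(table),
    gain_loss = gain_loss(table, standard_n = standard_n),
    forest = door_forest(table, components = components, level = level),
    metrics = convert_metrics(table),
    settings = list(level = level, alpha = alpha, standard_n = standard_n,
                    arms = rownames(table))
  )
  if (!is.null(components))
    out$component_gain_loss <- component_gain_loss(components,
                                                   standard_n = standard_n)
  if (!is.null(keys)) {
    if (is.null(names(keys))) names(keys) <- paste0("key_", seq_along(keys))
    out$partial_credit <- lapply(keys, function(k)
      partial_credit_diff(table, k, level = level))
  }
  class(out) <- "door_report"
  out
}

#' @export
print.door_report <- function(x, ...) {
  overall <- x$forest[x$forest$type == "overall", ]
  cat(sprintf(
    "DOOR analysis (%s vs %s)\n  DOOR probability %.1f%% (%d%% CI: %.1f%%, %.1f%%; P = %.2f)\n",
    x$settings$arms[1L], x$settings$arms[2L], 100 * overall$estimate,
    round(100 * x$settings$level), 100 * overall$ci_low,
    100 * overall$ci_high, overall$p_value))
  cat(sprintf("  win ratio %.3f, win odds %.3f, NTB %.3f\n",
              x$metrics$win_ratio, x$metrics$win_odds, x$metrics$ntb))
  if (!is.null(x$partial_credit))
    for (nm in names(x$partial_credit))
      cat(sprintf("  partial credit [%s]: %+.3f grade points (P = %.2f)\n",
                  nm, x$partial_credit[[nm]]$estimate,
                  x$partial_credit[[nm]]$p_value))
  invisible(x)
}

effect_row <- function(label, e) {
  data.frame(label = label, estimate = e$estimate, ci_low = e$ci_low,
             ci_high = e$ci_high, level = e$level, p_value = e$p_value,
             method = e$method, scale = e$scale, n1 = e$n1, n2 = e$n2,
             stringsAsFactors = FALSE)
}

#' Write a DOOR report bundle to disk
#'
#' Writes every table of a [door_analyze()] bundle as CSV plus a single
#' JSON summary, a manifest (package version and settings), and forest /
#' distribution figures (PNG and SVG) whose numbers are exactly the CSV
#' contents.
#'
#' @param report A `door_report`.
#' @param dir Output directory (created if needed).
#' @param figures Emit figures; default TRUE.
#' @return Invisibly, the paths written.
#' @export
write_door_report <- function(report, dir, figures = TRUE) {
  stopifnot(inherits(report, "door_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(report$distribution, "distribution.csv")
  gl <- report$gain_loss
  wcsv(data.frame(category = names(gl$per_category),
                  gain_or_loss = unname(gl$per_category),
                  cumulative = unname(gl$cumulative),
                  gain_or_loss_raw = unname(gl$per_category_raw),
                  cumulative_raw = unname(gl$cumulative_raw)),
       "gain_loss.csv")
  wcsv(report$forest, "forest.csv")
  if (!is.null(report$component_gain_loss))
    wcsv(data.frame(component = names(report$component_gain_loss),
                    gain_or_loss = unname(report$component_gain_loss)),
         "component_gain_loss.csv")
  if (!is.null(report$partial_credit))
    wcsv(do.call(rbind, Map(effect_row, names(report$partial_credit),
                            report$partial_credit)),
         "partial_credit.csv")
  summary_json <- list(
    settings = report$settings,
    metrics = report$metrics,
    overall = report$forest[report$forest$type == "overall", ],
    package_version = as.character(utils::packageVersion("doorstats")))
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, jp)
  if (figures) {
    for (ext in c("png", "svg")) {
      fp <- file.path(dir, paste0("forest.", ext))
      if (ext == "png") grDevices::png(fp, width = 900, height = 500)
      else grDevices::svg(fp, width = 9, height = 5)
      plot(report$forest)
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  invisible(paths)
}

#' Write a grading-key grid bundle to disk
#'
#' Long-format CSV of the grid (plus the tipping boundary) and the contour
#' figure as PNG and SVG.
#'
#' @param grid A [grade_grid()].
#' @param dir Output directory.
#' @param figures Emit figures; default TRUE.
#' @return Invisibly, the paths written.
#' @export
write_grade_grid <- function(grid, dir, figures = TRUE) {
  stopifnot(inherits(grid, "grade_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- file.path(dir, "grade_grid.csv")
  utils::write.csv(as.data.frame(grid), gp, row.names = FALSE)
  bp <- file.path(dir, "tipping_boundary.csv")
  utils::write.csv(tipping_boundary(grid), bp, row.names = FALSE)
  paths <- c(gp, bp)
  if (figures) {
    for (ext in c("png", "svg")) {
      fp <- file.path(dir, paste0("grade_grid.", ext))
      if (ext == "png") grDevices::png(fp, width = 700, height = 700)
      else grDevices::svg(fp, width = 7, height = 7)
      plot(grid)
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  invisible(paths)
}
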