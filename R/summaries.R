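# round half away from zero, to whole patients
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' DOOR distribution table with cumulative percentages
#'
#' Per-arm category counts, percentages (one decimal), and cumulative counts
#' and percentages accumulated from the most desirable category downward.
#'
#' @param table A [door_table()].
#' @return Data frame with columns `arm`, `category`, `n`, `pct`, `cum_n`,
#'   `cum_pct`.
#' @examples
#' distribution_table(door_fixture("dori05_door"))
#' @export
distribution_table <- function(table) {
  sch <- door_scheme_of(table)
  out <- lapply(1:2, function(r) {
    cnt <- as.numeric(table[r, ])
    n <- sum(cnt)
    data.frame(arm = rownames(table)[r],
               category = factor(sch$labels, levels = sch$labels),
               n = cnt, pct = round(100 * cnt / n, 1),
               cum_n = cumsum(cnt),
               cum_pct = round(100 * cumsum(cnt) / n, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected gain/loss table standardized per N assigned patients
#'
#' For each DOOR category, the number of patients who would be gained (or
#' lost, negative) in that category if `standard_n` patients were treated
#' with the experimental intervention instead of control:
#' round((a_k/n1 - b_k/n2) * standard_n), rounding half away from zero,
#' computed from raw counts rather than rounded percentages. Cumulative
#' values are computed analogously on the cumulative proportions.
#'
#' @param table A [door_table()].
#' @param standard_n Standardizing cohort size; default 1,000.
#' @return Object of class `gain_loss`: list with integer vectors
#'   `per_category` and `cumulative` (named by category), their unrounded
#'   counterparts `per_category_raw` and `cumulative_raw`, and `standard_n`.
#' @examples
#' gain_loss(door_fixture("dori05_door"))$per_category  # 27 -48 19 0 3
#' @export
gain_loss <- function(table, standard_n = 1000) {
  if (!(is.numeric(standard_n) && length(standard_n) == 1L && standard_n >= 1))
    stop("`standard_n` must be a positive cohort size", call. = FALSE)
  ac <- arm_counts(table)
  d <- (ac$a / ac$n1 - ac$b / ac$n2) * standard_n
  dc <- (cumsum(ac$a) / ac$n1 - cumsum(ac$b) / ac$n2) * standard_n
  labels <- door_scheme_of(table)$labels
  structure(list(per_category = stats::setNames(round_half_away(d), labels),
                 cumulative = stats::setNames(round_half_away(dc), labels),
                 per_category_raw = stats::setNames(d, labels),
                 cumulative_raw = stats::setNames(dc, labels),
                 standard_n = standard_n),
            class = "gain_loss")
}

#' @export
print.gain_loss <- function(x, ...) {
  cat("Expected gain/loss per", format(x$standard_n, big.mark = ","),
      "assigned patients (experimental - control):\n")
  print(data.frame(category = names(x$per_category),
                   gain_or_loss = unname(x$per_category),
                   cumulative = unname(x$cumulative)), row.names = FALSE)
  invisible(x)
}

#' Expected gain/loss in component events per N assigned patients
#'
#' For each binary component (event coded as the less desirable second
#' level), the change in event count per `standard_n` patients treated with
#' experimental instead of control:
#' round((event_rate_exp - event_rate_ctl) * standard_n), half away from
#' zero.
#'
#' @param components Named list of 2 x 2 [door_table()]s, no-event column
#'   first (e.g., `door_fixture("dori05_components")`).
#' @param standard_n Standardizing cohort size; default 1,000.
#' @return Named integer vector, one value per component.
#' @examples
#' component_gain_loss(door_fixture("dori05_components"))
#' @export
component_gain_loss <- function(components, standard_n = 1000) {
  vapply(components, function(tb) {
    if (ncol(tb) != 2L)
      stop("component tables must have exactly 2 levels", call. = FALSE)
    ac <- arm_counts(tb)
    round_half_away((ac$a[2L] / ac$n1 - ac$b[2L] / ac$n2) * standard_n)
  }, numeric(1))
}
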