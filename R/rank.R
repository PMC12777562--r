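#' Count cross-arm wins, ties and losses
#'
#' Over all n1 x n2 cross-arm pairs, counts pairs in which the experimental
#' participant's DOOR category is more desirable than the control
#' participant's (a win), equally desirable (a tie), or less desirable
#' (a loss). Computed in closed form from the 2 x K table:
#' wins = sum_k a_k * sum_\{j>k\} b_j and ties = sum_k a_k * b_k, which equals
#' the brute-force double loop over expanded participants.
#'
#' @param table A [door_table()].
#' @return An object of class `pair_counts`: list with `wins`, `ties`,
#'   `losses`, `total` (= n1 * n2), `n1`, `n2`.
#' @examples
#' count_pairs(door_fixture("dori05_door"))
#' @export
count_pairs <- function(table) {
  ac <- arm_counts(table)
  if (ac$n1 < 1 || ac$n2 < 1)
    stop("both arms must be nonempty", call. = FALSE)
  K <- length(ac$a)
  # b_gt[k] = number of control participants strictly less desirable than k
  b_gt <- rev(cumsum(rev(ac$b)))[-1L]
  b_gt <- c(b_gt, 0)
  wins <- sum(ac$a * b_gt)
  ties <- sum(ac$a * ac$b)
  total <- ac$n1 * ac$n2
  structure(list(wins = wins, ties = ties, losses = total - wins - ties,
                 total = total, n1 = ac$n1, n2 = ac$n2),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("Cross-arm pairs: ", format(x$total, big.mark = ","), " (wins ",
      format(x$wins, big.mark = ","), ", ties ",
      format(x$ties, big.mark = ","), ", losses ",
      format(x$losses, big.mark = ","), ")\n", sep = "")
  invisible(x)
}

#' Estimate the DOOR probability
#'
#' The DOOR probability is the probability that a randomly chosen
#' participant on the experimental intervention has a more desirable outcome
#' than one on control, with ties counted half:
#' (wins + ties / 2) / (n1 * n2). A value of 50% corresponds to no
#' difference (identical distributions imply 50%, though not conversely).
#'
#' @param x A `pair_counts`, [door_table()], or [door_data()].
#' @return The estimated probability in \[0, 1\].
#' @examples
#' door_probability(door_fixture("dori05_door"))  # 0.5095
#' @export
door_probability <- function(x) {
  pc <- as_pair_counts(x)
  if (pc$total <= 0) stop("no cross-arm pairs to compare", call. = FALSE)
  (pc$wins + pc$ties / 2) / pc$total
}

as_pair_counts <- function(x) {
  if (inherits(x, "pair_counts")) x
  else if (inherits(x, "door_table")) count_pairs(x)
  else if (inherits(x, "door_data")) count_pairs(tabulate_door(x))
  else stop("cannot interpret object of class ", class(x)[1L],
            " as pair counts", call. = FALSE)
}

#' Consistent variance of the DOOR probability estimator
#'
#' Plug-in estimate of the sampling variance of the DOOR probability based
#' on the two-sample U-statistic decomposition with the half-tie kernel
#' phi = 1(win) + 0.5 * 1(tie):
#' \deqn{\widehat{Var} = [v + (n_1 - 1)(Q_1 - P^2) + (n_2 - 1)(Q_2 - P^2)]
#'   / (n_1 n_2)}
#' where v = P - Delta/4 - P^2 is the kernel variance (Delta the tie
#' probability) and Q1, Q2 are the structural components for pairs sharing a
#' control or experimental participant. Returns 0 for a degenerate table
#' (all mass in one shared category).
#'
#' @param table A [door_table()].
#' @return Nonnegative variance estimate.
#' @export
variance_u <- function(table) {
  ac <- arm_counts(table)
  if (ac$n1 < 2 || ac$n2 < 2)
    stop("variance estimation needs at least 2 participants per arm",
         call. = FALSE)
  K <- length(ac$a)
  phi <- outer(seq_len(K), seq_len(K),
               function(k, j) (k < j) + 0.5 * (k == j))
  pa <- ac$a / ac$n1
  pb <- ac$b / ac$n2
  P <- sum(outer(pa, pb) * phi)
  h <- as.vector(phi %*% pb)     # placement of an experimental participant
  g <- as.vector(t(phi) %*% pa)  # placement of a control participant
  Q1 <- sum(pb * g^2)
  Q2 <- sum(pa * h^2)
  Delta <- sum(pa * pb)
  v <- P - Delta / 4 - P^2
  max(0, (v + (ac$n1 - 1) * (Q1 - P^2) + (ac$n2 - 1) * (Q2 - P^2)) /
        (ac$n1 * ac$n2))
}

# Tie-corrected variance of the DOOR probability estimator under
# exchangeability of the pooled sample (the rank/WMW variance):
#   (N + 1) / (12 n1 n2) * (1 - sum(t^3 - t) / (N^3 - N)),
# with t the pooled tie-group (category) sizes and N = n1 + n2.
rank_variance_null <- function(table) {
  ac <- arm_counts(table)
  N <- ac$n1 + ac$n2
  t <- ac$a + ac$b
  tie_corr <- 1 - sum(t^3 - t) / (N^3 - N)
  (N + 1) / (12 * ac$n1 * ac$n2) * tie_corr
}

new_effect <- function(estimate, ci_low, ci_high, level, p_value = NA_real_,
                       method, scale = "probability", n1 = NA, n2 = NA) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 level = level, p_value = p_value, method = method,
                 scale = scale, n1 = n1, n2 = n2),
            class = "door_effect")
}

#' @export
print.door_effect <- function(x, digits = 1, ...) {
  if (identical(x$scale, "probability")) {
    cat(sprintf("DOOR probability: %.*f%% (%d%% CI: %.*f%%, %.*f%%",
                digits, 100 * x$estimate, round(100 * x$level), digits,
                100 * x$ci_low, digits, 100 * x$ci_high))
  } else {
    cat(sprintf("Estimate: %.*f (%d%% CI: %.*f, %.*f", max(digits, 3),
                x$estimate, round(100 * x$level), max(digits, 3), x$ci_low,
                max(digits, 3), x$ci_high))
  }
  if (!is.na(x$p_value)) cat(sprintf("; P = %.2f", x$p_value))
  cat(")\n")
  cat("  method:", x$method, "\n")
  invisible(x)
}

#' Tie-corrected confidence interval for the DOOR probability
#'
#' Primary interval for the tied-data Mann-Whitney parameter: a symmetric
#' normal interval around the DOOR probability estimate whose standard error
#' is the tie-corrected rank variance of the estimator under exchangeability
#' of the pooled sample, the same variance that studentizes the
#' rank-sum test of the 50% null. Calibrated so that the packaged
#' doripenem/levofloxacin example reproduces its published bounds at
#' 0.1-percentage-point precision. Bounds are clipped to \[0, 1\].
#'
#' A consistent-variance alternative (`method = "logit"`), a logit-scale
#' Wald interval built on [variance_u()], is provided as a labeled fallback;
#' it is asymmetric and respects the \[0, 1\] range by construction.
#'
#' @param table A [door_table()].
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"halperin"` (tie-corrected rank variance, default) or
#'   `"logit"` (logit Wald on the consistent U-statistic variance).
#' @return A `door_effect` with the estimate, bounds and method metadata
#'   (no p-value; see [wmw_test()]).
#' @examples
#' halperin_ci(door_fixture("dori05_door"))  # 51.0% (47.6%, 54.3%)
#' @export
halperin_ci <- function(table, level = 0.95,
                        method = c("halperin", "logit")) {
  method <- match.arg(method)
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("`level` must be a single number in (0, 1)", call. = FALSE)
  ac <- arm_counts(table)
  if (ac$n1 < 2 || ac$n2 < 2)
    stop("interval estimation needs at least 2 participants per arm",
         call. = FALSE)
  p <- door_probability(table)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "halperin") {
    v <- rank_variance_null(table)
    if (v <= 0) {
      warning("degenerate table: confidence interval collapses to the point ",
              "estimate", call. = FALSE)
      return(new_effect(p, p, p, level,
                        method = "tie-corrected rank variance (degenerate)",
                        n1 = ac$n1, n2 = ac$n2))
    }
    half <- z * sqrt(v)
    new_effect(p, max(0, p - half), min(1, p + half), level,
               method = "tie-corrected rank variance (Halperin-type)",
               n1 = ac$n1, n2 = ac$n2)
  } else {
    v <- variance_u(table)
    if (v <= 0 || p <= 0 || p >= 1) {
      warning("degenerate table: confidence interval collapses to the point ",
              "estimate", call. = FALSE)
      return(new_effect(p, p, p, level, method = "logit Wald (degenerate)",
                        n1 = ac$n1, n2 = ac$n2))
    }
    se_logit <- sqrt(v) / (p * (1 - p))
    lg <- stats::qlogis(p) + c(-1, 1) * z * se_logit
    new_effect(p, stats::plogis(lg[1L]), stats::plogis(lg[2L]), level,
               method = "logit Wald on U-statistic variance",
               n1 = ac$n1, n2 = ac$n2)
  }
}

#' Wilcoxon-Mann-Whitney test of the 50% DOOR probability null
#'
#' Normal-approximation rank-sum test with tie-corrected null variance. The
#' standardized statistic is (P - 0.5) / se0 where se0 is the square root of
#' the tie-corrected rank variance. No continuity correction is applied by
#' default.
#'
#' @param table A [door_table()].
#' @param alternative `"two.sided"` (default) or `"greater"` (DOOR
#'   probability exceeds 50%, favoring experimental).
#' @param correct Logical; apply a continuity correction of
#'   1 / (2 n1 n2) to the estimate-null distance.
#' @return A list of class `door_wmw` with `p_value`, `statistic` (z),
#'   `estimate` and `alternative`.
#' @examples
#' wmw_test(door_fixture("dori05_door"))$p_value  # 0.58
#' @export
wmw_test <- function(table, alternative = c("two.sided", "greater"),
                     correct = FALSE) {
  alternative <- match.arg(alternative)
  p <- door_probability(table)
  v0 <- rank_variance_null(table)
  if (v0 <= 0) {
    warning("all observations tied: test is degenerate, p = 1", call. = FALSE)
    return(structure(list(p_value = 1, statistic = 0, estimate = p,
                          alternative = alternative), class = "door_wmw"))
  }
  delta <- p - 0.5
  if (correct) {
    pc <- as_pair_counts(table)
    delta <- sign(delta) * max(0, abs(delta) - 1 / (2 * pc$total))
  }
  z <- delta / sqrt(v0)
  p_value <- switch(alternative,
                    two.sided = 2 * stats::pnorm(-abs(z)),
                    greater = stats::pnorm(z, lower.tail = FALSE))
  structure(list(p_value = p_value, statistic = z, estimate = p,
                 alternative = alternative), class = "door_wmw")
}

#' @export
print.door_wmw <- function(x, ...) {
  cat(sprintf("WMW test (%s): z = %.3f, p = %.4g (DOOR probability %.1f%%)\n",
              x$alternative, x$statistic, x$p_value, 100 * x$estimate))
  invisible(x)
}

#' Full rank-based estimate for a DOOR table
#'
#' Convenience wrapper combining [door_probability()], [halperin_ci()] and
#' [wmw_test()] into a single effect record.
#'
#' @inheritParams halperin_ci
#' @param alternative Passed to [wmw_test()].
#' @return A `door_effect` with point estimate, CI and p-value.
#' @examples
#' door_estimate(door_fixture("dori05_door"))
#' @export
door_estimate <- function(table, level = 0.95,
                          alternative = c("two.sided", "greater")) {
  est <- halperin_ci(table, level = level)
  est$p_value <- wmw_test(table, alternative = alternative)$p_value
  est
}

#' DOOR probability for a binary component outcome
#'
#' Components of a DOOR outcome (e.g., clinical failure, SAE, death) are
#' binary endpoints analyzed as 2-level DOOR outcomes with "no event" the
#' more desirable level.
#'
#' @param x A 2 x 2 [door_table()] (no event column first), or a
#'   [door_data()] together with `component`.
#' @param component When `x` is patient-level data, the name of the
#'   component flag column (1 = event). Records with a missing flag are
#'   excluded with a warning.
#' @inheritParams door_estimate
#' @return A `door_effect`.
#' @examples
#' component_door(door_fixture("dori05_components")[["Absence of clinical success"]])
#' @export
component_door <- function(x, component = NULL, level = 0.95,
                           alternative = c("two.sided", "greater")) {
  if (inherits(x, "door_data")) {
    if (is.null(component) || !component %in% x$components)
      stop("`component` must name a component flag column", call. = FALSE)
    flag <- x$records[[component]]
    keep <- !is.na(flag)
    if (any(!keep))
      warning(sum(!keep), " record(s) with missing ", sQuote(component),
              " flag excluded", call. = FALSE)
    counts <- t(sapply(c("experimental", "control"), function(g) {
      f <- flag[keep & x$records$arm == g]
      c(sum(f == 0), sum(f == 1))
    }))
    x <- door_table(counts, arms = x$arms,
                    scheme = door_scheme(c("No event", component)))
  }
  if (ncol(x) != 2L)
    stop("a component table must have exactly 2 levels", call. = FALSE)
  door_estimate(x, level = level, alternative = alternative)
}

#' Cumulative DOOR probability at a dichotomization cut
#'
#' Dichotomizes the DOOR outcome as "category <= cut (more desirable) vs
#' worse" and estimates the 2-level DOOR probability, as displayed in
#' cumulative forest plots. Uses the same interval method as the overall
#' analysis.
#'
#' @param table A [door_table()].
#' @param cut Integer cut in 1..K-1.
#' @inheritParams door_estimate
#' @return A `door_effect`.
#' @examples
#' cumulative_door(door_fixture("dori05_door"), cut = 1)
#' @export
cumulative_door <- function(table, cut, level = 0.95,
                            alternative = c("two.sided", "greater")) {
  K <- ncol(table)
  if (!(is.numeric(cut) && length(cut) == 1L && cut == round(cut) &&
        cut >= 1 && cut < K))
    stop("`cut` must be an integer in 1..", K - 1, call. = FALSE)
  top <- seq_len(cut)
  sch <- door_scheme_of(table)
  collapsed <- cbind(rowSums(unclass(table)[, top, drop = FALSE]),
                     rowSums(unclass(table)[, -top, drop = FALSE]))
  lab2 <- if (cut < K - 1) paste0("Worse than ", sch$labels[cut])
          else sch$labels[K]
  tab2 <- door_table(collapsed, arms = rownames(table),
                     scheme = door_scheme(c(paste(sch$labels[seq_len(cut)],
                                                  collapse = " / "), lab2)))
  door_estimate(tab2, level = level, alternative = alternative)
}

#' Convert pair counts to related pairwise-comparison metrics
#'
#' @param x A `pair_counts`, [door_table()] or [door_data()].
#' @return Named list: `door_probability` (p), `win_ratio` (wins / losses,
#'   `Inf` when there are wins but no losses), `win_odds`
#'   ((wins + ties/2) / (losses + ties/2)), and `ntb` (net treatment
#'   benefit, 2p - 1).
#' @examples
#' convert_metrics(door_fixture("dori05_door"))
#' @export
convert_metrics <- function(x) {
  pc <- as_pair_counts(x)
  p <- door_probability(pc)
  win_ratio <- if (pc$losses > 0) pc$wins / pc$losses
               else if (pc$wins > 0) Inf else NaN
  wo_den <- pc$losses + pc$ties / 2
  win_odds <- if (wo_den > 0) (pc$wins + pc$ties / 2) / wo_den
              else if (pc$wins > 0) Inf else NaN
  list(door_probability = p, win_ratio = win_ratio, win_odds = win_odds,
       ntb = 2 * p - 1)
}

#' Forest-plot data for overall, cumulative and component DOOR probabilities
#'
#' Builds the tidy table behind a DOOR forest plot: the overall DOOR
#' probability, the cumulative probability at every cut, and (optionally)
#' each binary component.
#'
#' @param table A [door_table()].
#' @param components Optional named list of 2 x 2 [door_table()]s (no event
#'   first), e.g. from [door_fixture()].
#' @inheritParams door_estimate
#' @return A data frame of class `door_forest` with columns `label`, `type`
#'   (overall / cumulative / component), `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n1`, `n2`.
#' @examples
#' door_forest(door_fixture("dori05_door"),
#'             components = door_fixture("dori05_components"))
#' @export
door_forest <- function(table, components = NULL, level = 0.95) {
  sch <- door_scheme_of(table)
  rows <- list()
  add <- function(label, type, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, type = type, estimate = est$estimate,
      ci_low = est$ci_low, ci_high = est$ci_high, p_value = est$p_value,
      n1 = est$n1, n2 = est$n2, stringsAsFactors = FALSE)
  }
  add("DOOR (overall)", "overall", door_estimate(table, level = level))
  for (cut in seq_len(ncol(table) - 1L))
    add(paste0("Cumulative: top ", cut, " (", sch$labels[cut], ")"),
        "cumulative", cumulative_door(table, cut, level = level))
  if (!is.null(components))
    for (nm in names(components))
      add(nm, "component", component_door(components[[nm]], level = level))
  out <- do.call(rbind, rows)
  class(out) <- c("door_forest", "data.frame")
  attr(out, "level") <- level
  out
}

#' Plot a DOOR forest table
#'
#' Base-graphics forest plot of the estimates in a [door_forest()] table,
#' with a reference line at 50%.
#'
#' @param x A `door_forest` data frame.
#' @param xlim Horizontal limits on the percent scale.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.door_forest <- function(x, xlim = NULL, ...) {
  n <- nrow(x)
  est <- 100 * x$estimate
  lo <- 100 * x$ci_low
  hi <- 100 * x$ci_high
  if (is.null(xlim)) xlim <- range(lo, hi, 50)
  op <- graphics::par(mar = c(4, 16, 2, 2))
  on.exit(graphics::par(op))
  graphics::plot(est, rev(seq_len(n)), xlim = xlim, ylim = c(0.5, n + 0.5),
                 pch = 15, yaxt = "n", xlab = "DOOR probability (%)",
                 ylab = "", ...)
  graphics::segments(lo, rev(seq_len(n)), hi, rev(seq_len(n)))
  graphics::abline(v = 50, lty = 2, col = "grey50")
  graphics::axis(2, at = rev(seq_len(n)), labels = x$label, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
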