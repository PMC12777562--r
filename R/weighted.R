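# per-category weight mass by arm; drops missing categories with a warning
weight_mass <- function(data) {
  rec <- data$records
  miss <- is.na(rec$category)
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing DOOR category excluded ",
            "from weighted analysis", call. = FALSE)
    rec <- rec[!miss, , drop = FALSE]
  }
  K <- data$scheme$K
  A <- vapply(seq_len(K), function(k)
    sum(rec$weight[rec$arm == "experimental" & rec$category == k]),
    numeric(1))
  B <- vapply(seq_len(K), function(k)
    sum(rec$weight[rec$arm == "control" & rec$category == k]), numeric(1))
  if (sum(A) <= 0 || sum(B) <= 0)
    stop("total weight must be positive in both arms", call. = FALSE)
  list(A = A, B = B, rec = rec)
}

#' Weighted cross-arm win/tie/loss mass
#'
#' Weighted analogue of [count_pairs()]: wins, ties and losses are sums of
#' w_i * w_j over cross-arm pairs. With unit weights this reduces exactly
#' to the unweighted pair counts. Effective per-arm sample sizes
#' (sum w)^2 / sum(w^2) are attached.
#'
#' @param data A [door_data()] with weights (unit weights by default).
#' @return A `pair_counts` with additional elements `ess1`, `ess2`.
#' @export
weighted_pair_counts <- function(data) {
  wm <- weight_mass(data)
  K <- length(wm$A)
  b_gt <- c(rev(cumsum(rev(wm$B)))[-1L], 0)
  wins <- sum(wm$A * b_gt)
  ties <- sum(wm$A * wm$B)
  total <- sum(wm$A) * sum(wm$B)
  w1 <- wm$rec$weight[wm$rec$arm == "experimental"]
  w2 <- wm$rec$weight[wm$rec$arm == "control"]
  structure(list(wins = wins, ties = ties, losses = total - wins - ties,
                 total = total, n1 = length(w1), n2 = length(w2),
                 ess1 = sum(w1)^2 / sum(w1^2),
                 ess2 = sum(w2)^2 / sum(w2^2)),
            class = "pair_counts")
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Converts user-supplied propensity scores (the probability of receiving
#' the experimental intervention given baseline covariates) into stabilized
#' IPTW weights: marginal arm probability / propensity for experimental
#' participants and marginal / (1 - propensity) for controls. Weights
#' beyond the configured percentiles are truncated to those percentiles,
#' with a message giving the count.
#'
#' @param data A [door_data()] whose records carry a `propensity` column.
#' @param truncate Two probabilities giving the lower/upper percentile
#'   bounds for weight truncation; default `c(0, 1)` (no truncation).
#' @return The dataset with its `weight` column replaced by the stabilized
#'   weights.
#' @export
stabilized_weights <- function(data, truncate = c(0, 1)) {
  rec <- data$records
  ps <- rec$propensity
  if (is.null(ps))
    stop("dataset has no propensity scores", call. = FALSE)
  bad <- which(is.na(ps) | ps <= 0 | ps >= 1)
  if (length(bad))
    stop("propensity for record ", sQuote(rec$id[bad[1L]]),
         " is missing or outside (0, 1)", call. = FALSE)
  p_marg <- mean(rec$arm == "experimental")
  w <- ifelse(rec$arm == "experimental", p_marg / ps, (1 - p_marg) / (1 - ps))
  if (truncate[1L] > 0 || truncate[2L] < 1) {
    bounds <- stats::quantile(w, truncate, names = FALSE)
    n_trunc <- sum(w < bounds[1L] | w > bounds[2L])
    if (n_trunc > 0)
      message(n_trunc, " weight(s) truncated to the [",
              truncate[1L], ", ", truncate[2L], "] percentile bounds")
    w <- pmin(pmax(w, bounds[1L]), bounds[2L])
  }
  data$records$weight <- w
  data
}

# stratified (within-arm) bootstrap of a statistic computed from a door_data
boot_within_arms <- function(data, statistic, B, seed) {
  if (!is.null(seed)) set.seed(seed)
  rec <- data$records[!is.na(data$records$category), , drop = FALSE]
  idx_e <- which(rec$arm == "experimental")
  idx_c <- which(rec$arm == "control")
  vapply(seq_len(B), function(b) {
    take <- c(sample(idx_e, replace = TRUE), sample(idx_c, replace = TRUE))
    statistic(rec[take, , drop = FALSE], data$scheme$K)
  }, numeric(1))
}

wmass_stat <- function(rec, K) {
  A <- vapply(seq_len(K), function(k)
    sum(rec$weight[rec$arm == "experimental" & rec$category == k]),
    numeric(1))
  B <- vapply(seq_len(K), function(k)
    sum(rec$weight[rec$arm == "control" & rec$category == k]), numeric(1))
  b_gt <- c(rev(cumsum(rev(B)))[-1L], 0)
  (sum(A * b_gt) + sum(A * B) / 2) / (sum(A) * sum(B))
}

#' IPTW-weighted DOOR probability with bootstrap interval
#'
#' Weighted DOOR probability
#' \deqn{\hat p_w = \sum_{i \in exp, j \in ctl} w_i w_j
#'   [1(i\ more\ desirable) + \tfrac12 1(tie)] / \sum w_i w_j,}
#' with a percentile confidence interval from a stratified nonparametric
#' bootstrap (resampling participants within each arm). With unit weights
#' the point estimate equals the unweighted DOOR probability exactly.
#'
#' @param data A [door_data()] with weights (e.g., from
#'   [stabilized_weights()]).
#' @param level Confidence level; default 0.95.
#' @param B Bootstrap replicates; default 2,000.
#' @param seed Seed for the bootstrap; required for reproducibility.
#' @return A `door_effect` (no p-value) whose method string records B and
#'   the effective sample sizes.
#' @export
weighted_door <- function(data, level = 0.95, B = 2000, seed = NULL) {
  pc <- weighted_pair_counts(data)
  p <- door_probability(pc)
  boots <- boot_within_arms(data, wmass_stat, B = B, seed = seed)
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  new_effect(p, min(qs[1L], p), max(qs[2L], p), level,
             method = sprintf(
               "IPTW-weighted DOOR probability; stratified percentile bootstrap (B=%d, ESS %.1f/%.1f)",
               B, pc$ess1, pc$ess2),
             n1 = pc$n1, n2 = pc$n2)
}

grade_stat <- function(key) {
  force(key)
  function(rec, K) {
    we <- rec$arm == "experimental"
    g <- key[rec$category]
    sum(rec$weight[we] * g[we]) / sum(rec$weight[we]) -
      sum(rec$weight[!we] * g[!we]) / sum(rec$weight[!we])
  }
}

#' IPTW-weighted partial-credit contrast with bootstrap interval
#'
#' Difference in weighted mean grades (experimental minus control) under a
#' grading key, with a stratified percentile bootstrap interval. With unit
#' weights the point estimate equals [partial_credit_diff()]'s.
#'
#' @inheritParams weighted_door
#' @param key A [grading_key()] of length K.
#' @return A `door_effect` on the grade-point scale.
#' @export
weighted_partial_credit <- function(data, key, level = 0.95, B = 2000,
                                    seed = NULL) {
  key <- as_grading_key(key, data$scheme$K)
  wm <- weight_mass(data)
  stat <- grade_stat(key)
  est <- stat(wm$rec, data$scheme$K)
  boots <- boot_within_arms(data, stat, B = B, seed = seed)
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  pc <- weighted_pair_counts(data)
  new_effect(est, min(qs[1L], est), max(qs[2L], est), level,
             method = sprintf(
               "IPTW-weighted mean grade difference; stratified percentile bootstrap (B=%d)",
               B),
             scale = "grade-points", n1 = pc$n1, n2 = pc$n2)
}
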