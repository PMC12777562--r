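#' Specify a design-stage scenario
#'
#' A design scenario fixes the per-arm DOOR category probabilities, the
#' per-arm sample size, the test level, and the simulation settings used by
#' [power_sim()].
#'
#' @param probs_exp,probs_ctl Probability vectors of length K (most
#'   desirable first); each must sum to 1 within 1e-9.
#' @param n_per_arm Participants per arm.
#' @param alpha Two-sided test level; default 0.05.
#' @param n_sims Number of simulated trials; default 2,000.
#' @param seed Simulation seed (mandatory for reproducibility).
#' @return Object of class `design_scenario`.
#' @examples
#' design_scenario(c(0.7, 0.2, 0.1), c(0.6, 0.25, 0.15), n_per_arm = 200,
#'                 seed = 1)
#' @export
design_scenario <- function(probs_exp, probs_ctl, n_per_arm, alpha = 0.05,
                            n_sims = 2000, seed) {
  check_probs <- function(p, what) {
    if (any(is.na(p)) || any(p < 0))
      stop(what, " must be nonnegative", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  check_probs(probs_exp, "probs_exp")
  check_probs(probs_ctl, "probs_ctl")
  if (length(probs_exp) != length(probs_ctl))
    stop("probability vectors must have equal length", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (n_per_arm < 2) stop("`n_per_arm` must be at least 2", call. = FALSE)
  if (n_sims < 100) stop("`n_sims` must be at least 100", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("a simulation `seed` is required", call. = FALSE)
  structure(list(probs_exp = as.numeric(probs_exp),
                 probs_ctl = as.numeric(probs_ctl),
                 n_per_arm = as.integer(n_per_arm), alpha = alpha,
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "design_scenario")
}

#' Population DOOR probability implied by two multinomials
#'
#' Closed form for the true DOOR probability under category probabilities
#' pi_exp and pi_ctl:
#' sum_k pi_exp\[k\] * (sum_\{j>k\} pi_ctl\[j\] + pi_ctl\[k\] / 2).
#'
#' @param probs_exp A `design_scenario`, or the experimental probability
#'   vector.
#' @param probs_ctl Control probability vector (ignored when a scenario is
#'   given).
#' @return The true DOOR probability in \[0, 1\].
#' @examples
#' true_door_probability(c(0.6, 0.4), c(0.4, 0.6))  # 0.6
#' @export
true_door_probability <- function(probs_exp, probs_ctl = NULL) {
  if (inherits(probs_exp, "design_scenario")) {
    probs_ctl <- probs_exp$probs_ctl
    probs_exp <- probs_exp$probs_exp
  }
  K <- length(probs_exp)
  ctl_gt <- c(rev(cumsum(rev(probs_ctl)))[-1L], 0)
  sum(probs_exp * (ctl_gt + probs_ctl / 2))
}

# vectorized rejection indicator for S simulated trials: draws per-arm
# multinomial tables and applies the tie-corrected normal WMW test
simulate_rejections <- function(scenario, n_per_arm = scenario$n_per_arm) {
  K <- length(scenario$probs_exp)
  A <- stats::rmultinom(scenario$n_sims, n_per_arm, scenario$probs_exp)
  B <- stats::rmultinom(scenario$n_sims, n_per_arm, scenario$probs_ctl)
  n1 <- n_per_arm
  n2 <- n_per_arm
  N <- n1 + n2
  Bgt <- apply(B, 2, function(col) c(rev(cumsum(rev(col)))[-1L], 0))
  wins <- colSums(A * Bgt)
  ties <- colSums(A * B)
  P <- (wins + ties / 2) / (n1 * n2)
  tt <- A + B
  tie_corr <- 1 - colSums(tt^3 - tt) / (N^3 - N)
  v0 <- (N + 1) / (12 * n1 * n2) * tie_corr
  z <- ifelse(v0 > 0, (P - 0.5) / sqrt(v0), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p < scenario$alpha
}

#' Simulation-based power for the WMW test of the DOOR probability
#'
#' Simulates two-arm trials by drawing per-arm multinomial category counts,
#' applies the tie-corrected WMW test at the scenario's alpha, and reports
#' the rejection fraction with a binomial Monte-Carlo confidence interval.
#' Deterministic given the scenario seed.
#'
#' @param scenario A [design_scenario()].
#' @param mc_level Level of the Monte-Carlo interval on the power estimate;
#'   default 0.95.
#' @return List of class `door_power`: `power`, `mc_ci`, `n_per_arm`,
#'   `n_sims`, `alpha`, `seed`, `true_p` (the closed-form DOOR
#'   probability).
#' @examples
#' power_sim(design_scenario(c(0.8, 0.2), c(0.6, 0.4), n_per_arm = 100,
#'                           n_sims = 500, seed = 7))
#' @export
power_sim <- function(scenario, mc_level = 0.95) {
  stopifnot(inherits(scenario, "design_scenario"))
  set.seed(scenario$seed)
  rej <- simulate_rejections(scenario)
  power <- mean(rej)
  se <- sqrt(power * (1 - power) / scenario$n_sims)
  z <- stats::qnorm(1 - (1 - mc_level) / 2)
  structure(list(power = power,
                 mc_ci = c(max(0, power - z * se), min(1, power + z * se)),
                 n_per_arm = scenario$n_per_arm, n_sims = scenario$n_sims,
                 alpha = scenario$alpha, seed = scenario$seed,
                 true_p = true_door_probability(scenario)),
            class = "door_power")
}

#' @export
print.door_power <- function(x, ...) {
  cat(sprintf(
    "Simulated power: %.3f (MC %d%% CI %.3f-%.3f) at n=%d/arm, alpha=%g\n",
    x$power, 95, x$mc_ci[1L], x$mc_ci[2L], x$n_per_arm, x$alpha))
  cat(sprintf("  true DOOR probability %.4f; %d simulations, seed %d\n",
              x$true_p, x$n_sims, x$seed))
  invisible(x)
}

#' Smallest per-arm sample size reaching a target power
#'
#' Searches over per-arm sample sizes by bracketing (doubling) and
#' bisection, re-running the power simulation at each candidate size with
#' common random numbers (the scenario seed is reset before every
#' candidate) so that the estimated power curve is monotone in n and the
#' search reproducible.
#'
#' @param scenario A [design_scenario()]; its `n_per_arm` is the lower
#'   bound of the search.
#' @param target_power Required power; default 0.9.
#' @param n_max Largest per-arm size to consider; default 100,000.
#' @return List of class `door_samplesize`: `n_per_arm`, `power` (achieved
#'   at that n), `target_power`, `evaluations` (data frame of candidate n
#'   and power).
#' @export
sample_size_search <- function(scenario, target_power = 0.9,
                               n_max = 100000) {
  stopifnot(inherits(scenario, "design_scenario"))
  if (abs(true_door_probability(scenario) - 0.5) < 1e-12)
    stop("scenario has no effect (true DOOR probability = 0.5); ",
         "no sample size attains power above alpha", call. = FALSE)
  if (!(target_power > 0 && target_power < 1))
    stop("`target_power` must lie in (0, 1)", call. = FALSE)
  evals <- list()
  power_at <- function(n) {
    set.seed(scenario$seed)
    pw <- mean(simulate_rejections(scenario, n_per_arm = n))
    evals[[length(evals) + 1L]] <<- data.frame(n_per_arm = n, power = pw)
    pw
  }
  lo <- max(2L, scenario$n_per_arm)
  p_lo <- power_at(lo)
  if (p_lo >= target_power) {
    return(structure(list(n_per_arm = lo, power = p_lo,
                          target_power = target_power,
                          evaluations = do.call(rbind, evals)),
                     class = "door_samplesize"))
  }
  hi <- lo
  p_hi <- p_lo
  while (p_hi < target_power) {
    if (hi >= n_max)
      stop("target power ", target_power, " not reached by n_per_arm = ",
           n_max, "; best found ", round(p_hi, 3), " at n = ", hi,
           call. = FALSE)
    hi <- min(n_max, hi * 2L)
    p_hi <- power_at(hi)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_at(mid) >= target_power) hi <- mid else lo <- mid
  }
  structure(list(n_per_arm = hi, power = power_at(hi),
                 target_power = target_power,
                 evaluations = do.call(rbind, evals)),
            class = "door_samplesize")
}

#' @export
print.door_samplesize <- function(x, ...) {
  cat(sprintf("Smallest n per arm reaching power %.2f: %d (achieved %.3f)\n",
              x$target_power, x$n_per_arm, x$power))
  invisible(x)
}
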