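#' Simulate a two-arm DOOR trial
#'
#' Draws patient-level data with per-arm multinomial DOOR categories and
#' component-event flags consistent with the category definition: category
#' k (k = 1..K-1) is "alive with k-1 deleterious events" -- exactly k-1 of
#' the non-fatal component flags are set, chosen with the configured
#' probabilities -- and category K is death, which sets the death flag (and,
#' by construction here, no non-fatal flags). The generator therefore never
#' produces flags that contradict the recorded category.
#'
#' @param n_exp,n_ctl Participants per arm.
#' @param probs_exp,probs_ctl Category probability vectors of length K.
#' @param components Names of the K-2 non-fatal component events; default
#'   `"event_1"` ... A `death` flag is always added.
#' @param component_probs Relative selection probabilities of the non-fatal
#'   components (which events a patient with fewer than K-2 events
#'   experienced); default equal.
#' @param scheme Optional [door_scheme()]; default labels follow the
#'   "alive with m events" pattern.
#' @param seed Mandatory seed.
#' @return A [door_data()] with component flags and unit weights.
#' @examples
#' simulate_door_trial(50, 50, c(0.7, 0.2, 0.07, 0.02, 0.01),
#'                     c(0.6, 0.25, 0.1, 0.04, 0.01), seed = 11)
#' @export
simulate_door_trial <- function(n_exp, n_ctl, probs_exp, probs_ctl,
                                components = NULL, component_probs = NULL,
                                scheme = NULL, seed) {
  if (missing(seed) || is.null(seed))
    stop("a `seed` is required", call. = FALSE)
  K <- length(probs_exp)
  if (length(probs_ctl) != K)
    stop("probability vectors must have equal length", call. = FALSE)
  if (abs(sum(probs_exp) - 1) > 1e-9 || abs(sum(probs_ctl) - 1) > 1e-9 ||
      any(probs_exp < 0) || any(probs_ctl < 0))
    stop("category probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  if (K < 3)
    stop("event-level simulation needs K >= 3 (alive categories plus death)",
         call. = FALSE)
  if (is.null(components))
    components <- paste0("event_", seq_len(K - 2L))
  if (length(components) != K - 2L)
    stop("need exactly K-2 = ", K - 2L, " non-fatal components to span ",
         "categories 'alive with 0..", K - 2L, " events'", call. = FALSE)
  if (is.null(component_probs))
    component_probs <- rep(1 / (K - 2L), K - 2L)
  if (length(component_probs) != K - 2L || any(component_probs < 0) ||
      sum(component_probs) <= 0)
    stop("`component_probs` must be ", K - 2L, " nonnegative values",
         call. = FALSE)
  if (is.null(scheme))
    scheme <- door_scheme(c("Alive with no events",
                            paste("Alive with", seq_len(K - 2L), "event(s)"),
                            "Death"))
  if (scheme$K != K) stop("scheme does not match K", call. = FALSE)

  set.seed(seed)
  category <- c(sample.int(K, n_exp, replace = TRUE, prob = probs_exp),
                sample.int(K, n_ctl, replace = TRUE, prob = probs_ctl))
  n <- n_exp + n_ctl
  M <- K - 2L
  flags <- matrix(0L, nrow = n, ncol = M,
                  dimnames = list(NULL, components))
  for (i in seq_len(n)) {
    k <- category[i]
    if (k > 1L && k < K) {
      hit <- sample.int(M, k - 1L, prob = component_probs)
      flags[i, hit] <- 1L
    }
  }
  comp <- as.data.frame(flags)
  comp$death <- as.integer(category == K)
  door_data(id = sprintf("S%05d", seq_len(n)),
            arm = rep(c("experimental", "control"), c(n_exp, n_ctl)),
            category = category, scheme = scheme,
            experimental = "experimental", components = comp)
}

# exponential tilt of a category distribution toward less desirable
# outcomes; gamma is the log-odds shift between best and worst category
tilt_probs <- function(p, gamma) {
  q <- p * exp(gamma * (seq_along(p) - 1) / (length(p) - 1))
  q / sum(q)
}

#' Confounded two-arm scenario for validating IPTW estimators
#'
#' Generates a nonrandomized comparison in which a binary baseline
#' covariate Z ~ Bernoulli(0.5) shifts both treatment assignment
#' (P(experimental | Z) = plogis(effect * (Z - 1/2))) and outcome severity
#' (the category distribution of either potential arm is exponentially
#' tilted toward less desirable categories by `effect` log-odds when
#' Z = 1). True propensity scores are recorded, so
#' [stabilized_weights()] + [weighted_door()] can be applied directly.
#'
#' The returned truth is the marginal (Z-standardized) DOOR probability,
#' computed in closed form from the mixture distributions
#' 0.5 * pi_a(Z=0) + 0.5 * pi_a(Z=1); with `effect = 0` it reduces to
#' [true_door_probability()] of the base vectors. For `effect > 0` the
#' unweighted estimate is biased downward: Z = 1 patients are both sicker
#' and over-represented in the experimental arm.
#'
#' @param effect Log-odds shift applied to assignment and outcome;
#'   default 2.
#' @param n_per_arm Expected participants per arm (total 2 * n_per_arm
#'   drawn; realized arm sizes are random); default 400.
#' @param probs_exp,probs_ctl Base (Z = 0 ... well, Z-averaged design)
#'   category distributions of the two arms; defaults give a 4-level
#'   outcome with a clear treatment benefit.
#' @param seed Mandatory seed.
#' @return List with `data` (a [door_data()] with `propensity` and the
#'   confounder in `records$z`), `truth` (marginal DOOR probability),
#'   `naive` (asymptotic value of the unweighted estimator, for
#'   reference), and the tilted per-stratum distributions.
#' @examples
#' sc <- confounded_scenario(effect = 2, n_per_arm = 200, seed = 3)
#' sc$truth
#' @export
confounded_scenario <- function(effect = 2, n_per_arm = 400,
                                probs_exp = c(0.45, 0.30, 0.15, 0.10),
                                probs_ctl = c(0.25, 0.35, 0.20, 0.20),
                                seed) {
  if (missing(seed) || is.null(seed))
    stop("a `seed` is required", call. = FALSE)
  if (!is.finite(effect)) stop("`effect` must be finite", call. = FALSE)
  pe0 <- probs_exp
  pc0 <- probs_ctl
  pe1 <- tilt_probs(probs_exp, effect)
  pc1 <- tilt_probs(probs_ctl, effect)
  pebar <- 0.5 * pe0 + 0.5 * pe1
  pcbar <- 0.5 * pc0 + 0.5 * pc1
  truth <- true_door_probability(pebar, pcbar)
  # asymptotic unweighted value: observed arms over-represent one stratum
  pz1 <- stats::plogis(effect / 2)   # P(exp | z = 1)
  pz0 <- stats::plogis(-effect / 2)  # P(exp | z = 0)
  wz1e <- pz1 / (pz1 + pz0)
  wz1c <- (1 - pz1) / ((1 - pz1) + (1 - pz0))
  naive <- true_door_probability((1 - wz1e) * pe0 + wz1e * pe1,
                                 (1 - wz1c) * pc0 + wz1c * pc1)

  set.seed(seed)
  n <- 2L * as.integer(n_per_arm)
  z <- stats::rbinom(n, 1L, 0.5)
  ps <- stats::plogis(effect * (z - 0.5))
  arm <- ifelse(stats::runif(n) < ps, "experimental", "control")
  if (length(unique(arm)) < 2L)  # degenerate draw at tiny n
    arm[1:2] <- c("experimental", "control")
  K <- length(pe0)
  category <- integer(n)
  strata <- list(list(arm == "experimental" & z == 0L, pe0),
                 list(arm == "experimental" & z == 1L, pe1),
                 list(arm == "control" & z == 0L, pc0),
                 list(arm == "control" & z == 1L, pc1))
  for (s in strata) {
    m <- sum(s[[1L]])
    if (m > 0)
      category[s[[1L]]] <- sample.int(K, m, replace = TRUE, prob = s[[2L]])
  }
  data <- door_data(id = sprintf("C%05d", seq_len(n)), arm = arm,
                    category = category, scheme = default_scheme(K),
                    experimental = "experimental", propensity = ps)
  data$records$z <- z
  list(data = data, truth = truth, naive = naive,
       strata = list(exp_z0 = pe0, exp_z1 = pe1, ctl_z0 = pc0,
                     ctl_z1 = pc1))
}
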