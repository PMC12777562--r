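test_that("closed-form pair counting matches published-table arithmetic", {
  pc <- count_pairs(dori_table())
  expect_equal(pc$wins, 32769)
  expect_equal(pc$ties, 77007)
  expect_equal(pc$losses, 30100)
  expect_equal(pc$total, 374 * 374)
})

test_that("pair counting equals the brute-force loop on random tables", {
  set.seed(7)
  for (i in 1:40) {
    tb <- random_table()
    pc <- count_pairs(tb)
    bf <- brute_force_pairs(tb)
    expect_equal(pc$wins, bf$wins)
    expect_equal(pc$ties, bf$ties)
    expect_equal(pc$losses, bf$losses)
  }
})

test_that("degenerate tables give all-tie or all-win pair counts", {
  all_tied <- door_table(rbind(c(5, 0), c(7, 0)))
  pc <- count_pairs(all_tied)
  expect_equal(c(pc$wins, pc$ties, pc$losses), c(0, 35, 0))
  expect_equal(door_probability(all_tied), 0.5)

  dominant <- door_table(rbind(c(4, 0, 0), c(0, 0, 6)))
  pc2 <- count_pairs(dominant)
  expect_equal(c(pc2$wins, pc2$ties, pc2$losses), c(24, 0, 0))
  expect_equal(door_probability(dominant), 1)
})

test_that("DOOR probability reproduces worked values", {
  expect_equal(door_probability(dori_table()), 0.5095406, tolerance = 1e-6)
  expect_equal(
    door_probability(structure(list(wins = 3, ties = 2, losses = 5,
                                    total = 10, n1 = 5, n2 = 2),
                               class = "pair_counts")), 0.4)
  same <- door_table(rbind(c(10, 5, 2), c(10, 5, 2)))
  expect_equal(door_probability(same), 0.5)
})

test_that("direction symmetry p(A,B) + p(B,A) = 1 holds exactly", {
  set.seed(13)
  for (i in 1:20) {
    tb <- random_table()
    expect_equal(door_probability(tb) + door_probability(swap_arms(tb)),
                 1, tolerance = 1e-15)
  }
})

test_that("strict stochastic dominance implies DOOR probability above 50%", {
  set.seed(29)
  for (i in 1:20) {
    K <- sample(3:6, 1)
    b <- as.vector(stats::rmultinom(1, 60, rexp(K)))
    # shift control mass toward worse categories to dominate it
    a <- b
    from <- which(a > 0)[1]
    a[from] <- a[from] - 1
    a[1] <- a[1] + 1
    tb <- door_table(rbind(a + c(3, rep(0, K - 1)), b + c(0, rep(0, K - 2), 3)))
    cum_a <- cumsum(tb[1, ]) / sum(tb[1, ])
    cum_b <- cumsum(tb[2, ]) / sum(tb[2, ])
    stopifnot(all(cum_a >= cum_b), any(cum_a > cum_b))
    expect_gt(door_probability(tb), 0.5)
  }
})

test_that("U-statistic variance agrees with a bootstrap oracle and 1/n scaling", {
  tb <- dori_table()
  v <- variance_u(tb)
  expect_gt(v, 0)

  set.seed(99)
  B <- 10000
  pa <- as.numeric(tb[1, ]) / 374
  pb <- as.numeric(tb[2, ]) / 374
  A <- stats::rmultinom(B, 374, pa)
  Bm <- stats::rmultinom(B, 374, pb)
  Bgt <- apply(Bm, 2, function(col) c(rev(cumsum(rev(col)))[-1], 0))
  phat <- (colSums(A * Bgt) + colSums(A * Bm) / 2) / (374 * 374)
  expect_equal(v, stats::var(phat), tolerance = 0.1)

  doubled <- door_table(2 * unclass(tb))
  expect_equal(variance_u(doubled) / v, 0.5, tolerance = 0.05)

  all_tied <- door_table(rbind(c(5, 0), c(7, 0)))
  expect_equal(variance_u(all_tied), 0)
})

test_that("confidence interval reproduces published bounds to 0.1 points", {
  ci <- halperin_ci(dori_table())
  expect_equal(round(100 * ci$estimate, 1), 51.0)
  expect_equal(round(100 * ci$ci_low, 1), 47.6)
  expect_equal(round(100 * ci$ci_high, 1), 54.3)

  comp <- dori_components()
  ci_inf <- halperin_ci(comp[["Infectious complications"]])
  expect_equal(round(100 * c(ci_inf$ci_low, ci_inf$ci_high), 1),
               c(46.2, 49.0))

  # logit fallback stays inside [0,1] and brackets the estimate
  ci_lw <- halperin_ci(dori_table(), method = "logit")
  expect_true(ci_lw$ci_low < ci_lw$estimate &&
                ci_lw$estimate < ci_lw$ci_high)
  expect_match(ci_lw$method, "logit")

  expect_warning(ci_d <- halperin_ci(door_table(rbind(c(5, 0), c(7, 0)))),
                 "degenerate")
  expect_equal(ci_d$ci_low, ci_d$ci_high)
})

test_that("interval coverage is near nominal under identical arms", {
  set.seed(2024)
  probs <- c(0.55, 0.3, 0.1, 0.05)
  reps <- 2000
  n <- 100
  A <- stats::rmultinom(reps, n, probs)
  B <- stats::rmultinom(reps, n, probs)
  covered <- vapply(seq_len(reps), function(i) {
    tb <- door_table(rbind(A[, i], B[, i]))
    ci <- halperin_ci(tb)
    ci$ci_low <= 0.5 && 0.5 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("WMW test reproduces the published p-value and edge behavior", {
  expect_equal(wmw_test(dori_table())$p_value, 0.58, tolerance = 0.01)

  same <- door_table(rbind(c(200, 100, 50), c(200, 100, 50)))
  expect_gt(wmw_test(same)$p_value, 0.99)

  extreme <- door_table(rbind(c(50, 0), c(0, 50)))
  expect_lt(wmw_test(extreme)$p_value, 1e-10)
  expect_gt(abs(wmw_test(extreme)$statistic), 8)

  expect_warning(p_tied <- wmw_test(door_table(rbind(c(5, 0), c(7, 0)))),
                 "tied")
  expect_equal(p_tied$p_value, 1)

  # one-sided in the favorable direction halves the two-sided p here
  tb <- dori_table()
  expect_equal(wmw_test(tb, "greater")$p_value,
               wmw_test(tb)$p_value / 2)
})

test_that("cumulative DOOR dichotomizes at each cut", {
  expect_equal(cumulative_door(dori_table(), 1)$estimate, 0.5133690,
               tolerance = 1e-6)
  same <- door_table(rbind(c(30, 20, 10), c(30, 20, 10)))
  for (cut in 1:2)
    expect_equal(cumulative_door(same, cut)$estimate, 0.5)
  # when arms differ only in the death column, the last cut equals the
  # death component analysis
  tb <- door_table(rbind(c(100, 50, 3), c(100, 50, 1)))
  death <- door_table(rbind(c(150, 3), c(150, 1)))
  expect_equal(cumulative_door(tb, 2)$estimate,
               component_door(death)$estimate)
  expect_error(cumulative_door(dori_table(), 5), "1..4")
})

test_that("component analyses reproduce published component probabilities", {
  comp <- dori_components()
  clin <- component_door(comp[["Absence of clinical success"]])
  expect_equal(round(100 * clin$estimate, 1), 54.3)
  expect_equal(round(100 * c(clin$ci_low, clin$ci_high), 1), c(51.1, 57.4))
  inf <- component_door(comp[["Infectious complications"]])
  expect_equal(round(100 * inf$estimate, 1), 47.6)
  death <- component_door(comp[["Death"]])
  expect_equal(death$estimate, 0.4986631, tolerance = 1e-6)
})

test_that("component analyses work from patient-level flags", {
  sch <- door_scheme(c("alive no event", "alive event", "death"))
  d <- door_data(id = 1:8, arm = rep(c("A", "B"), each = 4),
                 category = c(1, 1, 2, 3, 1, 2, 2, 2), scheme = sch,
                 experimental = "A",
                 components = data.frame(ev = c(0, 0, 1, NA, 0, 1, 1, 1)))
  expect_warning(est <- component_door(d, "ev"), "missing")
  # flags after exclusion: A 0,0,1; B 0,1,1,1
  manual <- component_door(door_table(rbind(c(2, 1), c(1, 3))))
  expect_equal(est$estimate, manual$estimate)
})

test_that("metric conversions satisfy their identities", {
  m <- convert_metrics(dori_table())
  expect_equal(m$win_ratio, 32769 / 30100)
  expect_equal(m$win_odds, (32769 + 77007 / 2) / (30100 + 77007 / 2))
  expect_equal(m$ntb, 2 * m$door_probability - 1)

  set.seed(5)
  for (i in 1:15) {
    tb <- random_table()
    m <- convert_metrics(tb)
    p <- door_probability(tb)
    expect_equal(m$ntb, 2 * p - 1)
    expect_equal(m$win_odds, p / (1 - p), tolerance = 1e-12)
  }

  # no ties: win ratio equals win odds; p = 0.5 gives ntb 0, win odds 1
  no_ties <- door_table(rbind(c(3, 0, 4, 0), c(0, 5, 0, 2)))
  m2 <- convert_metrics(no_ties)
  expect_equal(m2$win_ratio, m2$win_odds)
  balanced <- door_table(rbind(c(1, 1), c(1, 1)))
  mb <- convert_metrics(balanced)
  expect_equal(mb$ntb, 0)
  expect_equal(mb$win_odds, 1)
  # all wins: infinite ratio flagged as Inf
  expect_equal(convert_metrics(door_table(rbind(c(2, 0), c(0, 2))))$win_ratio,
               Inf)
})

test_that("forest table covers overall, cumulative and component rows", {
  fr <- door_forest(dori_table(), components = dori_components())
  expect_equal(nrow(fr), 1 + 4 + 4)
  expect_equal(fr$type,
               c("overall", rep("cumulative", 4), rep("component", 4)))
  expect_true(all(fr$ci_low <= fr$estimate & fr$estimate <= fr$ci_high))
  expect_equal(fr$estimate[1], 0.5095406, tolerance = 1e-6)
})
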