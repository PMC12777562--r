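test_that("mean grades reproduce worked values", {
  tb <- dori_table()
  m <- apply_grading(tb, c(100, 75, 50, 25, 0))
  expect_equal(unname(m), c(34100 / 374, 34100 / 374))

  ind <- suppressWarnings(apply_grading(tb, c(100, 0, 0, 0, 0)))
  expect_equal(unname(ind), 100 * c(263, 253) / 374)

  all_best <- door_table(rbind(c(9, 0), c(4, 0)))
  expect_equal(unname(apply_grading(all_best, c(100, 0))), c(100, 100))
})

test_that("partial credit difference reproduces worked values", {
  tb <- dori_table()
  even <- partial_credit_diff(tb, c(100, 75, 50, 25, 0))
  expect_equal(even$estimate, 0, tolerance = 1e-12)

  ind <- suppressWarnings(partial_credit_diff(tb, c(100, 0, 0, 0, 0)))
  expect_equal(ind$estimate, (263 - 253) / 374 * 100, tolerance = 1e-12)
  expect_equal(round(ind$estimate, 3), 2.674)

  same <- door_table(rbind(c(30, 20, 10), c(30, 20, 10)))
  expect_equal(partial_credit_diff(same, c(100, 40, 0))$estimate, 0)
  expect_true(ind$ci_low <= ind$estimate & ind$estimate <= ind$ci_high)
})

test_that("difference is affine in each grade with slope a_k/n1 - b_k/n2", {
  set.seed(17)
  for (i in 1:10) {
    tb <- random_table(K = 4)
    ac <- unclass(tb)
    slope2 <- ac[1, 2] / sum(ac[1, ]) - ac[2, 2] / sum(ac[2, ])
    d_at <- function(g2) suppressWarnings(
      partial_credit_diff(tb, c(100, g2, 30, 0))$estimate)
    expect_equal(d_at(80) - d_at(20), slope2 * 60, tolerance = 1e-10)
    # affinity: midpoint value is the average of endpoint values
    expect_equal(d_at(50), (d_at(20) + d_at(80)) / 2, tolerance = 1e-10)
  }
})

test_that("swapping arms negates the difference for every key", {
  set.seed(23)
  for (i in 1:10) {
    tb <- random_table(K = 5)
    key <- suppressWarnings(grading_key(c(100, sort(runif(3, 0, 100),
                                                    decreasing = TRUE), 0)))
    expect_equal(partial_credit_diff(tb, key)$estimate,
                 -partial_credit_diff(swap_arms(tb), key)$estimate,
                 tolerance = 1e-12)
  }
})

test_that("the indicator key equals 100 x difference in proportions", {
  set.seed(31)
  for (i in 1:10) {
    tb <- random_table(K = 2)
    ac <- unclass(tb)
    d <- partial_credit_diff(tb, c(100, 0))$estimate
    expect_equal(d, 100 * (ac[1, 1] / sum(ac[1, ]) - ac[2, 1] / sum(ac[2, ])),
                 tolerance = 1e-12)
  }
})

test_that("monotone keys agree in sign with stochastic dominance", {
  # experimental dominates control
  tb <- door_table(rbind(c(70, 20, 10), c(40, 30, 30)))
  for (g2 in c(10, 50, 90))
    expect_gt(partial_credit_diff(tb, c(100, g2, 0))$estimate, 0)
})

test_that("grade grids agree with scalar partial credit and label regions", {
  tb <- dori_table()
  grid <- grade_grid(tb, free_levels = c(2, 3), fixed_grades = c("4" = 10),
                     step = 25)
  i <- which(grid$g1 == 75)
  j <- which(grid$g2 == 50)
  scalar <- suppressWarnings(partial_credit_diff(tb, c(100, 75, 50, 10, 0)))
  expect_equal(grid$diff[i, j], scalar$estimate, tolerance = 1e-10)
  expect_equal(grid$p[i, j], scalar$p_value, tolerance = 1e-10)
  expect_equal(dim(grid$diff), c(5, 5))
  expect_true(grid$monotone[which(grid$g1 == 75), which(grid$g2 == 25)])
  expect_false(grid$monotone[which(grid$g1 == 25), which(grid$g2 == 75)])

  same <- door_table(rbind(c(30, 20, 10, 5), c(30, 20, 10, 5)))
  g0 <- grade_grid(same, free_levels = c(2, 3), step = 20)
  expect_true(all(g0$diff == 0))
  expect_true(all(g0$favored == "indeterminate"))

  dom <- door_table(rbind(c(3500, 1000, 500, 200), c(2500, 1500, 1000, 200)))
  expect_error(grade_grid(dom, free_levels = c(1, 3), step = 10), "interior")
})

test_that("a dominant large trial favors experimental over all monotone keys", {
  dom <- door_table(rbind(c(3500, 1000, 300, 200), c(2500, 1500, 500, 500)))
  gd <- grade_grid(dom, free_levels = c(2, 3), step = 10)
  expect_true(all(gd$favored[gd$monotone] == "experimental"))
})

test_that("tipping boundaries track sign structure", {
  # uniform favored status: empty boundary
  dom <- door_table(rbind(c(3500, 1000, 300, 200), c(2500, 1500, 500, 500)))
  gd <- grade_grid(dom, free_levels = c(2, 3), step = 10)
  if (all(gd$favored == "experimental"))
    expect_equal(nrow(tipping_boundary(gd)), 0)

  # antisymmetric construction: diff = c * (g2 - g3), boundary at diagonal
  anti <- door_table(rbind(c(2500, 3000, 2000, 2500),
                           c(2500, 2000, 3000, 2500)))
  ga <- grade_grid(anti, free_levels = c(2, 3), step = 10)
  tb <- tipping_boundary(ga)
  expect_gt(nrow(tb), 0)
  # every boundary edge lies within one grid step of the g2 = g3 diagonal
  mid <- cbind((tb$x0 + tb$x1) / 2, (tb$y0 + tb$y1) / 2)
  expect_lte(max(abs(mid[, 1] - mid[, 2])), 20)

  # single sign change along one axis gives a straight boundary line
  onez <- door_table(rbind(c(3000, 3500, 2000, 1500),
                           c(3000, 2500, 2000, 2500)))
  g1 <- grade_grid(onez, free_levels = c(2, 3), step = 10)
  tb1 <- tipping_boundary(g1)
  expect_gt(nrow(tb1), 0)
  expect_true(all(tb1$x0 == tb1$x1))       # all edges vertical
  expect_equal(length(unique(tb1$x0)), 1)  # a single straight line
})

test_that("grid sweeps require explicit grades for fixed interior levels", {
  expect_error(grade_grid(dori_table(), free_levels = c(2, 3), step = 50),
               "fixed_grades")
})
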