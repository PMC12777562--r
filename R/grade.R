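#' Per-arm mean grades under a grading key
#'
#' Applies a 0--100 grading key to the DOOR categories and returns the mean
#' grade in each arm: sum_k count_k * grade_k / n_arm.
#'
#' @param table A [door_table()].
#' @param key A [grading_key()] (or numeric vector) of length K.
#' @return Named numeric vector `c(experimental = , control = )` on the
#'   0--100 grade scale.
#' @examples
#' apply_grading(door_fixture("dori05_door"), c(100, 75, 50, 25, 0))
#' @export
apply_grading <- function(table, key) {
  key <- as_grading_key(key, ncol(table))
  ac <- arm_counts(table)
  c(experimental = sum(ac$a * key) / ac$n1,
    control = sum(ac$b * key) / ac$n2)
}

# per-arm mean and unpooled variance of graded scores from counts
grade_moments <- function(counts, n, key) {
  m <- sum(counts * key) / n
  s2 <- sum(counts * (key - m)^2) / (n - 1)
  list(mean = m, var = s2)
}

#' Between-arm difference in mean grades (partial credit analysis)
#'
#' Grade-based treatment contrast: the difference in mean grades
#' (experimental minus control) under a grading key, with a large-sample
#' normal CI and two-sided p-value using unpooled variances of the graded
#' scores.
#'
#' @inheritParams apply_grading
#' @param level Confidence level; default 0.95.
#' @return A `door_effect` on the grade-point scale (`scale =
#'   "grade-points"`).
#' @examples
#' partial_credit_diff(door_fixture("dori05_door"), c(100, 75, 50, 25, 0))
#' @export
partial_credit_diff <- function(table, key, level = 0.95) {
  key <- as_grading_key(key, ncol(table))
  ac <- arm_counts(table)
  if (ac$n1 < 2 || ac$n2 < 2)
    stop("partial credit inference needs at least 2 participants per arm",
         call. = FALSE)
  m1 <- grade_moments(ac$a, ac$n1, key)
  m2 <- grade_moments(ac$b, ac$n2, key)
  diff <- m1$mean - m2$mean
  se <- sqrt(m1$var / ac$n1 + m2$var / ac$n2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (se <= 0) {
    warning("zero variance in both arms: degenerate comparison, p = 1",
            call. = FALSE)
    return(new_effect(diff, diff, diff, level, p_value = 1,
                      method = "mean grade difference (degenerate)",
                      scale = "grade-points", n1 = ac$n1, n2 = ac$n2))
  }
  p_value <- 2 * stats::pnorm(-abs(diff / se))
  new_effect(diff, diff - z * se, diff + z * se, level, p_value = p_value,
             method = "mean grade difference, unpooled-variance normal",
             scale = "grade-points", n1 = ac$n1, n2 = ac$n2)
}

#' Sweep a grading-key grid over two free categories
#'
#' Evaluates the partial-credit contrast over a grid of grades for two free
#' interior categories, holding the remaining intermediate grades fixed
#' (category 1 is pinned at 100 and category K at 0). This is the
#' computation behind grading-key contour plots: each cell holds the
#' difference in mean grades and its p-value, and is labeled by which arm it
#' favors when significant.
#'
#' @param table A [door_table()].
#' @param free_levels Integer pair of interior category indices (neither 1
#'   nor K) whose grades vary.
#' @param fixed_grades Named numeric vector of grades for any remaining
#'   interior categories (names = category indices). Required when K > 4.
#' @param step Grid step in grade points; default 1 (a 101 x 101 grid).
#' @param alpha Two-sided significance threshold used to label cells;
#'   default 0.05.
#' @return An object of class `grade_grid`: list with `g1`, `g2` (grade
#'   axes for the two free categories), matrices `diff` and `p`, a `favored`
#'   character matrix (`"experimental"`, `"control"`, `"indeterminate"`),
#'   a logical `monotone` matrix flagging cells whose full key is monotone
#'   nonincreasing, `free_levels`, `alpha`, and the underlying `table`.
#' @examples
#' grade_grid(door_fixture("dori05_door"), free_levels = c(2, 3),
#'            fixed_grades = c("4" = 10), step = 25)
#' @export
grade_grid <- function(table, free_levels, fixed_grades = NULL, step = 1,
                       alpha = 0.05) {
  K <- ncol(table)
  free_levels <- as.integer(free_levels)
  if (length(free_levels) != 2L || anyDuplicated(free_levels) ||
      any(free_levels <= 1L | free_levels >= K))
    stop("`free_levels` must be two distinct interior categories ",
         "(grades for category 1 and ", K, " are pinned at 100 and 0)",
         call. = FALSE)
  interior <- setdiff(seq_len(K)[-c(1L, K)], free_levels)
  fixed <- rep(NA_real_, K)
  fixed[1L] <- 100
  fixed[K] <- 0
  if (length(interior)) {
    if (is.null(fixed_grades) ||
        !all(as.character(interior) %in% names(fixed_grades)))
      stop("grades for fixed interior categories ",
           paste(interior, collapse = ", "),
           " must be supplied via `fixed_grades`", call. = FALSE)
    fixed[interior] <- as.numeric(fixed_grades[as.character(interior)])
    if (any(fixed[interior] < 0 | fixed[interior] > 100))
      stop("fixed grades must lie in [0, 100]", call. = FALSE)
  }

  g1 <- seq(0, 100, by = step)
  g2 <- seq(0, 100, by = step)
  ac <- arm_counts(table)
  pa <- ac$a / ac$n1
  pb <- ac$b / ac$n2
  d <- pa - pb                  # per-category proportion differences
  i <- free_levels[1L]
  j <- free_levels[2L]
  fixed0 <- ifelse(is.na(fixed), 0, fixed)

  # diff is affine in each free grade: base + d_i g_i + d_j g_j
  base <- sum(fixed0 * d)
  diff <- base + outer(d[i] * g1, d[j] * g2, `+`)

  # per-arm score variances: E[g^2] - mean^2, each affine in g^2 and g
  arm_stats <- function(pk, n) {
    m <- sum(fixed0 * pk) + outer(pk[i] * g1, pk[j] * g2, `+`)
    e2 <- sum(fixed0^2 * pk) + outer(pk[i] * g1^2, pk[j] * g2^2, `+`)
    (e2 - m^2) / (n - 1)  # variance of the arm mean, n-1 divisor
  }
  vm <- arm_stats(pa, ac$n1) + arm_stats(pb, ac$n2)
  se <- sqrt(pmax(vm, 0))
  zmat <- ifelse(se > 0, diff / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(zmat)), 1)

  favored <- matrix("indeterminate", nrow = length(g1), ncol = length(g2))
  favored[p < alpha & diff > 0] <- "experimental"
  favored[p < alpha & diff < 0] <- "control"

  key_sorted <- function(gi, gj) {
    grades <- fixed
    grades[i] <- gi
    grades[j] <- gj
    !is.unsorted(-grades)
  }
  monotone <- outer(g1, g2, Vectorize(key_sorted))

  structure(list(g1 = g1, g2 = g2, free_levels = free_levels, diff = diff,
                 p = p, favored = favored, monotone = monotone,
                 alpha = alpha, fixed = fixed, table = table),
            class = "grade_grid")
}

#' @export
print.grade_grid <- function(x, ...) {
  cat("Grading-key grid over categories ", x$free_levels[1L], " and ",
      x$free_levels[2L], ": ", length(x$g1), " x ", length(x$g2),
      " keys\n", sep = "")
  tab <- table(factor(x$favored,
                      levels = c("experimental", "control", "indeterminate")))
  cat(sprintf("  favored at alpha = %.3g: experimental %d, control %d, indeterminate %d\n",
              x$alpha, tab[[1L]], tab[[2L]], tab[[3L]]))
  invisible(x)
}

#' Convert a grading-key grid to a long data frame
#'
#' @param x A [grade_grid()].
#' @param row.names,optional Unused, for generic consistency.
#' @param ... Unused.
#' @return Long-format data frame with columns `g1`, `g2` (grades of the
#'   two free categories), `diff`, `p`, `favored`, `monotone`.
#' @export
as.data.frame.grade_grid <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(g1 = rep(x$g1, times = length(x$g2)),
             g2 = rep(x$g2, each = length(x$g1)),
             diff = as.vector(x$diff), p = as.vector(x$p),
             favored = as.vector(x$favored),
             monotone = as.vector(x$monotone), stringsAsFactors = FALSE)
}

#' Extract the tipping boundary of a grading-key grid
#'
#' The tipping boundary separates grading keys that favor one therapy from
#' keys favoring the other (or from indeterminate keys): it is the set of
#' grid-cell edges between adjacent cells whose favored status differs,
#' reported as segments in grade coordinates (midpoints between adjacent
#' grid values), ordered by location.
#'
#' @param grid A [grade_grid()].
#' @return Data frame with one row per boundary edge: `x0`, `y0`, `x1`,
#'   `y1` (segment endpoints on the grade scale of the two free
#'   categories), and `from`, `to` (favored status on either side). Zero
#'   rows when a single status covers the grid.
#' @export
tipping_boundary <- function(grid) {
  f <- grid$favored
  g1 <- grid$g1
  g2 <- grid$g2
  n1 <- length(g1)
  n2 <- length(g2)
  half1 <- diff(g1) / 2
  half2 <- diff(g2) / 2
  segs <- list()
  # vertical edges between horizontally adjacent cells (along g1 axis)
  if (n1 > 1) {
    chg <- which(f[-n1, , drop = FALSE] != f[-1L, , drop = FALSE],
                 arr.ind = TRUE)
    if (nrow(chg)) {
      xm <- g1[chg[, 1L]] + half1[chg[, 1L]]
      yl <- g2[chg[, 2L]] - c(half2, half2[n2 - 1L])[pmax(chg[, 2L] - 1L, 1L)]
      yh <- g2[chg[, 2L]] + c(half2, half2[n2 - 1L])[pmin(chg[, 2L], n2 - 1L)]
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = xm, y0 = yl, x1 = xm, y1 = yh,
        from = f[cbind(chg[, 1L], chg[, 2L])],
        to = f[cbind(chg[, 1L] + 1L, chg[, 2L])], stringsAsFactors = FALSE)
    }
  }
  # horizontal edges between vertically adjacent cells (along g2 axis)
  if (n2 > 1) {
    chg <- which(f[, -n2, drop = FALSE] != f[, -1L, drop = FALSE],
                 arr.ind = TRUE)
    if (nrow(chg)) {
      ym <- g2[chg[, 2L]] + half2[chg[, 2L]]
      xl <- g1[chg[, 1L]] - c(half1, half1[n1 - 1L])[pmax(chg[, 1L] - 1L, 1L)]
      xh <- g1[chg[, 1L]] + c(half1, half1[n1 - 1L])[pmin(chg[, 1L], n1 - 1L)]
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = xl, y0 = ym, x1 = xh, y1 = ym,
        from = f[cbind(chg[, 1L], chg[, 2L])],
        to = f[cbind(chg[, 1L], chg[, 2L] + 1L)], stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  out[order(out$x0, out$y0), , drop = FALSE]
}

#' Plot a grading-key grid as a contour/region map
#'
#' Shades cells by favored arm (experimental, control, or indeterminate),
#' overlays contours of the mean-grade difference, and draws the tipping
#' boundary.
#'
#' @param x A [grade_grid()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.grade_grid <- function(x, ...) {
  zcode <- matrix(match(x$favored, c("control", "indeterminate",
                                     "experimental")),
                  nrow = length(x$g1))
  graphics::image(x$g1, x$g2, zcode, zlim = c(1, 3),
                  col = c("#d95f5f", "#f2f2f2", "#66b266"),
                  xlab = paste("Grade of category", x$free_levels[1L]),
                  ylab = paste("Grade of category", x$free_levels[2L]), ...)
  graphics::contour(x$g1, x$g2, x$diff, add = TRUE, col = "grey30",
                    lwd = 0.8)
  tb <- tipping_boundary(x)
  if (nrow(tb))
    graphics::segments(tb$x0, tb$y0, tb$x1, tb$y1, lwd = 2)
  invisible(x)
}
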