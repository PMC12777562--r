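test_that("the analysis bundle assembles every table with correct values", {
  rep <- door_analyze(dori_table(), components = dori_components(),
                      keys = list(even = c(100, 75, 50, 25, 0)))
  overall <- rep$forest[rep$forest$type == "overall", ]
  expect_equal(round(100 * overall$estimate, 1), 51.0)
  expect_equal(round(100 * c(overall$ci_low, overall$ci_high), 1),
               c(47.6, 54.3))
  expect_equal(round(overall$p_value, 2), 0.58)
  expect_equal(unname(rep$gain_loss$per_category), c(27, -48, 19, 0, 3))
  expect_equal(unname(rep$component_gain_loss), c(-86, 48, 29, 3))
  expect_equal(rep$partial_credit$even$estimate, 0, tolerance = 1e-12)

  # without keys, rank-based outputs only
  rep2 <- door_analyze(dori_table())
  expect_null(rep2$partial_credit)
  expect_null(rep2$component_gain_loss)
})

test_that("report bundles write deterministic CSV/JSON twins", {
  rep <- door_analyze(dori_table(), keys = list(even = c(100, 75, 50, 25, 0)))
  d1 <- file.path(tempdir(), "door_rep1")
  d2 <- file.path(tempdir(), "door_rep2")
  write_door_report(rep, d1, figures = FALSE)
  write_door_report(rep, d2, figures = FALSE)
  for (f in c("distribution.csv", "gain_loss.csv", "forest.csv",
              "partial_credit.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  fr <- utils::read.csv(file.path(d1, "forest.csv"))
  expect_equal(nrow(fr), 5)  # overall + 4 cumulative rows

  grid <- grade_grid(dori_table(), free_levels = c(2, 3),
                     fixed_grades = c("4" = 10), step = 10)
  gdir <- file.path(tempdir(), "door_grid")
  write_grade_grid(grid, gdir, figures = FALSE)
  gg <- utils::read.csv(file.path(gdir, "grade_grid.csv"))
  expect_equal(nrow(gg), 11 * 11)
  unlink(c(d1, d2, gdir), recursive = TRUE)
})

test_that("figures are emitted alongside their data", {
  rep <- door_analyze(dori_table())
  d <- file.path(tempdir(), "door_figs")
  write_door_report(rep, d, figures = TRUE)
  expect_true(file.exists(file.path(d, "forest.png")))
  expect_true(file.exists(file.path(d, "forest.svg")))
  unlink(d, recursive = TRUE)
})

cli_path <- function() system.file("cli", "door.R", package = "doorstats")

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status"), output = out)
}

test_that("the CLI analyzes a count table end to end", {
  counts <- file.path(tempdir(), "counts.csv")
  utils::write.csv(data.frame(arm = c("E", "C"), g1 = c(263, 253),
                              g2 = c(93, 111), g3 = c(16, 9), g4 = c(1, 1),
                              g5 = c(1, 0)), counts, row.names = FALSE)
  outdir <- file.path(tempdir(), "cli_out")
  res <- run_cli(c("analyze", "--table", counts, "--experimental", "E",
                   "--no-figures", "--out", outdir))
  expect_true(is.null(res$status) || res$status == 0)
  expect_true(file.exists(file.path(outdir, "forest.csv")))
  fr <- utils::read.csv(file.path(outdir, "forest.csv"))
  expect_equal(round(100 * fr$estimate[1], 1), 51.0)

  # missing input exits nonzero without partial outputs
  res_bad <- run_cli(c("analyze", "--table", "/nonexistent.csv",
                       "--out", file.path(tempdir(), "cli_bad")))
  expect_false(is.null(res_bad$status) || res_bad$status == 0)
  expect_false(file.exists(file.path(tempdir(), "cli_bad", "forest.csv")))
  unlink(c(counts, outdir), recursive = TRUE)
})

test_that("the CLI power subcommand echoes seeded, reproducible JSON", {
  scenario <- file.path(tempdir(), "scenario.json")
  jsonlite::write_json(list(probs_exp = c(0.7, 0.3), probs_ctl = c(0.5, 0.5),
                            n_per_arm = 60, n_sims = 200, seed = 9),
                       scenario, auto_unbox = TRUE)
  out1 <- file.path(tempdir(), "power1.json")
  out2 <- file.path(tempdir(), "power2.json")
  r1 <- run_cli(c("power", "--scenario", scenario, "--out", out1))
  r2 <- run_cli(c("power", "--scenario", scenario, "--out", out2))
  expect_true(is.null(r1$status) || r1$status == 0)
  expect_identical(readLines(out1), readLines(out2))
  res <- jsonlite::read_json(out1)
  expect_equal(res$seed, 9)
  expect_true(res$power > 0 && res$power <= 1)
  unlink(c(scenario, out1, out2))
})
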