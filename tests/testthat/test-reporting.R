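test_that("study configurations round-trip through flat key:value files", {
  cfg <- study_config(master_seed = 17, replicates = 10, n = 250,
                      rates = c(0.3, 0.5), inappropriate_rates = 0.5,
                      scenarios = c("mcar", "mar"), b_pred = 0.15,
                      include_negative = FALSE)
  path <- withr::local_tempfile(fileext = ".yml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(unclass(back), unclass(cfg))
  # unknown keys are rejected
  writeLines(c("master_seed: 1", "bogus_key: 2"), path)
  expect_error(read_study_config(path), "unknown config keys")
})

test_that("results round-trip through delimited text", {
  res <- run_study(study_config(master_seed = 4, replicates = 2, n = 100,
                                rates = 0.5, scenarios = "mcar",
                                include_negative = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study_results(res, path)
  back <- read_study_results(path)
  expect_equal(back$mean_b, res$mean_b, tolerance = 1e-12)
  expect_identical(back$scenario, res$scenario)

  cov_path <- withr::local_tempfile(fileext = ".tsv")
  write_implied_covariance(implied_covariance(population_spec("transient")),
                           cov_path)
  m <- read.delim(cov_path)
  expect_identical(m$variable, c("predictor", "h1", "h2", "liability"))
  expect_equal(m$h1[1], 0.16, tolerance = 1e-12)
})

test_that("rendered tables mirror the published layout", {
  res <- run_study(study_config(master_seed = 9, replicates = 3, n = 150))
  t1 <- render_study_table(res, 1)
  expect_match(t1[1], "Appropriate MR")
  expect_true(any(grepl("50% attrition rate:", t1)))
  expect_true(any(grepl("70% attrition rate:", t1)))
  expect_true(any(grepl("mnar-strong", t1)))
  # change-score tables carry the Diff column, MR tables do not
  t2 <- render_study_table(res, 2)
  expect_true(any(grepl("Diff", t2)))
  expect_false(any(grepl("Diff", render_study_table(res, 3))))
  # formatted coefficient matches the cell summary at two decimals
  cell <- res[res$cause_type == "enduring" & res$method == "mr" &
                res$sign == "positive" & res$rate == 0.5 &
                res$scenario == "mcar", ]
  expect_true(any(grepl(formatC(cell$mean_b, format = "f", digits = 2),
                        render_study_table(res, 3), fixed = TRUE)))
  expect_error(render_study_table(res[res$rate == 0.3, ], 1), "no cells")
  # negative-variant tables read from the sign-tagged cells
  expect_match(render_study_table(res, 5)[1], "negative variant")
})

test_that("the CLI runs the study end to end, reproducibly", {
  out1 <- file.path(withr::local_tempdir(), "run1")
  status <- cli_run(c("run-study", "--reps", "3", "--n", "150",
                      "--seed", "11", "--out", out1))
  expect_identical(status, 0L)
  files <- file.path(out1, c("cell_summaries.tsv", "config.yml",
                             "tables.txt", "manifest.yml"))
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
  manifest <- yaml::read_yaml(files[4])
  expect_identical(manifest$config$master_seed, 11L)
  expect_true(all(file.exists(unlist(manifest$outputs))))

  # round trip: the echoed config reproduces byte-identical machine output
  out2 <- file.path(withr::local_tempdir(), "run2")
  cli_run(c("run-study", "--config", files[2], "--out", out2))
  expect_identical(readLines(file.path(out2, "cell_summaries.tsv")),
                   readLines(files[1]))

  # flags override the config file
  out3 <- file.path(withr::local_tempdir(), "run3")
  cli_run(c("run-study", "--config", files[2], "--reps", "2",
            "--out", out3))
  res3 <- read_study_results(file.path(out3, "cell_summaries.tsv"))
  expect_true(all(res3$reps == 2))
})

test_that("the run-cell and estimands subcommands work", {
  out <- withr::local_tempdir()
  status <- cli_run(c("run-cell", "--scenario", "transient-mcar",
                      "--method", "mr", "--rate", "0.5", "--reps", "4",
                      "--n", "120", "--seed", "3", "--out", out))
  expect_identical(status, 0L)
  cell <- read_study_results(file.path(out, "cell_summary.tsv"))
  expect_equal(nrow(cell), 1)
  expect_identical(cell$cause_type, "transient")
  expect_identical(cell$scenario, "mcar")

  cli_run(c("estimands", "--rates", "0,0.5", "--out", out))
  grid <- read.delim(file.path(out, "estimands.tsv"))
  expect_true(all(
    abs(grid$estimand[grid$equals_true_effect] -
          grid$true_effect[grid$equals_true_effect]) < 1e-12))
  expect_true(all(grid$appropriate[grid$equals_true_effect]))

  expect_error(cli_run("no-such-command"), "unknown subcommand")
})

test_that("dump-samples writes replicate files", {
  out <- withr::local_tempdir()
  status <- cli_run(c("dump-samples", "--cause", "enduring", "--scenario",
                      "mar", "--rate", "0.5", "--reps", "2", "--n", "80",
                      "--seed", "5", "--out", out))
  expect_identical(status, 0L)
  files <- list.files(out, pattern = "^replicate_.*tsv$", full.names = TRUE)
  expect_length(files, 2)
  d <- read.delim(files[1])
  expect_identical(names(d), c("replicate", "seed", "predictor", "h1", "h2",
                               "liability", "retained"))
  expect_equal(sum(d$retained), 40)
})
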