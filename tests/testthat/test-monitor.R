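# Monitoring pipeline and the command-line commands.

test_that("a frozen series (S_t = S_0) yields zero estimates and no alerts", {
  comp <- fixtureCompModel()
  reg <- fixtureRegressor()$model
  s <- composeSpectrum(mixtureState(cNH2Cl = 2, cDOC = 2.4), label = "t0")
  res <- monitorSeries(list(s, s, s), comp, reg)
  expect_equal(res$delta245_AU, c(0, 0))
  expect_true(all(res$nox_rel_mgN_L < 0.01))
  expect_false(any(res$alert))
})

test_that("decay-only monitoring stays below threshold; nitrification alerts fire", {
  comp <- fixtureCompModel()
  reg <- fixtureRegressor()$model
  mon0 <- monitorSeries(simulateDecaySeries(decayOnlyScenario())$spectra,
                        comp, reg)
  expect_true(all(mon0$nox_rel_mgN_L < 0.05))
  expect_false(any(mon0$alert))

  sim <- simulateDecaySeries(nitrifyingScenario())
  truth <- groundTruthFrame(sim$states, sim$times)$nox_mgN_L[-1]
  mon <- monitorSeries(sim$spectra, comp, reg)
  expect_lte(max(abs(mon$nox_rel_mgN_L - truth)), 0.01)
  # alert raised exactly from the first timestamp where truth >= 0.05
  expect_equal(mon$alert, truth >= 0.05)
  # relative NOx is non-decreasing after onset on clean data
  expect_true(all(diff(mon$nox_rel_mgN_L) > -1e-9))
  expect_error(monitorSeries(sim$spectra[1], comp, reg), "baseline")
})

test_that("cmdSimulate writes deterministic series and truth files", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(scenario = "nitrifying", noise_sd = 0.001, seed = 11,
              name = "nit")
  cmdSimulate(c(cfg, list(out_dir = out1)))
  cmdSimulate(c(cfg, list(out_dir = out2)))
  f1 <- file.path(out1, "nit_series.csv")
  expect_true(file.exists(f1))
  expect_true(file.exists(file.path(out1, "nit_truth.csv")))
  expect_identical(readLines(f1), readLines(file.path(out2, "nit_series.csv")))
  # summary embeds seed and config hash
  smry <- jsonlite::read_json(file.path(out1, "simulate_summary.json"))
  expect_equal(smry$seed, 11)
  expect_match(smry$config_hash, "^[0-9a-f]{8}$")
  expect_error(cmdSimulate(list(out_dir = out1)), "scenario")
})

test_that("six-sample preset writes six series with distinct dynamics", {
  out <- withr::local_tempdir()
  files <- cmdSimulate(list(scenario = "six_samples", seed = 1,
                            out_dir = out))
  expect_length(files, 6L)
  expect_true(all(file.exists(files)))
  truths <- lapply(sprintf("%s/sample%d_truth.csv", out, 1:6), utils::read.csv)
  finals <- vapply(truths, function(t) t$nox_mgN_L[nrow(t)], numeric(1))
  expect_equal(finals[2], 0)            # filtered: no conversion
  expect_gt(finals[6], max(finals[1:5]))  # enhanced low-residual nitrifies most
})

test_that("cmdCalibrate persists a 90-wavelength model and errors out cleanly", {
  out <- withr::local_tempdir()
  model <- cmdCalibrate(list(seed = 1, noise_sd = 0.001, out_dir = out))
  expect_length(model@wavelengthsNm, 90L)
  diag <- utils::read.csv(file.path(out, "compensation_diagnostics.csv"))
  expect_equal(nrow(diag), 90L)
  expect_true(file.exists(file.path(out, "compensation_model.json")))
  # byte-identical rerun
  out2 <- withr::local_tempdir()
  cmdCalibrate(list(seed = 1, noise_sd = 0.001, out_dir = out2))
  expect_identical(readLines(file.path(out, "compensation_model.json")),
                   readLines(file.path(out2, "compensation_model.json")))
  # two spectra are not a calibration
  expect_error(cmdCalibrate(list(levels = c(1, 2), noise_sd = 0,
                                 out_dir = out)),
               "insufficient")
})

test_that("cmdTrain reports 10 folds and reruns identically", {
  out <- withr::local_tempdir()
  cfg <- list(seed = 3, noise_sd = 0.001, out_dir = out,
              nitrite_levels = c(0, 0.1, 0.4, 0.9),
              nitrate_levels = c(0, 0.2, 0.6, 1.1),
              c_grid = c(10, 1000), gamma_grid = c(0.001, 0.1))
  res <- cmdTrain(cfg)
  expect_equal(res$report@folds, 10L)
  smry <- jsonlite::read_json(file.path(out, "train_summary.json"))
  expect_equal(smry$folds, 10L)
  res2 <- cmdTrain(cfg)
  expect_identical(res$model@cost, res2$model@cost)
  expect_identical(res$model@gamma, res2$model@gamma)
  expect_true(file.exists(file.path(out, "nox_model.json")))
  expect_true(file.exists(file.path(out, "cv_trace.csv")))
  expect_error(cmdTrain(list(training_csv = file.path(out, "missing.csv"))),
               "not found")
})

test_that("cmdMonitor runs the full pipeline from persisted artifacts", {
  out <- withr::local_tempdir()
  cmdSimulate(list(scenario = "nitrifying", noise_sd = 0, seed = 1,
                   name = "nit", out_dir = out))
  cmdCalibrate(list(seed = 1, noise_sd = 0, out_dir = out))
  cmdTrain(list(seed = 1, noise_sd = 0, out_dir = out,
                c_grid = c(10, 1000), gamma_grid = c(0.001, 0.1)))
  res <- cmdMonitor(list(series_csv = file.path(out, "nit_series.csv"),
                         compensation_model = file.path(out, "compensation_model.json"),
                         nox_model = file.path(out, "nox_model.json"),
                         out_dir = out, seed = 1))
  truth <- utils::read.csv(file.path(out, "nit_truth.csv"))$nox_mgN_L[-1]
  expect_lte(max(abs(res$nox_rel_mgN_L - truth)), 0.01)
  mcsv <- utils::read.csv(file.path(out, "monitoring.csv"))
  expect_named(mcsv, c("timestamp", "delta245_AU", "nox_rel_mgN_L",
                       "nox_cal_mgN_L", "extrapolated", "alert"))
  smry <- jsonlite::read_json(file.path(out, "monitor_summary.json"))
  expect_equal(smry$threshold_mgN_L, 0.05)
  expect_gt(smry$n_alerts, 0)
  expect_error(cmdMonitor(list(series_csv = file.path(out, "nit_series.csv"))),
               "compensation_model")
})

test_that("cmdMonitor applies local calibration when lab data are supplied", {
  out <- withr::local_tempdir()
  cmdSimulate(list(scenario = "nitrifying", noise_sd = 0, seed = 1,
                   name = "nit", out_dir = out))
  cmdCalibrate(list(seed = 1, noise_sd = 0, out_dir = out))
  cmdTrain(list(seed = 1, noise_sd = 0, out_dir = out,
                c_grid = c(10, 1000), gamma_grid = c(0.001, 0.1)))
  base <- list(series_csv = file.path(out, "nit_series.csv"),
               compensation_model = file.path(out, "compensation_model.json"),
               nox_model = file.path(out, "nox_model.json"), out_dir = out)
  raw <- cmdMonitor(base)
  lab <- data.frame(timestamp = raw$timestamp[c(2, 4, 6, 8)],
                    lab_mgN_L = 1.2 * raw$nox_rel_mgN_L[c(2, 4, 6, 8)] + 0.02)
  labcsv <- file.path(out, "lab.csv")
  utils::write.csv(lab, labcsv, row.names = FALSE)
  cal <- cmdMonitor(c(base, list(lab_csv = labcsv)))
  expect_equal(cal$nox_cal_mgN_L, 1.2 * cal$nox_rel_mgN_L + 0.02,
               tolerance = 1e-9)
  smry <- jsonlite::read_json(file.path(out, "monitor_summary.json"))
  expect_equal(smry$local_calibration$slope, 1.2, tolerance = 1e-6)
})

test_that("runCli maps error classes to distinct exit codes", {
  out <- withr::local_tempdir()
  cfgPath <- file.path(out, "cfg.json")
  jsonlite::write_json(list(scenario = "nitrifying", name = "x",
                            out_dir = out, noise_sd = 0),
                       cfgPath, auto_unbox = TRUE)
  expect_equal(suppressMessages(runCli(c("simulate", "--config", cfgPath,
                                         "--seed", "4"))), 0L)
  expect_true(file.exists(file.path(out, "x_series.csv")))
  expect_equal(suppressMessages(runCli(character(0))), 2L)
  expect_equal(suppressMessages(runCli(c("frobnicate", "--config", cfgPath))),
               2L)
  expect_equal(suppressMessages(runCli(c("monitor", "--config", cfgPath))), 2L)
  # validation failure: 2-spectrum calibration series
  calCfg <- file.path(out, "cal.json")
  jsonlite::write_json(list(levels = c(1, 2), noise_sd = 0, out_dir = out),
                       calCfg, auto_unbox = TRUE)
  expect_equal(suppressMessages(runCli(c("calibrate", "--config", calCfg))),
               3L)
})

test_that("config hash is stable and sensitive", {
  cfg <- list(scenario = "nitrifying", seed = 1)
  expect_identical(configHash(cfg), configHash(cfg))
  expect_false(identical(configHash(cfg),
                         configHash(list(scenario = "nitrifying", seed = 2))))
})
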