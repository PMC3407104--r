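test_that("study design validates its fields", {
  expect_error(study_design(main_times = c(9, 6)), "increasing")
  expect_error(study_design(main_times = c(0, 6)), "> 0")
  expect_error(study_design(responses = character(0)), "non-empty")
  expect_error(study_design(responses = "banana"), "unknown response")
  expect_error(study_design(omega = -0.1), "omega")
  expect_error(study_design(n_main = 0), ">= 1")
})

test_that("record counts follow the design combinatorics", {
  # 3 responses x 5 timepoints x 6 animals = 90 organ/serum records,
  # plus 3 early serum timepoints x 3 animals = 9; total 99
  des <- study_design(n_main = 6,
                      responses = c("protein_liver", "protein_serum",
                                    "protein_brain"),
                      omega = 0)
  ds <- generate_study(des, reference_model_config("IFNGFP"), seed = 1)
  expect_identical(nrow(ds), 99L)
  expect_identical(sum(ds$response == "protein_serum"), 5L * 6L + 9L)
  # early serum records come from a separate (third) experiment
  expect_setequal(unique(ds$experiment[ds$time %in% c(1, 3, 7)]), 3L)
  # destructive sampling: an animal appears only at one timepoint
  stopifnot(all(tapply(ds$time, ds$animal, function(x) length(unique(x))) == 1))
})

test_that("zero noise reproduces the model predictions exactly", {
  des <- study_design(n_main = 2, responses = c("protein_serum", "ISG15_liver"),
                      omega = 0)
  cfg <- reference_model_config("IFNGFP")
  ds <- generate_study(des, cfg, seed = 3)
  traj <- simulate_system(cfg$params$IFNGFP,
                          isg = cfg$isg$IFNGFP["ISG15_liver"],
                          times = c(0, 1, 3, 6, 7, 9, 13, 24, 48),
                          method = "matexp")
  for (i in seq_len(nrow(ds))) {
    comp <- if (ds$response[i] == "protein_serum") "serum_protein" else "ISG15_liver"
    expect_equal(ds$value[i], trajectory_values(traj, comp, ds$time[i]),
                 tolerance = 1e-10)
  }
})

test_that("generation is seed-deterministic", {
  des <- study_design(n_main = c(6, 8), omega = 0.2)
  cfg <- reference_model_config()
  a <- generate_study(des, cfg, seed = 42)
  b <- generate_study(des, cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_study(des, cfg, seed = 43)
  expect_false(identical(a$value, c$value))
  # animals per point drawn from the 6-8 range
  counts <- with(subset(as.data.frame(a), response == "protein_liver" &
                          molecule == "IFNGFP"), tapply(value, time, length))
  expect_true(all(counts >= 6 & counts <= 8))
})

test_that("empirical noise CV converges to omega", {
  des <- study_design(main_times = 6, n_main = 10000,
                      early_serum_times = numeric(0),
                      responses = "protein_liver", omega = 0.2)
  ds <- generate_study(des, reference_model_config("IFNGFP"), seed = 9)
  cv <- sd(ds$value) / mean(ds$value)
  expect_equal(cv, 0.2, tolerance = 0.05 * 0.2 / 0.2)  # within 5% of omega
})

test_that("optional experiment-level and animal-level factors engage", {
  des0 <- study_design(n_main = 4, responses = "protein_liver", omega = 0,
                       early_serum_times = numeric(0))
  des1 <- study_design(n_main = 4, responses = "protein_liver", omega = 0,
                       early_serum_times = numeric(0),
                       experiment_scale_sd = 0.3)
  cfg <- reference_model_config("IFNGFP")
  d0 <- generate_study(des0, cfg, seed = 5)
  d1 <- generate_study(des1, cfg, seed = 5)
  # the scale factor is shared within an experiment
  ratio <- d1$value / d0$value
  expect_true(all(abs(tapply(ratio, d1$experiment, sd) < 1e-12)))
  expect_gt(length(unique(round(ratio, 10))), 1L)
})

test_that("recovery experiment aggregates estimates and rejects bad input", {
  expect_error(recovery_experiment(reference_model_config(),
                                   study_design(), n_replicates = 0),
               "n_replicates")
  cfg <- reference_model_config("IFNGFP")
  des <- study_design(responses = "mRNA_liver", omega = 0,
                      early_serum_times = numeric(0))
  rec <- recovery_experiment(cfg, des, n_replicates = 1, seed = 2,
                             stages = "transcription",
                             control = fit_control(n_starts = 1,
                                                   compute_se = FALSE))
  expect_identical(rec$n_failures, 0L)
  expect_true(all(rec$summary$median_rel_error < 0.01))
  expect_setequal(rec$summary$parameter,
                  paste0("transcription.",
                         c("k_NUNC", "k_INT", "k_S1", "k_S2", "k_DEG")))
})
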