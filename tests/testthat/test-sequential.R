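# Sequential workflow behaviour. Fits here run at reduced noise/size to keep
# the suite quick; the statistical recovery checks live in the acceptance
# tests.

test_that("stages must form a prefix of the ordered workflow", {
  cfg <- reference_model_config("IFNGFP")
  ds <- generate_study(study_design(n_main = 3, omega = 0.1), cfg, seed = 1)
  expect_error(sequential_fit(ds, cfg, stages = "brain"), "prefix")
  expect_error(sequential_fit(ds, cfg, stages = c("transcription", "brain")),
               "prefix")
})

test_that("stage specs validate their structure", {
  expect_error(stage_spec("protein"), "molecule")
  expect_error(stage_spec("isg", gene = "ISG15"), "organ")
  expect_error(stage_spec("transcription", free = "k_NUNC",
                          fixed = list(k_NUNC = 1)), "disjoint")
})

test_that("a stage failure raises a structured error with completed fits", {
  cfg <- reference_model_config("IFNGFP")
  des <- study_design(n_main = 3, omega = 0.1, responses = "mRNA_liver",
                      early_serum_times = numeric(0))
  ds <- generate_study(des, cfg, seed = 1)
  err <- tryCatch(
    sequential_fit(ds, cfg, stages = c("transcription", "protein"),
                   control = fit_control(n_starts = 1, compute_se = FALSE)),
    ifn_stage_error = function(e) e)
  expect_s3_class(err, "ifn_stage_error")
  expect_identical(err$stage, "protein.IFNGFP")
  expect_true("transcription" %in% names(err$completed))
})

test_that("the optimum never exceeds the starting objective", {
  cfg <- reference_model_config("IFNGFP")
  des <- study_design(n_main = 4, omega = 0.2,
                      responses = c("protein_liver", "protein_serum"))
  ds <- generate_study(des, cfg, seed = 6)
  ctrl <- fit_control(n_starts = 1, compute_se = FALSE)
  f <- fit_stage(ds, cfg, stage_spec("protein", molecule = "IFNGFP"),
                 seed = 6, control = ctrl)
  f0 <- fit_stage(ds, cfg, stage_spec("protein", molecule = "IFNGFP"),
                  seed = 6, control = fit_control(n_starts = 1, maxit_nm = 0,
                                                  polish = FALSE,
                                                  compute_se = FALSE))
  expect_lte(f$mvof, f0$mvof)
})

test_that("sequential fit wires the four stages and updates the config", {
  cfg <- reference_model_config("IFNGFP")
  des <- study_design(n_main = 3, omega = 0.05,
                      responses = c("mRNA_liver", "protein_liver",
                                    "protein_serum", "protein_brain",
                                    "ISG15_liver"))
  ds <- generate_study(des, cfg, seed = 7)
  res <- sequential_fit(ds, cfg, seed = 7,
                        control = fit_control(n_starts = 1,
                                              compute_se = FALSE))
  expect_setequal(names(res$fits),
                  c("transcription", "protein.IFNGFP", "brain.IFNGFP",
                    "isg.ISG15.liver"))
  # fitted estimates are written back into the configuration
  expect_equal(res$config$params$IFNGFP$protein$k_S,
               unname(res$fits$protein.IFNGFP$estimates["k_S"]))
  expect_equal(res$config$isg$IFNGFP$ISG15_liver$IFN_50,
               unname(res$fits$isg.ISG15.liver$estimates["IFN_50"]))
  # per-response residual variances accompany each stage
  expect_setequal(names(res$fits$protein.IFNGFP$omega2),
                  c("protein_liver", "protein_serum"))
})

test_that("model discrimination report compares delay against no delay", {
  cfg <- reference_model_config("IFNGFP")
  des <- study_design(n_main = 4, omega = 0.15,
                      responses = c("mRNA_liver", "protein_liver",
                                    "protein_serum"))
  ds <- generate_study(des, cfg, seed = 9)
  res <- fit_with_selection(ds, cfg, seed = 9,
                            control = fit_control(n_starts = 1,
                                                  compute_se = FALSE))
  expect_s3_class(res, "ifn_selection_report")
  cmp <- res$comparisons$delay.IFNGFP
  expect_identical(cmp$candidates, c("no_delay", "transit_delay"))
  # data were generated with a 3-compartment delay: the delay model wins
  expect_identical(cmp$selected, "transit_delay")
  expect_gt(cmp$dMVOF, lrt_threshold(0.05, 1))
})
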