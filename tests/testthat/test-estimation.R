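test_that("observation tables are validated and non-positive values dropped", {
  expect_error(as_ifn_dataset(data.frame(molecule = "x")), "missing column")
  base <- data.frame(molecule = "IFNGFP", response = "mRNA_liver",
                     time = c(6, 9), value = c(1, 2), experiment = 1,
                     animal = 1:2)
  expect_s3_class(as_ifn_dataset(base), "ifn_dataset")
  expect_error(as_ifn_dataset(transform(base, response = "mystery")),
               "unknown response")
  expect_error(as_ifn_dataset(rbind(base, base)), "duplicated")
  withpos <- rbind(base, data.frame(molecule = "IFNGFP",
                                    response = "mRNA_liver", time = 13,
                                    value = -1, experiment = 1, animal = 3))
  expect_message(d <- as_ifn_dataset(withpos), "non-positive")
  expect_identical(nrow(d), 2L)
  expect_identical(attr(d, "n_dropped_nonpositive"), 1L)
})

test_that("proportional-error objective matches its definition", {
  d <- make_obs("IFNGFP", "mRNA_liver", c(6, 9, 13), c(2, 3, 4))
  # perfect fit: both the log-variance and residual terms vanish at omega2=1
  expect_identical(neg2ll(d, c(2, 3, 4), omega2 = 1), 0)
  # single e-fold residual with unit variance contributes exactly 1
  d1 <- make_obs("IFNGFP", "mRNA_liver", 6, exp(1) * 5)
  expect_equal(neg2ll(d1, 5, omega2 = 1), 1, tolerance = 1e-12)
  # inflating any one residual strictly increases the objective
  v0 <- neg2ll(d, c(2, 3, 4.2), omega2 = 0.04)
  v1 <- neg2ll(d, c(2, 3, 4.5), omega2 = 0.04)
  expect_gt(v1, v0)
  # non-positive predictions yield +Inf with diagnostics, not NaN
  v <- neg2ll(d, c(2, -1, 4), omega2 = 1)
  expect_identical(as.numeric(v), Inf)
  expect_identical(attr(v, "diagnostics")$row, 2L)
  expect_error(neg2ll(d, c(2, 3, 4), omega2 = c(protein_serum = 1)),
               "mRNA_liver")
})

test_that("objective equals an independent Gaussian log-density oracle", {
  set.seed(11)
  n <- 40
  resp <- sample(c("mRNA_liver", "protein_serum"), n, replace = TRUE)
  pred <- exp(rnorm(n, 2, 1))
  obs <- pred * exp(rnorm(n, 0, 0.3))
  d <- as_ifn_dataset(data.frame(molecule = "IFNGFP", response = resp,
                                 time = seq_len(n), value = obs,
                                 experiment = 1, animal = seq_len(n)))
  omega2 <- c(mRNA_liver = 0.09, protein_serum = 0.25)
  ll <- sum(dnorm(log(d$value), log(pred),
                  sqrt(omega2[d$response]), log = TRUE))
  expect_equal(neg2ll(d, pred, omega2), -2 * ll - n * log(2 * pi),
               tolerance = 1e-10)
})

test_that("log-residuals are invariant to a common response rescaling", {
  d <- make_obs("IFNGFP", "protein_serum", c(1, 3, 7), c(10, 40, 90))
  pred <- c(12, 38, 95)
  c_scale <- 1e3
  d2 <- d; d2$value <- d2$value * c_scale
  expect_equal(neg2ll(d, pred, 0.04), neg2ll(d2, pred * c_scale, 0.04),
               tolerance = 1e-10)
})

test_that("noise-free transcription data are recovered from a 2x start", {
  # dense sampling, so all five transcription parameters are identifiable
  cfg <- reference_model_config("IFNGFP")
  des <- study_design(main_times = c(0.25, 0.5, 1, 2, 4, 6, 9, 13, 24, 48),
                      n_main = 2, early_serum_times = numeric(0),
                      responses = "mRNA_liver", omega = 0)
  ds <- generate_study(des, cfg, seed = 2)
  truth <- unlist(unclass(cfg$params$IFNGFP$transcription))
  f <- fit_stage(ds, cfg, stage_spec("transcription"), start = truth * 2,
                 seed = 3, control = fit_control(n_starts = 3,
                                                 jitter_sd = 0.25))
  expect_lt(max(rel_err(f$estimates[names(truth)], truth)), 0.01)
  expect_identical(f$convergence, 0L)
  # starting at the generating truth, the optimizer stays put
  f0 <- fit_stage(ds, cfg, stage_spec("transcription"), seed = 3,
                  control = fit_control(n_starts = 1))
  expect_lt(max(rel_err(f0$estimates[names(truth)], truth)), 1e-3)
  expect_lte(f0$mvof, neg2ll(ds, ds$value, omega2 = 1) + 1e-8)
})

test_that("fitting a stage without its responses fails clearly", {
  cfg <- reference_model_config("IFNGFP")
  d <- make_obs("IFNGFP", "protein_serum", c(1, 3), c(10, 20))
  expect_error(fit_stage(d, cfg, stage_spec("transcription")),
               "mRNA_liver")
})

test_that("standard errors follow the curvature of the objective", {
  # quadratic toy objective (theta - 2)^2 / v has SE exactly sqrt(v)
  v <- 0.25
  toy <- structure(list(estimates = c(theta = 2),
                        objective = function(th) {
                          list(value = (th[["theta"]] - 2)^2 / v)
                        }),
                   class = "ifn_fit")
  se <- standard_errors(toy)
  expect_equal(unname(se$se["theta"]), sqrt(v), tolerance = 1e-6)
  expect_true(se$hessian_pd)
  expect_equal(unname(se$cv_pct["theta"]), 100 * sqrt(v) / 2,
               tolerance = 1e-6)
  # a flat (non-positive-definite) objective reports unavailable SEs
  flat <- structure(list(estimates = c(a = 1, b = 1),
                         objective = function(th) list(value = th[["a"]]^0)),
                    class = "ifn_fit")
  sf <- standard_errors(flat)
  expect_false(sf$hessian_pd)
  expect_true(all(is.na(sf$se)))
})

test_that("standard errors shrink with replication as 1/sqrt(n)", {
  cfg <- reference_model_config("IFNGFP")
  ses <- vapply(c(3, 12, 48), function(n_per) {
    des <- study_design(main_times = c(0.25, 0.5, 1, 2, 4, 6, 9, 13, 24, 48),
                        n_main = n_per, early_serum_times = numeric(0),
                        responses = "mRNA_liver", omega = 0.2)
    ds <- generate_study(des, cfg, seed = 101)
    f <- fit_stage(ds, cfg, stage_spec("transcription"), seed = 5,
                   control = fit_control(n_starts = 1))
    unname(f$se["k_INT"])
  }, numeric(1))
  # each 4-fold increase in animals should halve the SE (within 40%)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.4)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.4)
})
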