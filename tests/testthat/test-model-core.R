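gfp <- reference_kinetic_params("IFNGFP")
apo <- reference_kinetic_params("IFNGFPApo")

test_that("initial state places the dose in DNA and zeros the rest", {
  y <- initial_state(gfp)
  expect_identical(unname(y["DNA"]), 1)
  expect_true(all(y[setdiff(names(y), "DNA")] == 0))
  expect_identical(unname(initial_state(gfp, dose_scale = 2)["DNA"]), 2)
  expect_error(initial_state(gfp, dose_scale = 0), "dose_scale")
  y2 <- initial_state(gfp, isg = list(ISG15_liver = isg_params(1, 1, isg0 = 0.5)))
  expect_identical(unname(y2["ISG15_liver"]), 0.5)
})

test_that("transcription right-hand side matches hand evaluation", {
  st <- c(DNA = 1, DNAprime = 0, mRNA = 0)
  d <- transcription_rhs(st, gfp$transcription)
  expect_equal(unname(d["DNA"]), -1.712, tolerance = 1e-12)
  expect_equal(unname(d["DNAprime"]), 0.112, tolerance = 1e-12)
  expect_equal(unname(d["mRNA"]), 1080, tolerance = 1e-12)
  # linear homogeneous system: zero state has zero derivative
  expect_true(all(transcription_rhs(c(DNA = 0, DNAprime = 0, mRNA = 0),
                                    gfp$transcription) == 0))
})

test_that("protein right-hand side: transit feed, zero state, mass balance", {
  st <- c(mRNA = 1, T1 = 0, T2 = 0, T3 = 0, liver_protein = 0,
          serum_protein = 0)
  d <- protein_rhs(st, gfp$protein)
  expect_equal(unname(d["T1"]), 1.45)
  expect_equal(unname(d[c("T2", "T3")]), c(0, 0))
  expect_true(all(protein_rhs(st * 0, gfp$protein) == 0))
  # configuration errors: peripheral state and parameters must co-occur
  expect_error(protein_rhs(c(st, peripheral_protein = 0), gfp$protein),
               "peripheral")
  expect_error(protein_rhs(st, apo$protein), "peripheral")
  # mass balance: d(liver + serum + P)/dt = k_S*Tn - k_D*liver - k_sb*serum
  set.seed(42)
  for (i in 1:25) {
    s <- setNames(runif(7, 0, 100),
                  c("mRNA", "T1", "T2", "T3", "liver_protein",
                    "serum_protein", "peripheral_protein"))
    d <- protein_rhs(s, apo$protein)
    lhs <- sum(d[c("liver_protein", "serum_protein", "peripheral_protein")])
    rhs <- apo$protein$k_S * s[["T3"]] -
      apo$protein$k_D * s[["liver_protein"]] -
      apo$protein$k_sb * s[["serum_protein"]]
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("brain right-hand side and its steady state", {
  expect_identical(brain_rhs(0, 0, 1, 1), 0)
  expect_equal(brain_rhs(10, 1e6, 3.75e-5, 0.509), 37.5 - 5.09,
               tolerance = 1e-12)
  # constant serum driver: brain approaches (k_sb/k_E) * serum
  grid <- seq(0, 200, by = 0.05)
  b <- solve_driven_brain(grid, rep(1e5, length(grid)),
                          k_sb = 3.75e-5, k_E = 0.509, times = 200)
  expect_equal(b, 3.75e-5 / 0.509 * 1e5, tolerance = 1e-6)
})

test_that("ISG right-hand side: half-maximum, linear form, decay limit", {
  sat <- isg_params(k_S_ISG = 2, k_D_ISG = 0.5, IFN_50 = 151)
  d <- isg_rhs(0, driver = 151, sat)
  expect_equal(d, 2 / 2, tolerance = 1e-12)   # synthesis at half-maximum
  lin <- isg_params(k_S_ISG = 2.05e-3, k_D_ISG = 0.127)
  expect_equal(isg_rhs(1, driver = 100, lin), 0.205 - 0.127,
               tolerance = 1e-12)
  expect_equal(isg_rhs(3, driver = 0, lin), -0.127 * 3, tolerance = 1e-12)
  expect_error(isg_rhs(0, 1, lin, form = "saturable"), "IFN_50")
})

test_that("near-zero DNA conversion reduces mRNA to the two-exponential cascade", {
  tr <- transcription_params(k_NUNC = 1.60, k_INT = 1e-10, k_S1 = 1080,
                             k_S2 = 2.96, k_DEG = 2.12)
  pr <- gfp$protein
  kps <- kinetic_parameter_set("cascade", tr, pr, gfp$brain)
  tt <- seq(0, 10, by = 0.25)
  traj <- simulate_system(kps, times = tt, method = "matexp")
  closed <- 1080 / (2.12 - 1.60) * (exp(-1.60 * tt) - exp(-2.12 * tt))
  got <- trajectory_values(traj, "mRNA")
  expect_equal(got[-1], closed[-1], tolerance = 1e-4)
})

test_that("constant-driver ISG turnover matches its closed form", {
  p <- isg_params(k_S_ISG = 3, k_D_ISG = 0.4, isg0 = 2)
  grid <- seq(0, 30, by = 0.01)
  drv <- rep(50, length(grid))
  tt <- c(1, 5, 10, 30)
  got <- solve_driven_isg(grid, drv, p, tt)
  S <- 3 * 50
  closed <- S / 0.4 * (1 - exp(-0.4 * tt)) + 2 * exp(-0.4 * tt)
  expect_equal(got, closed, tolerance = 1e-4)
})

test_that("simulation from an empty system stays identically zero", {
  y0 <- initial_state(gfp); y0["DNA"] <- 0; y0["DNA"] <- 1e-300
  # a fully zero state is rejected by initial_state (dose > 0); pass it
  # explicitly to the simulator
  y0 <- setNames(numeric(length(y0)), names(y0))
  traj <- simulate_system(gfp, times = seq(0, 10, by = 1), initial = y0)
  expect_true(all(traj$states == 0))
})

test_that("kinetic block is linear in the injected dose", {
  tt <- seq(0, 48, by = 2)
  # exact path: linearity holds to full precision; adaptive path: within
  # solver error
  for (method in c("matexp", "lsoda")) {
    t1 <- simulate_system(gfp, times = tt, dose_scale = 1, method = method)
    t3 <- simulate_system(gfp, times = tt, dose_scale = 3, method = method)
    # compare only values resolvable above the solver floor
    peak <- rep(apply(t1$states, 2, max), each = length(tt) - 1)
    keep <- t1$states[-1, ] > 1e-9 * peak
    ratio <- t3$states[-1, ][keep] / t1$states[-1, ][keep]
    expect_equal(unname(ratio), rep(3, length(ratio)),
                 tolerance = if (method == "matexp") 1e-6 else 5e-4)
  }
})

test_that("all states decay to zero once synthesis inputs are exhausted", {
  # the horizon is set by each system's slowest eigenvalue: the fusion's
  # peripheral store drains at ~5e-5/h, so its washout takes ~1e6 h
  for (p in list(gfp, apo)) {
    A <- ifnpkpd:::.kinetic_matrix(p)
    slowest <- min(abs(Re(eigen(A, only.values = TRUE)$values)))
    t_end <- max(1e4, 40 / slowest)
    traj <- simulate_system(p, times = c(0, 1, 3, 6, 12, 24, 48, t_end))
    peak <- apply(traj$states, 2, max)
    final <- traj$states[8, ]
    nz <- peak > 0
    expect_true(all(final[nz] / peak[nz] < 1e-6))
  }
})

test_that("adaptive solver agrees with the independent Euler oracle", {
  tt <- c(0, 6, 24, 48)
  for (p in list(gfp, apo)) {
    oracle <- euler_kinetics(p, tt, dt = 1e-3)
    traj <- simulate_system(p, times = tt)
    for (comp in c("mRNA", "liver_protein", "serum_protein", "brain_protein")) {
      expect_equal(trajectory_values(traj, comp)[-1],
                   unname(oracle[-1, comp]), tolerance = 5e-3)
    }
  }
})

test_that("matrix-exponential and adaptive solutions agree", {
  tt <- seq(0, 48, by = 3)
  for (p in list(gfp, apo)) {
    a <- simulate_system(p, times = tt, method = "lsoda")
    b <- simulate_system(p, times = tt, method = "matexp")
    scale <- apply(abs(b$states), 2, max)
    expect_lt(max(abs(a$states - b$states) /
                    rep(pmax(scale, 1e-12), each = length(tt))), 1e-4)
  }
})

test_that("staged brain/ISG solves agree with the coupled simulation", {
  isg <- reference_isg_params("IFNGFP")[c("ISG15_liver", "ISG15_brain")]
  tt <- c(0, 6, 9, 13, 24, 48)
  coupled <- simulate_system(gfp, isg = isg, times = tt)
  grid <- seq(0, 48, length.out = 4801)
  ref <- simulate_system(gfp, times = grid, method = "matexp")
  serum <- trajectory_values(ref, "serum_protein")
  staged_brain <- solve_driven_brain(grid, serum, gfp$protein$k_sb,
                                     gfp$brain$k_E, tt)
  expect_equal(trajectory_values(coupled, "brain_protein")[-1],
               staged_brain[-1], tolerance = 1e-4)
  liver <- trajectory_values(ref, "liver_protein")
  staged_isg <- solve_driven_isg(grid, liver, isg$ISG15_liver, tt)
  expect_equal(trajectory_values(coupled, "ISG15_liver")[-1],
               staged_isg[-1], tolerance = 1e-3)
})

test_that("trajectories export tidy and reject unknown compartments", {
  traj <- simulate_system(gfp, times = c(0, 6, 12))
  df <- as.data.frame(traj)
  expect_named(df, c("time_h", "compartment", "value", "units", "molecule"))
  expect_identical(nrow(df), 3L * ncol(traj$states))
  expect_true(all(df$molecule == "IFNGFP"))
  expect_error(trajectory_values(traj, "plasma"), "unknown compartment")
  expect_error(simulate_system(gfp, times = c(1, 2)), "start at 0")
  expect_error(simulate_system(gfp, times = c(0, 2, 2)), "increasing")
})
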