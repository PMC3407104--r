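# Compartment layout for one molecule:
#   DNA, DNAprime, mRNA            hepatic transcription block
#   T1..Tn                         transit chain delaying protein synthesis
#   liver_protein (pg/mg protein), serum_protein (pg/mL),
#   peripheral_protein (pg/mL, ApoAI fusion only), brain_protein (pg/mg)
#   <gene>_<organ>                 ISG turnover responses (gene-expression units)
# Liver/brain protein density 1 mg/mL and a 1 mL volume of distribution make
# amounts and concentrations numerically interchangeable, so all transfers are
# plain first-order exchanges between scalar states.

.transit_names <- function(n) if (n > 0L) paste0("T", seq_len(n)) else character(0)

.kinetic_state_names <- function(protein) {
  c("DNA", "DNAprime", "mRNA", .transit_names(protein$n_transit),
    "liver_protein", "serum_protein",
    if (!is.null(protein$peripheral)) "peripheral_protein",
    "brain_protein")
}

#' Initial system state
#'
#' The hydrodynamic injection deposits the plasmid dose in the liver at time
#' zero; the effective amount is unknown, so an arbitrary dose unit is used.
#' All downstream compartments start empty, except ISG responses which start
#' at their configured baseline `isg0`.
#'
#' @param params A [kinetic_parameter_set()] defining the model variant (number
#'   of transit compartments, peripheral compartment present or not).
#' @param dose_scale Initial DNA amount in arbitrary dose units (default 1).
#' @param isg Optional named list of [isg_params()] (names `<gene>_<organ>`)
#'   whose responses are appended to the state.
#' @return Named numeric state vector with `DNA = dose_scale` and all other
#'   components zero (ISG components at their `isg0`).
#' @export
#' @examples
#' initial_state(reference_kinetic_params("IFNGFP"))
initial_state <- function(params, dose_scale = 1, isg = NULL) {
  .check_positive(dose_scale, "dose_scale")
  nms <- .kinetic_state_names(params$protein)
  y <- setNames(numeric(length(nms)), nms)
  y["DNA"] <- dose_scale
  if (length(isg)) {
    isg0 <- vapply(isg, function(p) p$isg0, numeric(1))
    y <- c(y, setNames(isg0, names(isg)))
  }
  y
}

#' Transcription right-hand side
#'
#' Two active DNA pools drive mRNA synthesis: the injected pool `DNA` decays
#' by degradation (`k_NUNC`) and by conversion into the second pool
#' `DNAprime`; one rate constant `k_INT` governs both the formation and the
#' elimination of `DNAprime`.
#'
#' @param state Named numeric vector containing `DNA`, `DNAprime`, `mRNA`.
#' @param p A [transcription_params()] object.
#' @return Named derivative vector for `DNA`, `DNAprime`, `mRNA` (per hour).
#' @export
transcription_rhs <- function(state, p) {
  DNA <- state[["DNA"]]; DNAp <- state[["DNAprime"]]; mRNA <- state[["mRNA"]]
  c(DNA = -(p$k_NUNC + p$k_INT) * DNA,
    DNAprime = p$k_INT * (DNA - DNAp),
    mRNA = p$k_S1 * DNA + p$k_S2 * DNAp - p$k_DEG * mRNA)
}

#' Hepatic protein and disposition right-hand side
#'
#' Transit-chain-delayed hepatic synthesis followed by reversible liver-serum
#' exchange, optional serum-peripheral exchange, and the (slow) serum-to-brain
#' loss. There is no direct first-order elimination from serum.
#'
#' @param state Named numeric vector containing `mRNA`, the transit states
#'   `T1..Tn` (if `n_transit > 0`), `liver_protein`, `serum_protein` and, for
#'   the peripheral variant, `peripheral_protein`.
#' @param p A [hepatic_protein_params()] object.
#' @return Named derivative vector for the transit, liver, serum (and
#'   peripheral) components.
#' @export
protein_rhs <- function(state, p) {
  has_p_state <- "peripheral_protein" %in% names(state)
  if (has_p_state != !is.null(p$peripheral)) {
    stop("peripheral compartment state and parameters must be supplied together",
         call. = FALSE)
  }
  n <- p$n_transit
  mRNA <- state[["mRNA"]]
  lIFN <- state[["liver_protein"]]; sIFN <- state[["serum_protein"]]
  d <- numeric(0)
  if (n > 0L) {
    Tn <- state[.transit_names(n)]
    dT <- p$k_TRAN * (c(mRNA, Tn[-n]) - Tn)
    d <- setNames(dT, .transit_names(n))
    syn_in <- Tn[[n]]
  } else {
    syn_in <- mRNA
  }
  d_liver <- p$k_S * syn_in - p$k_D * lIFN - p$k_ls * lIFN + p$k_sl * sIFN
  d_serum <- p$k_ls * lIFN - p$k_sl * sIFN - p$k_sb * sIFN
  if (!is.null(p$peripheral)) {
    P <- state[["peripheral_protein"]]
    d_serum <- d_serum - p$peripheral$k_sp * sIFN + p$peripheral$k_ps * P
    d_P <- p$peripheral$k_sp * sIFN - p$peripheral$k_ps * P
    c(d, liver_protein = d_liver, serum_protein = d_serum,
      peripheral_protein = d_P)
  } else {
    c(d, liver_protein = d_liver, serum_protein = d_serum)
  }
}

#' Brain disposition right-hand side
#'
#' One-compartment brain model: first-order input from serum (`k_sb`) and
#' first-order exit/degradation (`k_E`).
#'
#' @param brain_protein Brain protein level (pg/mg protein).
#' @param serum_protein Serum protein level (pg/mL).
#' @param k_sb Serum-to-brain input rate (1/h).
#' @param k_E Brain exit rate (1/h).
#' @return Derivative of the brain protein level (pg/mg/h).
#' @export
brain_rhs <- function(brain_protein, serum_protein, k_sb, k_E) {
  k_sb * serum_protein - k_E * brain_protein
}

#' ISG turnover right-hand side
#'
#' Indirect-response model: synthesis driven by the interferon protein level
#' in the matching organ (linearly, or saturably through
#' `driver / (driver + IFN_50)`), first-order degradation.
#'
#' @param isg Current ISG level (gene-expression units).
#' @param driver Protein level in the matching organ (pg/mg or pg/mL).
#' @param p An [isg_params()] object.
#' @param form `"saturable"` or `"linear"`; defaults to saturable when
#'   `IFN_50` is present in `p`, linear otherwise.
#' @return Derivative of the ISG level (gene-expression units/h).
#' @export
isg_rhs <- function(isg, driver, p,
                    form = if (!is.null(p$IFN_50)) "saturable" else "linear") {
  form <- match.arg(form, c("saturable", "linear"))
  syn <- if (form == "saturable") {
    if (is.null(p$IFN_50))
      stop("saturable ISG synthesis requires IFN_50", call. = FALSE)
    p$k_S_ISG * driver / (driver + p$IFN_50)
  } else {
    p$k_S_ISG * driver
  }
  syn - p$k_D_ISG * isg
}

# Constant-coefficient matrix of the linear kinetic block (everything except
# the ISG responses, which may be nonlinear in their driver).
.kinetic_matrix <- function(params) {
  pr <- params$protein; tr <- params$transcription
  nms <- .kinetic_state_names(pr)
  m <- length(nms)
  A <- matrix(0, m, m, dimnames = list(nms, nms))
  A["DNA", "DNA"] <- -(tr$k_NUNC + tr$k_INT)
  A["DNAprime", "DNA"] <- tr$k_INT
  A["DNAprime", "DNAprime"] <- -tr$k_INT
  A["mRNA", "DNA"] <- tr$k_S1
  A["mRNA", "DNAprime"] <- tr$k_S2
  A["mRNA", "mRNA"] <- -tr$k_DEG
  n <- pr$n_transit
  if (n > 0L) {
    tn <- .transit_names(n)
    prev <- c("mRNA", tn[-n])
    for (i in seq_len(n)) {
      A[tn[i], prev[i]] <- pr$k_TRAN
      A[tn[i], tn[i]] <- -pr$k_TRAN
    }
    syn_src <- tn[n]
  } else {
    syn_src <- "mRNA"
  }
  A["liver_protein", syn_src] <- A["liver_protein", syn_src] + pr$k_S
  A["liver_protein", "liver_protein"] <- A["liver_protein", "liver_protein"] -
    (pr$k_D + pr$k_ls)
  A["liver_protein", "serum_protein"] <- pr$k_sl
  A["serum_protein", "liver_protein"] <- pr$k_ls
  A["serum_protein", "serum_protein"] <- -(pr$k_sl + pr$k_sb)
  if (!is.null(pr$peripheral)) {
    A["serum_protein", "serum_protein"] <-
      A["serum_protein", "serum_protein"] - pr$peripheral$k_sp
    A["serum_protein", "peripheral_protein"] <- pr$peripheral$k_ps
    A["peripheral_protein", "serum_protein"] <- pr$peripheral$k_sp
    A["peripheral_protein", "peripheral_protein"] <- -pr$peripheral$k_ps
  }
  A["brain_protein", "serum_protein"] <- pr$k_sb
  A["brain_protein", "brain_protein"] <- -params$brain$k_E
  A
}

# Exact solution of x' = A x at the requested times (x0 at t = 0), by matrix
# exponential stepping. The transit chain makes A defective (eigenvalue
# -k_TRAN with multiplicity n_transit), so an eigen decomposition is not an
# option; Pade-based expm is exact for any structure. Step propagators are
# cached per unique step length, so uniform grids cost a single expm.
.lin_solve <- function(A, x0, times) {
  m <- nrow(A)
  X <- matrix(0, m, length(times))
  hs <- diff(c(0, times))
  pos <- hs[hs > 0]
  use_powers <- FALSE
  if (length(pos)) {
    g <- min(pos)
    mult <- round(pos / g)
    use_powers <- all(abs(pos / g - mult) < 1e-9) && max(mult) <= 8192
  }
  cache <- list()
  if (use_powers) {
    base_E <- as.matrix(Matrix::expm(A * g))
    cache[["1"]] <- base_E
    get_pow <- function(k) {
      key <- as.character(k)
      E <- cache[[key]]
      if (!is.null(E)) return(E)
      half <- get_pow(k %/% 2L)
      E <- half %*% half
      if (k %% 2L == 1L) E <- E %*% base_E
      cache[[key]] <<- E
      E
    }
  }
  x <- x0
  for (i in seq_along(times)) {
    h <- hs[i]
    if (h > 0) {
      if (use_powers) {
        E <- get_pow(round(h / g))
      } else {
        key <- sprintf("%.15g", h)
        E <- cache[[key]]
        if (is.null(E)) {
          E <- as.matrix(Matrix::expm(A * h))
          cache[[key]] <- E
        }
      }
      x <- as.numeric(E %*% x)
    }
    X[, i] <- x
  }
  dimnames(X) <- list(rownames(A), NULL)
  X
}

# Solve dR/dt = S(t) - kD * R on the grid `grid` (strictly increasing, first
# element 0) given the synthesis series S at the grid points, assuming S is
# piecewise linear. Exact exponential-integrator update per step, so stiffly
# accurate for large kD. Returns R at every grid point.
.solve_turnover <- function(grid, S, kD, r0 = 0) {
  n <- length(grid)
  h <- diff(grid)
  if (n == 1L) return(r0)
  uh <- unique(h)
  phi <- exp(-kD * h)
  x <- kD * h
  small <- x < 1e-4   # series forms avoid catastrophic cancellation
  I0 <- ifelse(small, h * (1 - x / 2 + x^2 / 6), (1 - phi) / kD)
  I1 <- ifelse(small, h^2 * (0.5 - x / 6 + x^2 / 24),
               h * (1 - phi) / kD - (1 - phi * (1 + x)) / kD^2)
  u <- S[-n] * I0 + (diff(S) / h) * I1
  if (length(uh) == 1L) {
    # uniform grid: linear recurrence R_i = phi * R_{i-1} + u_i
    r <- stats::filter(u, phi[1], method = "recursive", init = r0)
    c(r0, as.numeric(r))
  } else {
    r <- numeric(n); r[1] <- r0
    for (i in 2:n) r[i] <- phi[i - 1] * r[i - 1] + u[i - 1]
    r
  }
}

#' Simulate the full kinetic/dynamic system
#'
#' Integrates the coupled transcription, transit/protein, brain and ISG
#' system for one molecule. The default integrator is the stiff-capable
#' adaptive `deSolve::lsoda` (rate constants span about nine orders of
#' magnitude, so stiffness handling is mandatory); `method = "matexp"`
#' computes the linear kinetic block exactly through the matrix exponential
#' and layers the ISG responses on top with an exponential-integrator step,
#' which is much faster inside fitting loops.
#'
#' @param params A [kinetic_parameter_set()].
#' @param isg Optional named list of [isg_params()] (names `<gene>_<organ>`,
#'   organ one of `"liver"`/`"brain"`) to be driven by the matching protein
#'   compartment.
#' @param times Output time grid in hours; strictly increasing, starting at 0.
#' @param dose_scale Initial DNA amount (arbitrary dose units).
#' @param initial Optional full initial state (overrides `dose_scale`).
#' @param rtol,atol Solver tolerances (lsoda).
#' @param method `"lsoda"` (default) or `"matexp"`.
#' @param isg_dt Internal driver grid spacing (h) for the matexp ISG layer.
#' @return An object of class `ifn_trajectory`: list with `times`, a
#'   time-by-compartment `states` matrix, and metadata.
#' @export
#' @examples
#' tr <- simulate_system(reference_kinetic_params("IFNGFP"),
#'                       times = seq(0, 48, by = 1))
#' head(as.data.frame(tr))
simulate_system <- function(params, isg = NULL, times = seq(0, 48, by = 0.5),
                            dose_scale = 1, initial = NULL,
                            rtol = 1e-8, atol = 1e-10,
                            method = c("lsoda", "matexp"), isg_dt = 0.02) {
  method <- match.arg(method)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) stop("'times' must start at 0", call. = FALSE)
  if (length(isg)) {
    if (is.null(names(isg)) || any(!nzchar(names(isg)))) {
      stop("'isg' must be a named list (names '<gene>_<organ>')", call. = FALSE)
    }
  }
  y0 <- if (is.null(initial)) initial_state(params, dose_scale, isg) else initial
  kin_names <- .kinetic_state_names(params$protein)
  isg_names <- names(isg)
  if (!identical(names(y0), c(kin_names, isg_names))) {
    stop("initial state does not match the model variant (transit/peripheral/ISG layout)",
         call. = FALSE)
  }

  if (method == "lsoda") {
    A <- .kinetic_matrix(params)
    nk <- length(kin_names)
    organ_state <- vapply(isg, function(p) {
      switch(attr(p, "organ") %||% "liver",
             liver = "liver_protein", brain = "brain_protein",
             stop("ISG organ must be 'liver' or 'brain'", call. = FALSE))
    }, character(1))
    rhs <- function(t, y, parms) {
      dy_k <- A %*% y[seq_len(nk)]
      if (length(isg)) {
        d_isg <- vapply(seq_along(isg), function(i) {
          isg_rhs(y[nk + i], y[[organ_state[i]]], isg[[i]])
        }, numeric(1))
        list(c(dy_k, d_isg))
      } else {
        list(as.numeric(dy_k))
      }
    }
    out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                          atol = atol, maxsteps = 50000)
    diag_istate <- attr(out, "istate")[1]
    if (diag_istate < 0 || nrow(out) < length(times)) {
      reached <- out[nrow(out), 1]
      stop(sprintf("ODE solver failed to converge beyond t = %g h (of %g h requested)",
                   reached, max(times)), call. = FALSE)
    }
    states <- out[, -1, drop = FALSE]
    rownames(states) <- NULL
  } else {
    A <- .kinetic_matrix(params)
    X <- .lin_solve(A, y0[kin_names], times)
    states <- t(X)
    colnames(states) <- kin_names
    if (length(isg)) {
      tmax <- max(times)
      ngrid <- max(2L, ceiling(tmax / isg_dt))
      grid <- seq(0, tmax, length.out = ngrid + 1L)
      Xg <- .lin_solve(A, y0[kin_names], grid)
      isg_cols <- matrix(0, length(times), length(isg),
                         dimnames = list(NULL, isg_names))
      for (i in seq_along(isg)) {
        p <- isg[[i]]
        organ <- attr(p, "organ") %||% "liver"
        drv <- Xg[if (organ == "liver") "liver_protein" else "brain_protein", ]
        drv <- pmax(drv, 0)
        S <- if (!is.null(p$IFN_50)) {
          p$k_S_ISG * drv / (drv + p$IFN_50)
        } else {
          p$k_S_ISG * drv
        }
        r <- .solve_turnover(grid, S, p$k_D_ISG, r0 = y0[[isg_names[i]]])
        isg_cols[, i] <- approx(grid, r, xout = times)$y
      }
      states <- cbind(states, isg_cols)
    }
  }

  neg <- states < -10 * atol
  if (any(neg)) {
    warning(sprintf("%d state value(s) below -10*atol (most negative %.3g); check tolerances",
                    sum(neg), min(states)), call. = FALSE)
  }

  structure(list(times = times, states = states,
                 molecule = params$molecule, params = params, isg = isg,
                 rtol = rtol, atol = atol, method = method),
            class = "ifn_trajectory")
}

#' Brain trajectory driven by a fixed serum profile
#'
#' Staged counterpart of the brain block: the serum time profile predicted by
#' the liver/serum sub-model is treated as a fixed forcing function (brain
#' uptake does not feed back on serum at any meaningful magnitude).
#'
#' @param driver_times,driver_values Serum profile grid (h) and values
#'   (pg/mL), interpreted as piecewise linear.
#' @param k_sb Serum-to-brain input rate (1/h).
#' @param k_E Brain exit rate (1/h).
#' @param times Output times (h), within the driver grid span.
#' @param brain0 Initial brain level (default 0).
#' @return Numeric vector of brain protein levels at `times`.
#' @export
solve_driven_brain <- function(driver_times, driver_values, k_sb, k_E, times,
                               brain0 = 0) {
  r <- .solve_turnover(driver_times, k_sb * driver_values, k_E, r0 = brain0)
  approx(driver_times, r, xout = times)$y
}

#' ISG trajectory driven by a fixed protein profile
#'
#' Staged counterpart of the ISG turnover block, used when fitting dynamic
#' parameters with the kinetic model held fixed.
#'
#' @param driver_times,driver_values Protein profile in the matching organ,
#'   interpreted as piecewise linear.
#' @param p An [isg_params()] object.
#' @param times Output times (h), within the driver grid span.
#' @return Numeric vector of ISG levels at `times`.
#' @export
solve_driven_isg <- function(driver_times, driver_values, p, times) {
  drv <- pmax(driver_values, 0)
  S <- if (!is.null(p$IFN_50)) {
    p$k_S_ISG * drv / (drv + p$IFN_50)
  } else {
    p$k_S_ISG * drv
  }
  r <- .solve_turnover(driver_times, S, p$k_D_ISG, r0 = p$isg0)
  approx(driver_times, r, xout = times)$y
}

.compartment_units <- function(compartment) {
  units <- c(DNA = "dose units", DNAprime = "dose units",
             mRNA = "gene expression units",
             liver_protein = "pg/mg protein", serum_protein = "pg/mL",
             peripheral_protein = "pg/mL", brain_protein = "pg/mg protein")
  out <- units[compartment]
  out[startsWith(compartment, "T")] <- "gene expression units"
  out[is.na(out)] <- "gene expression units"   # ISG responses
  unname(out)
}

#' @export
as.data.frame.ifn_trajectory <- function(x, ...) {
  comps <- colnames(x$states)
  data.frame(
    time_h = rep(x$times, times = length(comps)),
    compartment = rep(comps, each = length(x$times)),
    value = as.vector(x$states),
    units = rep(.compartment_units(comps), each = length(x$times)),
    molecule = x$molecule,
    stringsAsFactors = FALSE
  )
}

#' @export
print.ifn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory for %s: %d time points over [0, %g] h, %d compartments (%s)\n",
              x$molecule, length(x$times), max(x$times), ncol(x$states),
              x$method))
  peaks <- apply(x$states, 2, max)
  cat("  peak values:\n")
  for (nm in colnames(x$states)) {
    cat(sprintf("    %-20s %.4g\n", nm, peaks[[nm]]))
  }
  invisible(x)
}

#' Extract one compartment series from a trajectory
#'
#' @param trajectory An `ifn_trajectory`.
#' @param compartment Compartment name (see trajectory column names).
#' @param times Optional times at which to linearly interpolate; defaults to
#'   the trajectory's own grid.
#' @return Numeric vector of compartment values.
#' @export
trajectory_values <- function(trajectory, compartment, times = NULL) {
  if (!compartment %in% colnames(trajectory$states)) {
    stop(sprintf("unknown compartment '%s' (available: %s)", compartment,
                 paste(colnames(trajectory$states), collapse = ", ")),
         call. = FALSE)
  }
  v <- trajectory$states[, compartment]
  if (is.null(times)) return(v)
  approx(trajectory$times, v, xout = times)$y
}
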