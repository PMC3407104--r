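#' Mean transit time of the hepatic synthesis delay
#'
#' Expected traversal time of the transit chain, counting the final
#' synthesis-driving step: `MTT = (n_transit + 1) / k_TRAN`. With the default
#' chain of three transit compartments this maps the transit rate constants
#' of the two molecules onto their characteristic synthesis delays.
#'
#' @param k_TRAN Transit rate constant (1/h).
#' @param n_transit Number of transit compartments (default 3).
#' @return Mean transit time in hours.
#' @export
#' @examples
#' mean_transit_time(1.45)    # ~2.76 h
#' mean_transit_time(0.266)   # ~15 h
mean_transit_time <- function(k_TRAN, n_transit = 3L) {
  .check_positive(k_TRAN, "k_TRAN")
  n_transit <- .check_nonneg(n_transit, "n_transit")
  (n_transit + 1) / k_TRAN
}

#' First-order half-life
#'
#' @param k First-order rate constant (1/h).
#' @return `log(2) / k`, in hours.
#' @export
half_life <- function(k) {
  .check_positive(k, "k")
  log(2) / k
}

#' Area under a trajectory compartment curve
#'
#' Trapezoidal integral of the named compartment over `[t0, t1]`, with
#' linearly interpolated endpoints.
#'
#' @param trajectory An `ifn_trajectory`.
#' @param compartment Compartment name (e.g. `"serum_protein"`).
#' @param t0,t1 Integration limits in hours; default to the trajectory span.
#' @return The integral (concentration x h, in the compartment's units).
#' @export
auc <- function(trajectory, compartment, t0 = NULL, t1 = NULL) {
  t0 <- t0 %||% min(trajectory$times)
  t1 <- t1 %||% max(trajectory$times)
  if (t0 >= t1) stop("'t0' must be < 't1'", call. = FALSE)
  if (t0 < min(trajectory$times) || t1 > max(trajectory$times)) {
    stop(sprintf("[%g, %g] is outside the trajectory span [%g, %g]",
                 t0, t1, min(trajectory$times), max(trajectory$times)),
         call. = FALSE)
  }
  tt <- trajectory$times
  keep <- tt > t0 & tt < t1
  grid <- c(t0, tt[keep], t1)
  v <- trajectory_values(trajectory, compartment, grid)
  sum(diff(grid) * (v[-1] + v[-length(v)]) / 2)
}

#' Derived pharmacokinetic report for one molecule
#'
#' Secondary quantities computed from a fitted or reference parameter set:
#' mean transit time of the synthesis delay, hepatic protein degradation
#' half-life, brain exit half-life, and the serum AUC over a simulation
#' window.
#'
#' @param params A [kinetic_parameter_set()].
#' @param t_auc Length-2 window (h) for the serum AUC (default 0-48 h).
#' @param dt Simulation output spacing for the AUC (h).
#' @return A data.frame with columns `quantity`, `value`, `units`, `inputs`.
#' @export
derived_report <- function(params, t_auc = c(0, 48), dt = 0.1) {
  pr <- params$protein
  rows <- list()
  if (pr$n_transit > 0L && !is.null(pr$k_TRAN)) {
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "mean_transit_time",
      value = mean_transit_time(pr$k_TRAN, pr$n_transit), units = "h",
      inputs = sprintf("k_TRAN=%g, n_transit=%d", pr$k_TRAN, pr$n_transit))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "liver_protein_half_life", value = half_life(pr$k_D),
    units = "h", inputs = sprintf("k_D=%g", pr$k_D))
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "brain_exit_half_life", value = half_life(params$brain$k_E),
    units = "h", inputs = sprintf("k_E=%g", params$brain$k_E))
  traj <- simulate_system(params, times = seq(0, t_auc[2], by = dt),
                          method = "matexp")
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "serum_auc",
    value = auc(traj, "serum_protein", t0 = t_auc[1], t1 = t_auc[2]),
    units = "pg*h/mL",
    inputs = sprintf("serum_protein over [%g, %g] h", t_auc[1], t_auc[2]))
  out <- do.call(rbind, rows)
  out$molecule <- params$molecule
  out
}
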