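# Independent fixed-step Euler oracle for the kinetic block. The right-hand
# side is written out from the model equations directly (not by calling the
# package's rhs functions) so that it stays an independent check on the
# adaptive and matrix-exponential solvers.
euler_kinetics <- function(params, times, dt = 1e-3, dose = 1) {
  tr <- params$transcription
  pr <- params$protein
  n <- pr$n_transit
  periph <- !is.null(pr$peripheral)
  DNA <- dose; DNAp <- 0; mRNA <- 0
  Tr <- numeric(n)
  liver <- 0; serum <- 0; P <- 0; brain <- 0
  k_E <- params$brain$k_E
  n_steps <- round(max(times) / dt)
  rec_steps <- round(times / dt)
  out <- matrix(NA_real_, length(times), 8,
                dimnames = list(NULL, c("DNA", "DNAprime", "mRNA", "Tn",
                                        "liver_protein", "serum_protein",
                                        "peripheral_protein", "brain_protein")))
  record <- function(i) {
    out[i, ] <<- c(DNA, DNAp, mRNA, if (n > 0) Tr[n] else NA, liver, serum,
                   if (periph) P else NA, brain)
  }
  hit <- match(0L, rec_steps)
  if (!is.na(hit)) record(hit)
  for (s in seq_len(n_steps)) {
    dDNA <- -(tr$k_NUNC + tr$k_INT) * DNA
    dDNAp <- tr$k_INT * (DNA - DNAp)
    dmRNA <- tr$k_S1 * DNA + tr$k_S2 * DNAp - tr$k_DEG * mRNA
    if (n > 0) {
      dT <- pr$k_TRAN * (c(mRNA, Tr[-n]) - Tr)
      syn <- Tr[n]
    } else {
      dT <- numeric(0)
      syn <- mRNA
    }
    dliver <- pr$k_S * syn - pr$k_D * liver - pr$k_ls * liver + pr$k_sl * serum
    dserum <- pr$k_ls * liver - pr$k_sl * serum - pr$k_sb * serum
    if (periph) {
      dserum <- dserum - pr$peripheral$k_sp * serum + pr$peripheral$k_ps * P
      dP <- pr$peripheral$k_sp * serum - pr$peripheral$k_ps * P
    }
    dbrain <- pr$k_sb * serum - k_E * brain
    DNA <- DNA + dt * dDNA
    DNAp <- DNAp + dt * dDNAp
    mRNA <- mRNA + dt * dmRNA
    if (n > 0) Tr <- Tr + dt * dT
    liver <- liver + dt * dliver
    serum <- serum + dt * dserum
    if (periph) P <- P + dt * dP
    brain <- brain + dt * dbrain
    hit <- match(s, rec_steps)
    if (!is.na(hit)) record(hit)
  }
  out
}

# Tiny observation table builder for estimation tests.
make_obs <- function(molecule, response, time, value, experiment = 1L) {
  as_ifn_dataset(data.frame(molecule = molecule, response = response,
                            time = time, value = value,
                            experiment = experiment,
                            animal = seq_along(value)))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
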