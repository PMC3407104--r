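#' @importFrom stats approx median optim pchisq qchisq rnorm setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite value > 0 (got %s)",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single finite value >= 0", name), call. = FALSE)
  }
  as.numeric(x)
}

#' Hepatic transcription parameters
#'
#' Rate constants of the plasmid-DNA to mRNA transcription block: two pools of
#' transcriptionally active DNA (`DNA`, the material deposited by the
#' hydrodynamic injection, and `DNAprime`, a second, longer-lived active form
#' produced from it) both drive mRNA synthesis, each with its own first-order
#' synthesis rate.
#'
#' @param k_NUNC First-order degradation rate of DNA (1/h).
#' @param k_INT First-order rate controlling both the formation and the
#'   elimination of the second active DNA pool (1/h).
#' @param k_S1 mRNA synthesis rate from DNA (gene-expression units/h per
#'   DNA unit).
#' @param k_S2 mRNA synthesis rate from DNAprime (same units as `k_S1`).
#' @param k_DEG First-order mRNA degradation rate (1/h).
#' @return An object of class `transcription_params`.
#' @export
#' @examples
#' transcription_params(k_NUNC = 1.60, k_INT = 0.112, k_S1 = 1080,
#'                      k_S2 = 2.96, k_DEG = 2.12)
transcription_params <- function(k_NUNC, k_INT, k_S1, k_S2, k_DEG) {
  out <- list(
    k_NUNC = .check_positive(k_NUNC, "k_NUNC"),
    k_INT  = .check_positive(k_INT, "k_INT"),
    k_S1   = .check_positive(k_S1, "k_S1"),
    k_S2   = .check_positive(k_S2, "k_S2"),
    k_DEG  = .check_positive(k_DEG, "k_DEG")
  )
  structure(out, class = "transcription_params")
}

#' Hepatic protein synthesis and disposition parameters
#'
#' Parameters of the transit-compartment-delayed hepatic protein synthesis and
#' of protein exchange between liver, serum and (optionally) a peripheral
#' distribution compartment. The transit chain delays protein synthesis
#' relative to mRNA; with `n_transit = 0` synthesis is driven by mRNA directly
#' and no delay (nor `k_TRAN`) is involved. There is no direct first-order
#' elimination from serum: serum protein is cleared only through back-transfer
#' to the liver (and the negligibly slow brain uptake `k_sb`).
#'
#' @param k_S Hepatic protein synthesis rate (pg/h per gene-expression unit).
#' @param k_D Hepatic protein degradation rate (1/h).
#' @param k_TRAN Transit rate constant (1/h); may be `NULL` when
#'   `n_transit = 0`.
#' @param n_transit Number of transit compartments (non-negative integer,
#'   default 3).
#' @param k_ls Liver-to-serum transfer rate (1/h).
#' @param k_sl Serum-to-liver transfer rate (1/h).
#' @param k_sb Serum-to-brain input rate (1/h). This is the brain uptake rate
#'   written `k_sbr` alongside the disposition equations; the tabulated symbol
#'   `k_sb` is used throughout the package.
#' @param peripheral Either `NULL` (no peripheral compartment; the plain
#'   interferon-GFP model) or a list with elements `k_sp` (serum-to-peripheral
#'   rate, 1/h) and `k_ps` (peripheral-to-serum rate, 1/h), as required by the
#'   ApoAI fusion.
#' @return An object of class `hepatic_protein_params`.
#' @export
hepatic_protein_params <- function(k_S, k_D, k_TRAN = NULL, n_transit = 3L,
                                   k_ls, k_sl, k_sb, peripheral = NULL) {
  n_transit <- .check_nonneg(n_transit, "n_transit")
  if (n_transit != round(n_transit)) stop("'n_transit' must be an integer", call. = FALSE)
  n_transit <- as.integer(n_transit)
  if (n_transit > 0L) {
    if (is.null(k_TRAN)) stop("'k_TRAN' is required when n_transit > 0", call. = FALSE)
    k_TRAN <- .check_positive(k_TRAN, "k_TRAN")
  } else if (!is.null(k_TRAN)) {
    k_TRAN <- .check_positive(k_TRAN, "k_TRAN")
  }
  if (!is.null(peripheral)) {
    if (!is.list(peripheral) || !all(c("k_sp", "k_ps") %in% names(peripheral))) {
      stop("'peripheral' must be NULL or a list with elements k_sp and k_ps",
           call. = FALSE)
    }
    peripheral <- list(k_sp = .check_positive(peripheral$k_sp, "k_sp"),
                       k_ps = .check_positive(peripheral$k_ps, "k_ps"))
  }
  out <- list(
    k_S = .check_positive(k_S, "k_S"),
    k_D = .check_positive(k_D, "k_D"),
    k_TRAN = k_TRAN,
    n_transit = n_transit,
    k_ls = .check_positive(k_ls, "k_ls"),
    k_sl = .check_positive(k_sl, "k_sl"),
    k_sb = .check_positive(k_sb, "k_sb"),
    peripheral = peripheral
  )
  structure(out, class = "hepatic_protein_params")
}

#' Brain disposition parameters
#'
#' @param k_E First-order brain exit/degradation rate (1/h). Tabulated as
#'   `k_b0`; the package uses the equation symbol `k_E`.
#' @return An object of class `brain_params`.
#' @export
brain_params <- function(k_E) {
  structure(list(k_E = .check_positive(k_E, "k_E")), class = "brain_params")
}

#' Interferon-stimulated gene turnover parameters
#'
#' Indirect-response (turnover) model for an interferon-stimulated gene (ISG):
#' synthesis is driven by the interferon protein level in the matching organ,
#' either linearly (`k_S_ISG * IFN`; used for brain responses) or through a
#' saturable function `k_S_ISG * IFN / (IFN + IFN_50)` (used for liver
#' responses); degradation is first order.
#'
#' @param k_S_ISG ISG synthesis rate. Saturable model: gene-expression
#'   units/h. Linear model: gene-expression units * mL / (pg * h).
#' @param k_D_ISG First-order ISG degradation rate (1/h).
#' @param IFN_50 Protein level at half-maximal synthesis (pg/mL). `NULL`
#'   selects the linear model.
#' @param isg0 Initial ISG level (gene-expression units; default 0).
#' @return An object of class `isg_params`.
#' @export
isg_params <- function(k_S_ISG, k_D_ISG, IFN_50 = NULL, isg0 = 0) {
  if (!is.null(IFN_50)) IFN_50 <- .check_positive(IFN_50, "IFN_50")
  structure(list(
    k_S_ISG = .check_positive(k_S_ISG, "k_S_ISG"),
    k_D_ISG = .check_positive(k_D_ISG, "k_D_ISG"),
    IFN_50 = IFN_50,
    isg0 = .check_nonneg(isg0, "isg0")
  ), class = "isg_params")
}

#' Full kinetic parameter set for one molecule
#'
#' Bundles the transcription, hepatic protein and brain parameter blocks for
#' one expressed molecule (plain interferon-GFP, the interferon-GFP-ApoAI
#' fusion, or a user-defined construct).
#'
#' @param molecule Molecule label, e.g. `"IFNGFP"` or `"IFNGFPApo"`.
#' @param transcription A [transcription_params()] object.
#' @param protein A [hepatic_protein_params()] object.
#' @param brain A [brain_params()] object.
#' @return An object of class `kinetic_parameter_set`.
#' @export
kinetic_parameter_set <- function(molecule, transcription, protein, brain) {
  stopifnot(is.character(molecule), length(molecule) == 1L, nzchar(molecule))
  if (!inherits(transcription, "transcription_params"))
    stop("'transcription' must be a transcription_params object", call. = FALSE)
  if (!inherits(protein, "hepatic_protein_params"))
    stop("'protein' must be a hepatic_protein_params object", call. = FALSE)
  if (!inherits(brain, "brain_params"))
    stop("'brain' must be a brain_params object", call. = FALSE)
  structure(list(molecule = molecule, transcription = transcription,
                 protein = protein, brain = brain),
            class = "kinetic_parameter_set")
}

#' @export
print.kinetic_parameter_set <- function(x, ...) {
  cat("Kinetic parameter set:", x$molecule, "\n")
  tr <- x$transcription
  cat(sprintf("  transcription: k_NUNC=%g k_INT=%g k_S1=%g k_S2=%g k_DEG=%g (1/h)\n",
              tr$k_NUNC, tr$k_INT, tr$k_S1, tr$k_S2, tr$k_DEG))
  pr <- x$protein
  cat(sprintf("  protein: k_S=%g k_D=%g k_TRAN=%s n_transit=%d k_ls=%g k_sl=%g k_sb=%g\n",
              pr$k_S, pr$k_D, ifelse(is.null(pr$k_TRAN), "-", format(pr$k_TRAN)),
              pr$n_transit, pr$k_ls, pr$k_sl, pr$k_sb))
  if (!is.null(pr$peripheral)) {
    cat(sprintf("  peripheral: k_sp=%g k_ps=%g\n",
                pr$peripheral$k_sp, pr$peripheral$k_ps))
  }
  cat(sprintf("  brain: k_E=%g\n", x$brain$k_E))
  invisible(x)
}

#' Reference kinetic parameter sets
#'
#' Published in-vivo estimates for the two studied constructs: plain
#' interferon-alpha-GFP (`"IFNGFP"`) and the interferon-alpha-GFP-ApoAI fusion
#' (`"IFNGFPApo"`). Transcription parameters are shared between the two
#' molecules; the ApoAI fusion additionally requires a peripheral serum
#' distribution compartment. These sets serve as defaults for simulation and
#' as ground truth for the synthetic-data generator.
#'
#' @param molecule `"IFNGFP"` or `"IFNGFPApo"`.
#' @return A [kinetic_parameter_set()].
#' @export
#' @examples
#' reference_kinetic_params("IFNGFP")
reference_kinetic_params <- function(molecule = c("IFNGFP", "IFNGFPApo")) {
  molecule <- match.arg(molecule)
  tr <- transcription_params(k_NUNC = 1.60, k_INT = 0.112, k_S1 = 1080,
                             k_S2 = 2.96, k_DEG = 2.12)
  if (molecule == "IFNGFP") {
    pr <- hepatic_protein_params(k_S = 769, k_D = 22.4, k_TRAN = 1.45,
                                 n_transit = 3L, k_ls = 120, k_sl = 0.406,
                                 k_sb = 1.08e-6)
    br <- brain_params(k_E = 0.118)
  } else {
    pr <- hepatic_protein_params(k_S = 53600, k_D = 0.0773, k_TRAN = 0.266,
                                 n_transit = 3L, k_ls = 1720, k_sl = 0.420,
                                 k_sb = 3.75e-5,
                                 peripheral = list(k_sp = 1.54, k_ps = 0.00994))
    br <- brain_params(k_E = 0.509)
  }
  kinetic_parameter_set(molecule, tr, pr, br)
}

#' Reference ISG turnover parameter sets
#'
#' Published turnover estimates for the two interferon-stimulated genes read
#' out in the study, ISG15 and 2'-5' OAS, in liver and brain. Liver responses
#' use the saturable synthesis model with parameters shared between molecules;
#' brain responses use the linear model with a molecule-specific synthesis
#' rate and a shared degradation rate.
#'
#' @param molecule `"IFNGFP"` or `"IFNGFPApo"` (only brain synthesis rates
#'   differ between the two).
#' @return A named list of [isg_params()] entries, each carrying `gene` and
#'   `organ` attributes; names are `"<gene>_<organ>"` and match the
#'   observation response labels.
#' @export
reference_isg_params <- function(molecule = c("IFNGFP", "IFNGFPApo")) {
  molecule <- match.arg(molecule)
  k_S_isg15_brain <- if (molecule == "IFNGFP") 2.05e-3 else 6.08e-4
  k_S_oas_brain <- if (molecule == "IFNGFP") 7.37e-5 else 2.45e-5
  out <- list(
    ISG15_liver = isg_params(k_S_ISG = 491, k_D_ISG = 491, IFN_50 = 151),
    OAS_liver   = isg_params(k_S_ISG = 0.0366, k_D_ISG = 1.18, IFN_50 = 255),
    ISG15_brain = isg_params(k_S_ISG = k_S_isg15_brain, k_D_ISG = 0.127),
    OAS_brain   = isg_params(k_S_ISG = k_S_oas_brain, k_D_ISG = 0.101)
  )
  for (nm in names(out)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    attr(out[[nm]], "gene") <- parts[1]
    attr(out[[nm]], "organ") <- parts[2]
  }
  out
}
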