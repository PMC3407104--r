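#' Supported observation response types
#'
#' Response labels used in observation tables: liver mRNA, protein in liver
#' (pg/mg protein), serum (pg/mL) and brain (pg/mg protein), and the two
#' interferon-stimulated genes (ISG15, 2'-5' OAS) in liver and brain
#' (gene-expression units).
#'
#' @return Character vector of valid response labels.
#' @export
response_types <- function() {
  c("mRNA_liver", "protein_liver", "protein_serum", "protein_brain",
    "ISG15_liver", "OAS_liver", "ISG15_brain", "OAS_brain")
}

.response_compartment <- function(response) {
  map <- c(mRNA_liver = "mRNA", protein_liver = "liver_protein",
           protein_serum = "serum_protein", protein_brain = "brain_protein",
           ISG15_liver = "ISG15_liver", OAS_liver = "OAS_liver",
           ISG15_brain = "ISG15_brain", OAS_brain = "OAS_brain")
  unname(map[response])
}

.response_units <- function(response) {
  map <- c(mRNA_liver = "gene expression units",
           protein_liver = "pg/mg protein", protein_serum = "pg/mL",
           protein_brain = "pg/mg protein",
           ISG15_liver = "gene expression units",
           OAS_liver = "gene expression units",
           ISG15_brain = "gene expression units",
           OAS_brain = "gene expression units")
  unname(map[response])
}

#' Validate and classify a tidy observation table
#'
#' Checks the observation schema (columns `molecule`, `response`, `time`,
#' `value`, `experiment`, optional `animal`), rejects non-positive values
#' (the likelihood operates on log-transformed data, so zero or negative
#' observations are dropped with a count report rather than imputed), and
#' rejects duplicate observation keys.
#'
#' @param x A data.frame of observations.
#' @return The validated data.frame with class `ifn_dataset`, with an
#'   attribute `n_dropped_nonpositive` counting removed rows.
#' @export
as_ifn_dataset <- function(x) {
  x <- as.data.frame(x)
  required <- c("molecule", "response", "time", "value", "experiment")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("observation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"animal" %in% names(x)) x$animal <- seq_len(nrow(x))
  if (nrow(x) == 0L) stop("observation table is empty", call. = FALSE)
  bad_resp <- setdiff(unique(x$response), response_types())
  if (length(bad_resp)) {
    stop("unknown response type(s): ", paste(bad_resp, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$time)) || any(x$time < 0)) {
    stop("observation times must be finite and >= 0", call. = FALSE)
  }
  nonpos <- !is.finite(x$value) | x$value <= 0
  n_dropped <- sum(nonpos)
  if (n_dropped > 0L) {
    message(sprintf("dropping %d observation(s) with non-positive value (log transform undefined)",
                    n_dropped))
    x <- x[!nonpos, , drop = FALSE]
    if (nrow(x) == 0L) stop("no positive observations remain", call. = FALSE)
  }
  key <- interaction(x$molecule, x$response, x$time, x$animal, x$experiment,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicated (molecule, response, time, animal, experiment) keys",
         call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, class = c("ifn_dataset", "data.frame"),
            n_dropped_nonpositive = n_dropped)
}

#' Proportional-error objective (-2 log-likelihood) on the log scale
#'
#' The observation model is `Y_obs = Y_pred * (1 + eps)` with `eps` of mean 0
#' and variance `omega^2`; fitting is done on log-transformed data, so the
#' objective is the extended-least-squares form
#' `sum_j [ log(omega2_r(j)) + (log Y_obs_j - log Y_pred_j)^2 / omega2_r(j) ]`,
#' with each response type `r` carrying its own residual variance. The
#' constant `N log(2*pi)` (and the log-normal Jacobian, constant given the
#' data) is omitted: only objective differences between fits are ever
#' interpreted.
#'
#' @param dataset An [as_ifn_dataset()] table.
#' @param predictions Numeric vector of model predictions aligned with
#'   `dataset` rows.
#' @param omega2 Residual variance(s) on the log/proportional scale: either a
#'   single value shared by all responses or a named vector with one entry
#'   per response type present in `dataset`.
#' @return The objective value; `+Inf` (with a `diagnostics` attribute
#'   locating the offending rows) if any prediction is non-positive.
#' @export
#' @examples
#' d <- as_ifn_dataset(data.frame(molecule = "IFNGFP", response = "mRNA_liver",
#'                                time = c(6, 9), value = c(1.0, 0.5),
#'                                experiment = 1))
#' neg2ll(d, c(1.0, 0.5), omega2 = 1)   # perfect fit: 0
neg2ll <- function(dataset, predictions, omega2) {
  if (length(predictions) != nrow(dataset)) {
    stop("'predictions' must have one value per observation", call. = FALSE)
  }
  bad <- !is.finite(predictions) | predictions <= 0
  if (any(bad)) {
    out <- Inf
    attr(out, "diagnostics") <- data.frame(
      row = which(bad),
      response = dataset$response[bad],
      time = dataset$time[bad],
      prediction = predictions[bad]
    )
    return(out)
  }
  r <- log(dataset$value) - log(predictions)
  if (is.null(names(omega2))) {
    if (length(omega2) != 1L) {
      stop("'omega2' must be a single value or a named per-response vector",
           call. = FALSE)
    }
    w2 <- rep(omega2, length(r))
  } else {
    miss <- setdiff(unique(dataset$response), names(omega2))
    if (length(miss)) {
      stop("no omega2 supplied for response(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    w2 <- unname(omega2[dataset$response])
  }
  if (any(w2 <= 0)) stop("omega2 must be > 0", call. = FALSE)
  sum(log(w2) + r^2 / w2)
}

# Profiled objective: at the ML optimum omega2 for each response equals the
# mean squared log-residual, giving sum_r n_r * (log(mean(r^2)) + 1). The
# variance is floored to keep the objective finite on noise-free data while
# remaining strictly decreasing in the residuals.
.OMEGA2_FLOOR <- 1e-18

.profiled_neg2ll <- function(resid, response, shared_omega = FALSE) {
  if (shared_omega) {
    ms <- max(mean(resid^2), .OMEGA2_FLOOR)
    val <- length(resid) * (log(ms) + mean(resid^2) / ms)
    omega2 <- setNames(rep(ms, length(unique(response))), unique(response))
  } else {
    val <- 0
    groups <- split(resid, response)
    omega2 <- setNames(numeric(length(groups)), names(groups))
    for (g in names(groups)) {
      rg <- groups[[g]]
      ms <- max(mean(rg^2), .OMEGA2_FLOOR)
      val <- val + length(rg) * (log(ms) + mean(rg^2) / ms)
      omega2[g] <- ms
    }
  }
  list(value = val, omega2 = omega2)
}
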