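# Model discrimination rules: nested candidates are compared on the drop in
# the -2 log-likelihood objective (dMVOF) against chi-squared quantiles;
# non-nested candidates on the residual-based AIC; and a winner without
# adequately precise estimates (any CV% above 100) is demoted.

#' Likelihood-ratio significance thresholds
#'
#' Chi-squared quantile for the drop in objective function value (dMVOF)
#' required for significance at level `alpha` with `df` extra parameters.
#' For one extra parameter these are the classical 3.84 / 6.63 / 10.83 at
#' the 5% / 1% / 0.1% levels.
#'
#' @param alpha Significance level (e.g. 0.05).
#' @param df Number of extra parameters in the full model.
#' @return The dMVOF threshold.
#' @export
#' @examples
#' round(lrt_threshold(0.05, 1), 2)   # 3.84
lrt_threshold <- function(alpha, df = 1L) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  qchisq(1 - alpha, df = df)
}

#' Likelihood-ratio test between nested fits
#'
#' Compares a nested (reduced) fit against a full fit of the same data:
#' `dMVOF = MVOF(nested) - MVOF(full)` is referred to a chi-squared
#' distribution with `extra_params` degrees of freedom. A negative dMVOF is
#' allowed but flagged, since at the respective optima of truly nested models
#' it indicates an optimizer failure.
#'
#' @param fit_nested,fit_full `ifn_fit` objects for the reduced and full
#'   model.
#' @param extra_params Number of extra parameters in the full model; defaults
#'   to the difference in `Np`.
#' @param labels Candidate labels (length 2, nested then full).
#' @return An object of class `ifn_comparison` with the dMVOF, p-value,
#'   verdicts at the 5%/1%/0.1% levels and the selected label (5% level).
#' @export
lrt <- function(fit_nested, fit_full, extra_params = NULL,
                labels = c("nested", "full")) {
  if (is.null(extra_params)) extra_params <- fit_full$Np - fit_nested$Np
  if (!is.numeric(extra_params) || extra_params < 1 ||
      extra_params != round(extra_params)) {
    stop("'extra_params' must be a positive integer", call. = FALSE)
  }
  if (!is.null(fit_nested$N) && !is.null(fit_full$N) &&
      fit_nested$N != fit_full$N) {
    stop(sprintf("fits use different data (N = %d vs %d)",
                 fit_nested$N, fit_full$N), call. = FALSE)
  }
  dmvof <- fit_nested$mvof - fit_full$mvof
  flagged <- dmvof < 0
  levels <- c(`5%` = 0.05, `1%` = 0.01, `0.1%` = 0.001)
  thresholds <- vapply(levels, lrt_threshold, numeric(1), df = extra_params)
  significant <- dmvof > thresholds
  p_value <- pchisq(max(dmvof, 0), df = extra_params, lower.tail = FALSE)
  selected <- if (significant[["5%"]]) labels[2] else labels[1]
  structure(list(type = "lrt", candidates = labels, dMVOF = dmvof,
                 extra_params = as.integer(extra_params),
                 thresholds = thresholds, significant = significant,
                 p_value = p_value, selected = selected,
                 negative_dmvof = flagged),
            class = "ifn_comparison")
}

#' Residual-based AIC of a fit
#'
#' `AIC = N * log(RSS / N) + 2 * Np` with the residual sum of squares taken
#' on the log scale, the natural logarithm, and `N` the number of data
#' points. Used to compare non-nested candidates; the lowest value wins.
#'
#' @param fit An `ifn_fit`, or any list with elements `N`, `rss_log`
#'   and `Np`.
#' @return The AIC value.
#' @export
#' @examples
#' aic(list(N = 10, rss_log = 10, Np = 2))   # 10 * log(1) + 4 = 4
aic <- function(fit) {
  if (is.null(fit$N) || is.null(fit$rss_log) || is.null(fit$Np)) {
    stop("'fit' must carry N, rss_log and Np", call. = FALSE)
  }
  if (!is.finite(fit$rss_log) || fit$rss_log <= 0) {
    stop("RSS must be positive and finite", call. = FALSE)
  }
  fit$N * log(fit$rss_log / fit$N) + 2 * fit$Np
}

.max_cv <- function(fit) {
  cv <- fit$cv_pct
  if (is.null(cv) || all(is.na(cv))) return(NA_real_)
  max(abs(cv), na.rm = TRUE)
}

#' Select among candidate fits
#'
#' Nested pairs (declared through `nesting`) are resolved by the
#' likelihood-ratio test at the 5% level; otherwise candidates are ranked by
#' AIC. A precision gate is applied to the winner: a candidate whose
#' parameter estimates carry a CV% above `cv_limit` (or whose standard
#' errors are unavailable) is demoted in favour of the next-ranked candidate
#' with proper standard errors; if no candidate passes the gate the ranking
#' winner is kept and flagged.
#'
#' @param candidates Named list of `ifn_fit` objects (at least one; a single
#'   candidate is returned unchanged with a warning).
#' @param nesting Optional character vector `c(nested, full)` naming two
#'   candidates as nested; resolved by [lrt()] instead of AIC.
#' @param alpha Significance level of the nested test.
#' @param cv_limit Precision gate on CV% (default 100).
#' @return An object of class `ifn_comparison` with a candidate table and
#'   the selected label.
#' @export
select_model <- function(candidates, nesting = NULL, alpha = 0.05,
                         cv_limit = 100) {
  if (length(candidates) == 0L) stop("no candidates supplied", call. = FALSE)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("'candidates' must be a named list", call. = FALSE)
  }
  tab <- data.frame(
    label = names(candidates),
    Np = vapply(candidates, function(f) f$Np, numeric(1)),
    mvof = vapply(candidates, function(f) f$mvof, numeric(1)),
    aic = vapply(candidates, function(f) f$aic, numeric(1)),
    max_cv_pct = vapply(candidates, .max_cv, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  if (length(candidates) == 1L) {
    warning("single candidate supplied; returning it unchanged", call. = FALSE)
    return(structure(list(type = "single", candidates = names(candidates),
                          table = tab, selected = names(candidates)[1],
                          demoted = character(0)),
                     class = "ifn_comparison"))
  }

  if (!is.null(nesting)) {
    if (length(nesting) != 2L || !all(nesting %in% names(candidates))) {
      stop("'nesting' must name two candidates: c(nested, full)", call. = FALSE)
    }
    cmp <- lrt(candidates[[nesting[1]]], candidates[[nesting[2]]],
               labels = nesting)
    order_pref <- if (cmp$p_value <= alpha) rev(nesting) else nesting
    type <- "lrt"
  } else {
    order_pref <- tab$label[order(tab$aic)]
    cmp <- NULL
    type <- "aic"
  }

  proper <- function(label) {
    cv <- .max_cv(candidates[[label]])
    is.finite(cv) && cv <= cv_limit
  }
  demoted <- character(0)
  selected <- NA_character_
  for (lab in order_pref) {
    if (proper(lab)) { selected <- lab; break }
    demoted <- c(demoted, lab)
  }
  gate_failed <- is.na(selected)
  if (gate_failed) selected <- order_pref[1]

  structure(list(type = type, candidates = names(candidates), table = tab,
                 lrt = cmp, selected = selected, demoted = demoted,
                 precision_gate_failed = gate_failed, alpha = alpha,
                 cv_limit = cv_limit),
            class = "ifn_comparison")
}

#' @export
print.ifn_comparison <- function(x, ...) {
  cat("Model comparison (", x$type, ")\n", sep = "")
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (identical(x$type, "lrt") && !is.null(x$dMVOF)) {
    cat(sprintf("  dMVOF = %.3f on %d extra parameter(s), p = %.4g\n",
                x$dMVOF, x$extra_params, x$p_value))
    if (isTRUE(x$negative_dmvof)) {
      cat("  WARNING: negative dMVOF - suspect optimizer failure in the full fit\n")
    }
  }
  if (!is.null(x$lrt)) {
    cat(sprintf("  nested test: dMVOF = %.3f, p = %.4g\n",
                x$lrt$dMVOF, x$lrt$p_value))
  }
  if (length(x$demoted)) {
    cat("  demoted for imprecision (CV% > limit):",
        paste(x$demoted, collapse = ", "), "\n")
  }
  cat("  selected:", x$selected, "\n")
  invisible(x)
}
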