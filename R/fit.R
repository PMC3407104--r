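# Sequential maximum-likelihood fitting.
#
# The model is fitted in four stages, each conditioning on the parameters
# estimated before it: (i) hepatic transcription (shared between molecules),
# (ii) hepatic protein synthesis and liver/serum disposition (per molecule),
# (iii) brain distribution (per molecule, driven by the stage-(ii) serum
# profile), (iv) ISG turnover (per gene and organ; liver saturable and shared
# across molecules, brain linear with molecule-specific synthesis rates and a
# shared degradation rate). All observations available to a stage are fitted
# simultaneously under the proportional-error likelihood of neg2ll(), with
# the residual variance of each response profiled out analytically.

.STAGE_ORDER <- c("transcription", "protein", "brain", "isg")

#' Model configuration (parameter scaffold)
#'
#' Bundles per-molecule kinetic parameter sets and per-molecule ISG parameter
#' lists. Used both as the container of fitted estimates and as the source of
#' fixed/starting values during sequential fitting.
#'
#' @param params Named list of [kinetic_parameter_set()] objects, keyed by
#'   molecule label.
#' @param isg Named list (same molecule keys) of named lists of
#'   [isg_params()], keyed `<gene>_<organ>`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(params, isg = NULL) {
  stopifnot(is.list(params), length(params) >= 1L, !is.null(names(params)))
  for (m in names(params)) {
    if (!inherits(params[[m]], "kinetic_parameter_set"))
      stop("params[['", m, "']] must be a kinetic_parameter_set", call. = FALSE)
  }
  if (is.null(isg)) isg <- setNames(vector("list", length(params)), names(params))
  structure(list(params = params, isg = isg), class = "model_config")
}

#' Reference model configuration
#'
#' [model_config()] populated with the published kinetic and ISG parameter
#' estimates for one or both molecules; the default simulation truth and
#' fitting start point.
#'
#' @param molecules Molecule labels to include.
#' @return A `model_config`.
#' @export
reference_model_config <- function(molecules = c("IFNGFP", "IFNGFPApo")) {
  params <- lapply(molecules, reference_kinetic_params)
  names(params) <- molecules
  isg <- lapply(molecules, reference_isg_params)
  names(isg) <- molecules
  model_config(params, isg)
}

#' Stage specification for fitting
#'
#' Describes one fitting stage: which parameters are free, which are pinned
#' to fixed values, which responses and molecules are used, and the
#' structural options of the stage (transit chain length, peripheral
#' compartment, ISG synthesis form and parameter sharing).
#'
#' @param stage One of `"transcription"`, `"protein"`, `"brain"`, `"isg"`.
#' @param molecule Molecule label (required for `protein` and `brain`
#'   stages).
#' @param free Character vector of free parameter names; `NULL` selects the
#'   stage default.
#' @param fixed Named list of parameter values pinned during this stage
#'   (overriding the scaffold).
#' @param responses Response labels used; `NULL` selects the stage default.
#' @param n_transit Transit chain length for the `protein` stage (0 = no
#'   synthesis delay, `k_TRAN` dropped).
#' @param peripheral Logical: include the serum-peripheral exchange in the
#'   `protein` stage. `NULL` adopts the scaffold's variant.
#' @param gene,organ ISG stage: gene (`"ISG15"`/`"OAS"`) and organ
#'   (`"liver"`/`"brain"`).
#' @param form ISG synthesis form, `"saturable"` or `"linear"`; defaults to
#'   saturable in liver, linear in brain.
#' @param per_molecule_k_S ISG stage: estimate a separate synthesis rate per
#'   molecule (default `TRUE` in brain, `FALSE` in liver).
#' @param molecules Molecules whose data enter the stage; `NULL` = all
#'   available.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(stage, molecule = NULL, free = NULL, fixed = list(),
                       responses = NULL, n_transit = 3L, peripheral = NULL,
                       gene = NULL, organ = NULL, form = NULL,
                       per_molecule_k_S = NULL, molecules = NULL) {
  stage <- match.arg(stage, .STAGE_ORDER)
  if (stage %in% c("protein", "brain") && is.null(molecule)) {
    stop("'molecule' is required for the ", stage, " stage", call. = FALSE)
  }
  if (stage == "isg") {
    if (is.null(gene) || is.null(organ)) {
      stop("'gene' and 'organ' are required for the isg stage", call. = FALSE)
    }
    organ <- match.arg(organ, c("liver", "brain"))
    if (is.null(form)) form <- if (organ == "liver") "saturable" else "linear"
    form <- match.arg(form, c("saturable", "linear"))
    if (is.null(per_molecule_k_S)) per_molecule_k_S <- organ == "brain"
  }
  if (is.null(responses)) {
    responses <- switch(stage,
      transcription = "mRNA_liver",
      protein = c("protein_liver", "protein_serum"),
      brain = "protein_brain",
      isg = paste0(gene, "_", organ))
  }
  spec <- structure(list(stage = stage, molecule = molecule, free = free,
                         fixed = fixed, responses = responses,
                         n_transit = as.integer(n_transit),
                         peripheral = peripheral, gene = gene, organ = organ,
                         form = form, per_molecule_k_S = per_molecule_k_S,
                         molecules = molecules),
                    class = "stage_spec")
  if (!is.null(free) && length(intersect(free, names(fixed)))) {
    stop("free and fixed parameter sets must be disjoint: ",
         paste(intersect(free, names(fixed)), collapse = ", "), call. = FALSE)
  }
  spec
}

#' Fitting control settings
#'
#' @param n_starts Number of optimizer starts: the supplied start plus
#'   jittered copies (log-normal jitter).
#' @param jitter_sd Standard deviation of the log-scale start jitter.
#' @param shared_omega Estimate a single residual variance across responses
#'   instead of one per response.
#' @param maxit_nm Nelder-Mead iteration cap (`NULL` = scaled to dimension).
#' @param polish Run a quasi-Newton (BFGS) polish after the simplex.
#' @param compute_se Compute standard errors at the optimum.
#' @param driver_dt Grid spacing (h) of fixed driver profiles in staged fits.
#' @return A list of control settings.
#' @export
fit_control <- function(n_starts = 5L, jitter_sd = 0.35, shared_omega = FALSE,
                        maxit_nm = NULL, polish = TRUE, compute_se = TRUE,
                        driver_dt = 0.05) {
  list(n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
       shared_omega = shared_omega, maxit_nm = maxit_nm, polish = polish,
       compute_se = compute_se, driver_dt = driver_dt)
}

# -- internal: light-weight parameter assembly (no validity checks; the
#    optimizer guarantees positivity through the log parameterization, and
#    stage (ii) legitimately holds k_sb at 0 until stage (iii)).
.kps_light <- function(molecule, transcription, protein, k_E = 1) {
  list(molecule = molecule, transcription = transcription, protein = protein,
       brain = list(k_E = k_E))
}

.subset_stage_data <- function(dataset, spec) {
  mols <- spec$molecules %||% spec$molecule %||% unique(dataset$molecule)
  sub <- dataset[dataset$response %in% spec$responses &
                   dataset$molecule %in% mols, , drop = FALSE]
  for (r in spec$responses) {
    if (!any(sub$response == r)) {
      stop(sprintf("dataset has no observations for response '%s'%s", r,
                   if (!is.null(spec$molecule)) paste0(" (molecule ", spec$molecule, ")") else ""),
           call. = FALSE)
    }
  }
  rownames(sub) <- NULL
  sub
}

# Build the stage predictor: returns list(par_names, start, predict) where
# predict(theta) gives predictions aligned with the stage data rows.
.stage_predictor <- function(dataset, scaffold, spec, control) {
  sub <- .subset_stage_data(dataset, spec)
  times_u <- sort(unique(c(0, sub$time)))
  t_index <- match(sub$time, times_u)

  if (spec$stage == "transcription") {
    par_names <- spec$free %||% c("k_NUNC", "k_INT", "k_S1", "k_S2", "k_DEG")
    base <- unclass(scaffold$params[[1]]$transcription)
    base <- modifyList(base, spec$fixed)
    predict <- function(theta) {
      p <- modifyList(base, as.list(theta))
      A <- matrix(c(-(p$k_NUNC + p$k_INT), 0, 0,
                    p$k_INT, -p$k_INT, 0,
                    p$k_S1, p$k_S2, -p$k_DEG),
                  nrow = 3, byrow = TRUE)
      X <- .lin_solve(A, c(1, 0, 0), times_u)
      X[3, t_index]
    }
    start <- unlist(base[par_names])
  } else if (spec$stage == "protein") {
    m <- spec$molecule
    kps <- scaffold$params[[m]]
    if (is.null(kps)) stop("no scaffold parameters for molecule ", m, call. = FALSE)
    tr <- kps$transcription
    n_transit <- spec$n_transit
    periph <- spec$peripheral %||% !is.null(kps$protein$peripheral)
    par_names <- spec$free %||% c("k_S", "k_D",
                                  if (n_transit > 0L) "k_TRAN",
                                  "k_ls", "k_sl",
                                  if (periph) c("k_sp", "k_ps"))
    base <- list(k_S = kps$protein$k_S, k_D = kps$protein$k_D,
                 k_TRAN = kps$protein$k_TRAN %||% 1,
                 k_ls = kps$protein$k_ls, k_sl = kps$protein$k_sl,
                 k_sb = kps$protein$k_sb,
                 k_sp = kps$protein$peripheral$k_sp %||% 1,
                 k_ps = kps$protein$peripheral$k_ps %||% 0.01)
    base <- modifyList(base, spec$fixed)
    liver_rows <- sub$response == "protein_liver"
    predict <- function(theta) {
      p <- modifyList(base, as.list(theta))
      pr <- list(k_S = p$k_S, k_D = p$k_D, k_TRAN = p$k_TRAN,
                 n_transit = n_transit, k_ls = p$k_ls, k_sl = p$k_sl,
                 k_sb = p$k_sb,
                 peripheral = if (periph) list(k_sp = p$k_sp, k_ps = p$k_ps))
      A <- .kinetic_matrix(.kps_light(m, tr, pr))
      x0 <- numeric(nrow(A)); x0[1] <- 1
      X <- .lin_solve(A, x0, times_u)
      ifelse(liver_rows, X["liver_protein", t_index], X["serum_protein", t_index])
    }
    start <- unlist(base[par_names])
  } else if (spec$stage == "brain") {
    m <- spec$molecule
    kps <- scaffold$params[[m]]
    if (is.null(kps)) stop("no scaffold parameters for molecule ", m, call. = FALSE)
    par_names <- spec$free %||% c("k_sb", "k_E")
    base <- list(k_sb = kps$protein$k_sb, k_E = kps$brain$k_E)
    base <- modifyList(base, spec$fixed)
    tmax <- max(sub$time)
    grid <- seq(0, tmax, length.out = ceiling(tmax / control$driver_dt) + 1L)
    A <- .kinetic_matrix(kps)
    x0 <- numeric(nrow(A)); x0[1] <- 1
    serum <- pmax(.lin_solve(A, x0, grid)["serum_protein", ], 0)
    predict <- function(theta) {
      p <- modifyList(base, as.list(theta))
      solve_driven_brain(grid, serum, p$k_sb, p$k_E, sub$time)
    }
    start <- unlist(base[par_names])
  } else { # isg
    mols <- spec$molecules %||% sort(unique(sub$molecule))
    key <- paste0(spec$gene, "_", spec$organ)
    saturable <- spec$form == "saturable"
    per_mol <- spec$per_molecule_k_S
    par_names <- spec$free %||% c(
      if (per_mol) paste0("k_S_ISG.", mols) else "k_S_ISG",
      "k_D_ISG",
      if (saturable) "IFN_50")
    tmax <- max(sub$time)
    grid <- seq(0, tmax, length.out = ceiling(tmax / control$driver_dt) + 1L)
    drivers <- lapply(mols, function(m) {
      kps <- scaffold$params[[m]]
      if (is.null(kps)) stop("no scaffold parameters for molecule ", m, call. = FALSE)
      A <- .kinetic_matrix(kps)
      x0 <- numeric(nrow(A)); x0[1] <- 1
      comp <- if (spec$organ == "liver") "liver_protein" else "brain_protein"
      pmax(.lin_solve(A, x0, grid)[comp, ], 0)
    })
    names(drivers) <- mols
    ref_isg <- scaffold$isg[[mols[1]]][[key]]
    base <- list(k_S_ISG = ref_isg$k_S_ISG %||% 1,
                 k_D_ISG = ref_isg$k_D_ISG %||% 0.5,
                 IFN_50 = ref_isg$IFN_50 %||% 100, isg0 = 0)
    if (per_mol) {
      for (m in mols) {
        base[[paste0("k_S_ISG.", m)]] <-
          scaffold$isg[[m]][[key]]$k_S_ISG %||% base$k_S_ISG
      }
    }
    base <- modifyList(base, spec$fixed)
    mol_rows <- lapply(mols, function(m) which(sub$molecule == m))
    names(mol_rows) <- mols
    predict <- function(theta) {
      p <- modifyList(base, as.list(theta))
      pred <- numeric(nrow(sub))
      for (m in mols) {
        rows <- mol_rows[[m]]
        if (!length(rows)) next
        kS <- if (per_mol) p[[paste0("k_S_ISG.", m)]] else p$k_S_ISG
        ip <- structure(list(k_S_ISG = kS, k_D_ISG = p$k_D_ISG,
                             IFN_50 = if (saturable) p$IFN_50,
                             isg0 = p$isg0), class = "isg_params")
        pred[rows] <- solve_driven_isg(grid, drivers[[m]], ip, sub$time[rows])
      }
      pred
    }
    start <- unlist(base[par_names])
  }

  if (!all(par_names %in% names(start)) || any(!is.finite(start)) || any(start <= 0)) {
    stop("could not assemble positive starting values for: ",
         paste(par_names, collapse = ", "),
         " (supply 'start' or a populated scaffold)", call. = FALSE)
  }
  list(data = sub, par_names = par_names, start = start[par_names],
       predict = predict)
}

# Multi-start simplex + quasi-Newton minimization of the profiled objective
# in log-parameter space.
.optimize_ml <- function(objective, start, seed, control) {
  lstart <- log(start)
  np <- length(lstart)
  f <- function(lth) {
    v <- objective(setNames(exp(lth), names(start)))$value
    if (!is.finite(v)) v <- 1e12
    v
  }
  set.seed(seed)
  starts <- list(lstart)
  if (control$n_starts > 1L) {
    for (k in seq_len(control$n_starts - 1L)) {
      starts[[k + 1L]] <- lstart + rnorm(np, 0, control$jitter_sd)
    }
  }
  maxit <- control$maxit_nm %||% (600L * np)
  best <- list(par = lstart, value = f(lstart), convergence = 0L)
  for (s in starts) {
    o <- list(par = s, value = f(s), convergence = 0L)
    for (cycle in 1:2) {   # simplex / quasi-Newton relay
      o1 <- tryCatch(
        optim(o$par, f, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(o1) && o1$value <= o$value) o <- o1
      if (control$polish) {
        o2 <- tryCatch(
          optim(o$par, f, method = "BFGS",
                control = list(maxit = 200L, reltol = 1e-14,
                               ndeps = rep(1e-7, np))),
          error = function(e) NULL)
        if (!is.null(o2) && o2$value <= o$value) o <- o2
      }
    }
    if (o$value < best$value) best <- o
  }
  list(par = setNames(exp(best$par), names(start)), value = best$value,
       convergence = best$convergence %||% 0L,
       at_bound = any(abs(best$par - lstart) > 12))
}

#' Fit one stage of the sequential model
#'
#' Minimizes the proportional-error objective ([neg2ll()]) over the stage's
#' free parameters, log-parameterized to enforce positivity, with the
#' per-response residual variances profiled out analytically. The optimizer
#' is a multi-start Nelder-Mead simplex followed by a BFGS polish.
#'
#' @param dataset An [as_ifn_dataset()] table.
#' @param scaffold A [model_config()] supplying fixed parameters from earlier
#'   stages and default starting values.
#' @param spec A [stage_spec()].
#' @param start Optional named vector of starting values for the free
#'   parameters (defaults to the scaffold values).
#' @param seed Integer seed for the jittered multi-start.
#' @param control A [fit_control()] list.
#' @return An object of class `ifn_fit`: estimates, standard errors, CV%,
#'   the objective value (`mvof`), per-response residual variances, log-scale
#'   RSS, AIC, and convergence metadata.
#' @export
fit_stage <- function(dataset, scaffold, spec, start = NULL, seed = 1L,
                      control = fit_control()) {
  if (!inherits(dataset, "ifn_dataset")) dataset <- as_ifn_dataset(dataset)
  pred <- .stage_predictor(dataset, scaffold, spec, control)
  sub <- pred$data
  start_vec <- pred$start
  if (!is.null(start)) {
    if (is.null(names(start)) || !all(names(start) %in% pred$par_names)) {
      stop("'start' must be named and cover only free parameters: ",
           paste(pred$par_names, collapse = ", "), call. = FALSE)
    }
    start_vec[names(start)] <- start
  }
  log_obs <- log(sub$value)
  objective <- function(theta) {
    p <- pred$predict(theta)
    if (any(!is.finite(p)) || any(p <= 0)) return(list(value = Inf))
    r <- log_obs - log(p)
    out <- .profiled_neg2ll(r, sub$response, control$shared_omega)
    out$resid <- r
    out
  }
  opt <- .optimize_ml(objective, start_vec, seed, control)
  at_opt <- objective(opt$par)
  rss <- sum(at_opt$resid^2)
  N <- nrow(sub)
  Np <- length(pred$par_names)
  fit <- structure(list(
    stage = spec$stage, spec = spec,
    molecule = spec$molecule %||% unique(sub$molecule),
    estimates = opt$par, start = start_vec,
    se = setNames(rep(NA_real_, Np), pred$par_names),
    cv_pct = setNames(rep(NA_real_, Np), pred$par_names),
    mvof = at_opt$value, omega2 = at_opt$omega2,
    N = N, Np = Np, rss_log = rss,
    aic = N * log(rss / N) + 2 * Np,
    convergence = opt$convergence, at_bound = opt$at_bound,
    hessian_pd = NA, n_starts = control$n_starts, seed = seed,
    objective = objective, responses = unique(sub$response)
  ), class = "ifn_fit")
  if (isTRUE(control$compute_se)) {
    se <- tryCatch(standard_errors(fit), error = function(e) NULL)
    if (!is.null(se)) {
      fit$se <- se$se
      fit$cv_pct <- se$cv_pct
      fit$hessian_pd <- se$hessian_pd
    }
  }
  fit
}

#' Standard errors and CV% of a fitted stage
#'
#' Computes standard errors from the inverse of the numerically
#' differentiated Hessian of half the objective (-2 log-likelihood / 2 is the
#' negative log-likelihood) at the optimum, in natural parameter space, and
#' the precision measure CV% = 100 * SE / estimate. A Hessian that is not
#' positive definite is reported as such and the standard errors are marked
#' unavailable - no silent pseudo-inverse is taken.
#'
#' @param fit An `ifn_fit` object.
#' @return List with elements `se`, `cv_pct` (named vectors) and
#'   `hessian_pd` (logical).
#' @export
standard_errors <- function(fit) {
  theta <- fit$estimates
  nms <- names(theta)
  f <- function(th) {
    v <- fit$objective(setNames(th, nms))$value / 2
    if (!is.finite(v)) 1e12 else v
  }
  H <- pracma::hessian(f, as.numeric(theta))
  cov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(se = setNames(rep(NA_real_, length(theta)), nms),
                cv_pct = setNames(rep(NA_real_, length(theta)), nms),
                hessian_pd = FALSE))
  }
  se <- sqrt(pmax(diag(cov), 0))
  list(se = setNames(se, nms),
       cv_pct = setNames(100 * se / as.numeric(theta), nms),
       hessian_pd = TRUE)
}

#' @export
print.ifn_fit <- function(x, ...) {
  cat(sprintf("Stage '%s' fit%s: N = %d, Np = %d\n", x$stage,
              if (!is.null(x$spec$molecule)) paste0(" (", x$spec$molecule, ")") else "",
              x$N, x$Np))
  cat(sprintf("  MVOF = %.4f, log-scale RSS = %.4f, AIC = %.4f, convergence = %d\n",
              x$mvof, x$rss_log, x$aic, x$convergence))
  est <- data.frame(estimate = as.numeric(x$estimates),
                    se = as.numeric(x$se),
                    cv_pct = as.numeric(x$cv_pct),
                    row.names = names(x$estimates))
  print(signif(est, 4))
  invisible(x)
}

.apply_fit_to_config <- function(config, fit) {
  est <- as.list(fit$estimates)
  spec <- fit$spec
  if (spec$stage == "transcription") {
    for (m in names(config$params)) {
      tr <- unclass(config$params[[m]]$transcription)
      config$params[[m]]$transcription <-
        structure(modifyList(tr, est), class = "transcription_params")
    }
  } else if (spec$stage == "protein") {
    m <- spec$molecule
    pr <- config$params[[m]]$protein
    periph <- spec$peripheral %||% !is.null(pr$peripheral)
    pr$n_transit <- spec$n_transit
    for (nm in intersect(names(est), c("k_S", "k_D", "k_TRAN", "k_ls", "k_sl", "k_sb"))) {
      pr[[nm]] <- est[[nm]]
    }
    if (spec$n_transit == 0L) pr$k_TRAN <- NULL
    if (periph) {
      pr$peripheral <- list(k_sp = est$k_sp %||% pr$peripheral$k_sp,
                            k_ps = est$k_ps %||% pr$peripheral$k_ps)
    } else {
      pr$peripheral <- NULL
    }
    config$params[[m]]$protein <- pr
  } else if (spec$stage == "brain") {
    m <- spec$molecule
    if (!is.null(est$k_sb)) config$params[[m]]$protein$k_sb <- est$k_sb
    if (!is.null(est$k_E)) config$params[[m]]$brain$k_E <- est$k_E
  } else if (spec$stage == "isg") {
    key <- paste0(spec$gene, "_", spec$organ)
    mols <- fit$molecule
    for (m in mols) {
      kS <- if (isTRUE(spec$per_molecule_k_S)) {
        est[[paste0("k_S_ISG.", m)]]
      } else {
        est$k_S_ISG
      }
      p <- isg_params(k_S_ISG = kS, k_D_ISG = est$k_D_ISG,
                      IFN_50 = if (spec$form == "saturable") est$IFN_50)
      attr(p, "gene") <- spec$gene
      attr(p, "organ") <- spec$organ
      config$isg[[m]][[key]] <- p
    }
  }
  config
}

#' Four-stage sequential fit
#'
#' Runs the staged fitting workflow: (i) transcription parameters fitted
#' jointly to all molecules' liver mRNA under a single shared parameter set;
#' (ii) with those fixed, hepatic protein/disposition parameters fitted per
#' molecule to liver and serum protein; (iii) with all previous fixed, brain
#' input and exit rates fitted per molecule against brain protein using the
#' stage-(ii) predicted serum profile; (iv) ISG turnover parameters fitted
#' per gene - saturable and shared across molecules in liver, linear in brain
#' with molecule-specific synthesis rates and a shared degradation rate.
#' Brain and ISG stage fits are skipped automatically for molecules/genes
#' without matching observations.
#'
#' @param dataset An [as_ifn_dataset()] table; must contain liver mRNA for
#'   stage (i).
#' @param start_config A [model_config()] of starting values (and structural
#'   variants) for the fit; defaults to the reference configuration for the
#'   molecules present in the data.
#' @param stages Stages to run; must be a prefix of
#'   `c("transcription", "protein", "brain", "isg")`.
#' @param seed Integer seed (stage fits derive their own sub-seeds).
#' @param control A [fit_control()] list.
#' @return An object of class `ifn_sequential_fit`: list of stage fits
#'   (keyed `transcription`, `protein.<molecule>`, `brain.<molecule>`,
#'   `isg.<gene>.<organ>`), the updated `config` of estimates, and the seed.
#' @export
sequential_fit <- function(dataset, start_config = NULL,
                           stages = .STAGE_ORDER, seed = 1L,
                           control = fit_control()) {
  if (!inherits(dataset, "ifn_dataset")) dataset <- as_ifn_dataset(dataset)
  stages <- match.arg(stages, .STAGE_ORDER, several.ok = TRUE)
  if (!identical(stages, .STAGE_ORDER[seq_along(stages)])) {
    stop("'stages' must be a prefix of the ordered workflow: ",
         paste(.STAGE_ORDER, collapse = " -> "), call. = FALSE)
  }
  molecules <- intersect(c("IFNGFP", "IFNGFPApo"), unique(dataset$molecule))
  if (!length(molecules)) molecules <- unique(dataset$molecule)
  config <- start_config %||% reference_model_config(molecules)
  molecules <- intersect(names(config$params), unique(dataset$molecule))

  fits <- list()
  run_fit <- function(label, spec, sub_seed) {
    tryCatch(
      fit_stage(dataset, config, spec, seed = sub_seed, control = control),
      error = function(e) {
        stop(structure(class = c("ifn_stage_error", "error", "condition"),
                       list(message = sprintf("stage '%s' failed: %s", label,
                                              conditionMessage(e)),
                            call = NULL, stage = label,
                            completed = fits)))
      })
  }

  sub_seed <- seed
  if ("transcription" %in% stages) {
    f <- run_fit("transcription", stage_spec("transcription"), sub_seed)
    fits$transcription <- f
    config <- .apply_fit_to_config(config, f)
  }
  if ("protein" %in% stages) {
    for (m in molecules) {
      sub_seed <- sub_seed + 1L
      has_periph <- !is.null(config$params[[m]]$protein$peripheral)
      sp <- stage_spec("protein", molecule = m,
                       n_transit = config$params[[m]]$protein$n_transit,
                       peripheral = has_periph)
      f <- run_fit(paste0("protein.", m), sp, sub_seed)
      fits[[paste0("protein.", m)]] <- f
      config <- .apply_fit_to_config(config, f)
    }
  }
  if ("brain" %in% stages) {
    for (m in molecules) {
      if (!any(dataset$molecule == m & dataset$response == "protein_brain")) next
      sub_seed <- sub_seed + 1L
      f <- run_fit(paste0("brain.", m), stage_spec("brain", molecule = m),
                   sub_seed)
      fits[[paste0("brain.", m)]] <- f
      config <- .apply_fit_to_config(config, f)
    }
  }
  if ("isg" %in% stages) {
    for (gene in c("ISG15", "OAS")) {
      for (organ in c("liver", "brain")) {
        resp <- paste0(gene, "_", organ)
        if (!any(dataset$response == resp)) next
        sub_seed <- sub_seed + 1L
        f <- run_fit(paste0("isg.", gene, ".", organ),
                     stage_spec("isg", gene = gene, organ = organ), sub_seed)
        fits[[paste0("isg.", gene, ".", organ)]] <- f
        config <- .apply_fit_to_config(config, f)
      }
    }
  }
  structure(list(fits = fits, config = config, seed = seed,
                 N = nrow(dataset)),
            class = "ifn_sequential_fit")
}

#' @export
print.ifn_sequential_fit <- function(x, ...) {
  cat(sprintf("Sequential fit: %d stage fit(s) on %d observations (seed %d)\n",
              length(x$fits), x$N, x$seed))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-22s MVOF = %10.3f  AIC = %10.3f  Np = %d\n",
                nm, f$mvof, f$aic, f$Np))
  }
  invisible(x)
}
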