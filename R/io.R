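# File interfaces: tidy observation CSV, parameter YAML with unit
# annotations, fit reports as JSON, and the config-driven pipeline entry
# points binding generation, simulation and fitting together.

.pkg_version <- function() as.character(utils::packageVersion("ifnpkpd"))

.mini_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 251L + 1L)) %% .Machine$integer.max)
}

.provenance <- function(seed = NULL, config = NULL) {
  list(package = "ifnpkpd", version = .pkg_version(),
       seed = seed, config_hash = if (!is.null(config)) .mini_hash(config))
}

#' Read / write tidy observation tables
#'
#' Comma-separated, UTF-8, header row mandatory, `.` decimal separator,
#' times in hours. Columns: `molecule`, `response`, `time`, `value`,
#' `experiment`, `animal`.
#'
#' @param path File path.
#' @return `read_observations()` returns a validated [as_ifn_dataset()].
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    stop("observation file not found: ", path, call. = FALSE)
  }
  x <- read.csv(path, stringsAsFactors = FALSE)
  as_ifn_dataset(x)
}

#' @rdname read_observations
#' @param dataset An observation table.
#' @export
write_observations <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df <- df[, c("molecule", "response", "time", "value", "experiment", "animal")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' Columns: `time_h`, `compartment`, `value`, `units`, `molecule`.
#'
#' @param trajectory An `ifn_trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.params_to_list <- function(kps) {
  pr <- kps$protein
  list(
    transcription = c(unclass(kps$transcription)),
    protein = list(k_S = pr$k_S, k_D = pr$k_D, k_TRAN = pr$k_TRAN,
                   n_transit = pr$n_transit, k_ls = pr$k_ls, k_sl = pr$k_sl,
                   k_sb = pr$k_sb,
                   peripheral = pr$peripheral),
    brain = list(k_E = kps$brain$k_E)
  )
}

.isg_to_list <- function(p) {
  list(k_S_ISG = p$k_S_ISG, k_D_ISG = p$k_D_ISG, IFN_50 = p$IFN_50,
       isg0 = p$isg0)
}

#' Read / write model configurations as YAML
#'
#' Serializes a [model_config()] (kinetic parameter sets and ISG parameters
#' per molecule) with explicit unit annotations; numeric values are written
#' with 12 significant digits so a write/read round trip is lossless at that
#' precision.
#'
#' @param config A [model_config()].
#' @param path File path.
#' @export
write_model_config <- function(config, path) {
  units <- list(rates = "1/h", k_S = "pg/h per gene-expression unit",
                k_S1_k_S2 = "gene-expression units/h per DNA unit",
                IFN_50 = "pg/mL",
                liver_brain_protein = "pg/mg protein", serum_protein = "pg/mL",
                mRNA_ISG = "gene-expression units (2^dCt scale)")
  mols <- lapply(names(config$params), function(m) {
    out <- .params_to_list(config$params[[m]])
    if (length(config$isg[[m]])) {
      out$isg <- lapply(config$isg[[m]], .isg_to_list)
    }
    out
  })
  names(mols) <- names(config$params)
  writeLines(yaml::as.yaml(list(units = units, molecules = mols),
                           precision = 12),
             path)
  invisible(path)
}

#' @rdname write_model_config
#' @return `read_model_config()` returns a [model_config()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$molecules)) stop("no 'molecules' block in ", path, call. = FALSE)
  params <- list(); isg <- list()
  for (m in names(y$molecules)) {
    b <- y$molecules[[m]]
    tr <- do.call(transcription_params, b$transcription)
    pr_args <- b$protein
    pr <- hepatic_protein_params(
      k_S = pr_args$k_S, k_D = pr_args$k_D, k_TRAN = pr_args$k_TRAN,
      n_transit = pr_args$n_transit %||% 3L, k_ls = pr_args$k_ls,
      k_sl = pr_args$k_sl, k_sb = pr_args$k_sb,
      peripheral = pr_args$peripheral)
    params[[m]] <- kinetic_parameter_set(m, tr, pr, brain_params(b$brain$k_E))
    if (!is.null(b$isg)) {
      isg[[m]] <- lapply(b$isg, function(ip) {
        do.call(isg_params, ip[!vapply(ip, is.null, logical(1))])
      })
      for (nm in names(isg[[m]])) {
        parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
        attr(isg[[m]][[nm]], "gene") <- parts[1]
        attr(isg[[m]][[nm]], "organ") <- parts[2]
      }
    } else {
      isg[m] <- list(NULL)
    }
  }
  model_config(params, isg)
}

#' JSON-ready report of a fitted stage
#'
#' @param fit An `ifn_fit` or `ifn_sequential_fit`.
#' @return A list suitable for [jsonlite::write_json()].
#' @export
fit_report <- function(fit) {
  if (inherits(fit, "ifn_sequential_fit")) {
    return(list(type = "sequential_fit", seed = fit$seed, N = fit$N,
                stages = lapply(fit$fits, fit_report)))
  }
  list(stage = fit$stage, molecule = fit$molecule,
       responses = fit$responses,
       estimates = as.list(fit$estimates), se = as.list(fit$se),
       cv_pct = as.list(fit$cv_pct), omega2 = as.list(fit$omega2),
       mvof = fit$mvof, N = fit$N, Np = fit$Np, rss_log = fit$rss_log,
       aic = fit$aic, convergence = fit$convergence,
       at_bound = fit$at_bound, hessian_pd = fit$hessian_pd,
       n_starts = fit$n_starts, seed = fit$seed)
}

#' Sequential fit with model discrimination
#'
#' Runs the full four-stage [sequential_fit()] and, at each of the study's
#' discrimination points, fits the competing model variant and compares:
#' synthesis delay (3 transit compartments) versus no delay per molecule
#' (likelihood-ratio test, one extra parameter), peripheral versus no
#' peripheral serum compartment where the variant carries one
#' (likelihood-ratio test, two extra parameters), and saturable versus
#' linear liver ISG synthesis per gene (AIC with the CV% precision gate).
#'
#' @param dataset An [as_ifn_dataset()] table.
#' @param start_config Starting [model_config()] (default: reference values).
#' @param seed Integer seed.
#' @param control A [fit_control()] list.
#' @return A list of class `ifn_selection_report` with elements `sequential`
#'   (the [sequential_fit()] result) and `comparisons` (named list of
#'   `ifn_comparison` objects).
#' @export
fit_with_selection <- function(dataset, start_config = NULL, seed = 1L,
                               control = fit_control()) {
  if (!inherits(dataset, "ifn_dataset")) dataset <- as_ifn_dataset(dataset)
  seq_fit <- sequential_fit(dataset, start_config = start_config,
                            seed = seed, control = control)
  config <- seq_fit$config
  comparisons <- list()
  molecules <- intersect(names(config$params), unique(dataset$molecule))

  for (m in molecules) {
    key <- paste0("protein.", m)
    if (is.null(seq_fit$fits[[key]])) next
    full <- seq_fit$fits[[key]]
    has_periph <- !is.null(config$params[[m]]$protein$peripheral)
    nodelay <- fit_stage(dataset, config,
                         stage_spec("protein", molecule = m, n_transit = 0L,
                                    peripheral = has_periph),
                         seed = seed + 101L, control = control)
    comparisons[[paste0("delay.", m)]] <-
      lrt(nodelay, full, extra_params = 1L,
          labels = c("no_delay", "transit_delay"))
    if (has_periph) {
      noperiph <- fit_stage(dataset, config,
                            stage_spec("protein", molecule = m,
                                       peripheral = FALSE,
                                       n_transit = config$params[[m]]$protein$n_transit),
                            seed = seed + 202L, control = control)
      comparisons[[paste0("peripheral.", m)]] <-
        lrt(noperiph, full, extra_params = 2L,
            labels = c("no_peripheral", "peripheral"))
    }
  }

  for (gene in c("ISG15", "OAS")) {
    key <- paste0("isg.", gene, ".liver")
    if (is.null(seq_fit$fits[[key]])) next
    sat <- seq_fit$fits[[key]]
    lin <- fit_stage(dataset, config,
                     stage_spec("isg", gene = gene, organ = "liver",
                                form = "linear", per_molecule_k_S = FALSE),
                     seed = seed + 303L, control = control)
    comparisons[[paste0("isg_form.", gene, ".liver")]] <-
      select_model(list(linear = lin, saturable = sat))
  }

  structure(list(sequential = seq_fit, comparisons = comparisons,
                 seed = seed),
            class = "ifn_selection_report")
}

#' @export
print.ifn_selection_report <- function(x, ...) {
  print(x$sequential)
  for (nm in names(x$comparisons)) {
    cat("\n--", nm, "--\n")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

.load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML path",
                             call. = FALSE)
  config
}

.resolve_truth <- function(config) {
  if (is.null(config$params) || identical(config$params, "reference")) {
    reference_model_config(config$molecules %||% c("IFNGFP", "IFNGFPApo"))
  } else {
    read_model_config(config$params)
  }
}

#' Pipeline: generate a synthetic observation CSV
#'
#' Config fields: `out` (CSV path), `seed`, optional `params` (YAML path or
#' `"reference"`), `molecules`, and `design` (arguments to [study_design()]).
#' A provenance JSON (`<out>.meta.json`: package version, seed, config hash)
#' is written alongside.
#'
#' @param config A list or YAML file path.
#' @return The generated dataset, invisibly.
#' @export
pipeline_generate <- function(config) {
  config <- .load_pipeline_config(config)
  if (is.null(config$out)) stop("config needs an 'out' CSV path", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  design <- do.call(study_design, config$design %||% list())
  truth <- .resolve_truth(config)
  ds <- generate_study(design, truth, seed = seed)
  write_observations(ds, config$out)
  jsonlite::write_json(.provenance(seed, config),
                       paste0(config$out, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(ds)
}

#' Pipeline: simulate trajectories and derived quantities
#'
#' Config fields: `out_prefix`, optional `params` (YAML path or
#' `"reference"`), `molecules`, and `times` (list with `to` and `by`, hours).
#' Writes one tidy trajectory CSV per molecule plus a derived-quantity JSON
#' report.
#'
#' @param config A list or YAML file path.
#' @return Named list of trajectories, invisibly.
#' @export
pipeline_simulate <- function(config) {
  config <- .load_pipeline_config(config)
  if (is.null(config$out_prefix)) stop("config needs an 'out_prefix'",
                                       call. = FALSE)
  truth <- .resolve_truth(config)
  tspec <- config$times %||% list(to = 48, by = 0.5)
  times <- seq(0, tspec$to, by = tspec$by)
  trajs <- list(); derived <- list()
  for (m in names(truth$params)) {
    tr <- simulate_system(truth$params[[m]], isg = truth$isg[[m]],
                          times = times)
    write_trajectory(tr, paste0(config$out_prefix, "_", m, ".csv"))
    trajs[[m]] <- tr
    derived[[m]] <- derived_report(truth$params[[m]],
                                   t_auc = c(0, max(times)))
  }
  jsonlite::write_json(
    list(provenance = .provenance(config$seed, config),
         derived = lapply(derived, function(d) as.list(d))),
    paste0(config$out_prefix, "_derived.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null")
  invisible(trajs)
}

#' Pipeline: fit the sequential model to an observation CSV
#'
#' Config fields: `observations` (CSV path), `out_dir`, `seed`, optional
#' `params` (starting values YAML or `"reference"`) and `stages`. Runs
#' [sequential_fit()] (with [fit_with_selection()] when all four stages are
#' requested), writes per-stage JSON reports, the selection report, and the
#' derived-quantity summary. A stage failure writes a machine-readable
#' failure record with the completed stages and re-raises the error.
#'
#' @param config A list or YAML file path.
#' @return The fit object, invisibly.
#' @export
pipeline_fit <- function(config) {
  config <- .load_pipeline_config(config)
  if (is.null(config$observations)) {
    stop("config needs an 'observations' CSV path", call. = FALSE)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_observations(config$observations)
  seed <- as.integer(config$seed %||% 1L)
  start_config <- .resolve_truth(config)
  stages <- config$stages %||% .STAGE_ORDER
  failure_path <- file.path(out_dir, "failure.json")

  res <- tryCatch({
    if (identical(stages, .STAGE_ORDER)) {
      fit_with_selection(ds, start_config = start_config, seed = seed)
    } else {
      sequential_fit(ds, start_config = start_config, stages = stages,
                     seed = seed)
    }
  }, ifn_stage_error = function(e) {
    jsonlite::write_json(
      list(provenance = .provenance(seed, config), failed_stage = e$stage,
           message = conditionMessage(e),
           completed = lapply(e$completed, fit_report)),
      failure_path, auto_unbox = TRUE, digits = NA, null = "null")
    stop(e)
  })

  seq_fit <- if (inherits(res, "ifn_selection_report")) res$sequential else res
  report <- list(provenance = .provenance(seed, config),
                 fit = fit_report(seq_fit))
  if (inherits(res, "ifn_selection_report")) {
    report$comparisons <- lapply(res$comparisons, function(cmp) {
      unclass(cmp)[setdiff(names(unclass(cmp)), c("lrt", "table"))]
    })
  }
  report$derived <- lapply(seq_fit$config$params, function(p) {
    as.list(derived_report(p))
  })
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  write_model_config(seq_fit$config, file.path(out_dir, "estimates.yaml"))
  invisible(res)
}
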