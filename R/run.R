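#' Reproducible run configuration
#'
#' A serializable description of a single model run: which model to
#' execute, the epithelium (preset name or explicit parameter list), the
#' geometry overrides, the simulation scale and the seed. A configuration
#' plus its seed reproduces a run exactly.
#'
#' @param model One of `"permeability"`, `"ter"`, `"steady_state"`.
#' @param preset Preset name (see [tj_presets()]); ignored when
#'   `epithelium` is given.
#' @param epithelium Optional named list of explicit [tj_epithelium()]
#'   fields (SI units).
#' @param n_strand,width Geometry overrides.
#' @param horizon Simulated seconds (`NULL` for the model default).
#' @param reps Replicates (permeability only).
#' @param seed RNG seed.
#' @param init Initial condition for the permeability model.
#' @param out Output directory for [tj_run()] (`NULL` = no files).
#' @return An object of class `tj_run_config`.
#' @seealso [tj_run()], [tj_write_config()], [tj_read_config()]
#' @export
tj_run_config <- function(model = c("permeability", "ter", "steady_state"),
                          preset = "Caco-2", epithelium = NULL,
                          n_strand = 4, width = 50, horizon = NULL,
                          reps = 512, seed = 1, init = "equilibrium",
                          out = NULL) {
  model <- match.arg(model)
  cfg <- list(model = model, preset = preset, epithelium = epithelium,
              n_strand = as.integer(n_strand), width = as.integer(width),
              horizon = horizon, reps = as.integer(reps),
              seed = as.integer(seed), init = init, out = out)
  class(cfg) <- "tj_run_config"
  cfg
}

#' @rdname tj_run_config
#' @param config A `tj_run_config`.
#' @param path YAML file path.
#' @export
tj_write_config <- function(config, path) {
  stopifnot(inherits(config, "tj_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname tj_run_config
#' @export
tj_read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(tj_run_config, obj[!vapply(obj, is.null, TRUE)])
}

#' Execute a configured model run
#'
#' Seeds the RNG from the configuration, runs the requested model, and (if
#' `config$out` is set) writes a `summary.json`, a `trace.csv` and a
#' plain-text `run.log` recording the seed and configuration. Identical
#' configurations produce identical outputs.
#'
#' @param config A [tj_run_config()].
#' @return The model result object, invisibly; with an `files` attribute
#'   listing any files written.
#' @export
tj_run <- function(config) {
  stopifnot(inherits(config, "tj_run_config"))
  epi <- if (!is.null(config$epithelium)) {
    do.call(tj_epithelium, config$epithelium)
  } else {
    tj_preset(config$preset)
  }
  geom <- tj_geometry(n_strand = config$n_strand, width = config$width)
  set.seed(config$seed)

  result <- switch(
    config$model,
    permeability = tj_permeability(
      epi, geom = geom, reps = config$reps,
      horizon = if (is.null(config$horizon)) 7200 else config$horizon,
      init = config$init),
    ter = tj_ter(
      epi, geom = geom,
      horizon = if (is.null(config$horizon)) 1e5 else config$horizon),
    steady_state = {
      mol <- tj_molecule(547)
      P <- tj_ss_permeability(epi, geom = geom, mol = mol) +
        tj_ttj_permeability(tj_tricellular(epi$rho_tTJ), mol)
      R_b <- tj_ss_resistance(epi, geom = geom)
      R_t <- tj_ttj_resistance(tj_tricellular(epi$rho_tTJ),
                               tj_electrical(epi$R_strand))
      list(P_TJ = P, TER = 1 / (1 / R_b + 1 / R_t), model = "steady_state")
    })

  files <- character()
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    summ <- run_summary(config, result)
    f_sum <- file.path(config$out, "summary.json")
    jsonlite::write_json(summ, f_sum, auto_unbox = TRUE, digits = NA)
    files <- f_sum
    tr <- run_trace(config, result)
    if (!is.null(tr)) {
      f_tr <- file.path(config$out, "trace.csv")
      utils::write.csv(tr, f_tr, row.names = FALSE)
      files <- c(files, f_tr)
    }
    f_log <- file.path(config$out, "run.log")
    writeLines(c(
      sprintf("model: %s", config$model),
      sprintf("epithelium: %s", epi$name),
      sprintf("seed: %d", config$seed),
      sprintf("n_strand: %d, width: %d", config$n_strand, config$width),
      sprintf("reps: %d, horizon: %s", config$reps,
              format(if (is.null(config$horizon)) "default"
                     else config$horizon)),
      sprintf("package version: %s",
              as.character(utils::packageVersion("tjbarrier")))),
      f_log)
    files <- c(files, f_log)
  }
  attr(result, "files") <- files
  invisible(result)
}

run_summary <- function(config, result) {
  if (inherits(result, "tj_perm")) {
    list(model = "permeability", epithelium = result$epithelium,
         P_bTJ_nm_s = result$P_bTJ * 1e9, P_tTJ_nm_s = result$P_tTJ * 1e9,
         P_TJ_nm_s = result$P_TJ * 1e9,
         lag_min = if (is.na(result$lag_time)) NULL else
           result$lag_time / 60,
         seed = config$seed)
  } else if (inherits(result, "tj_ter")) {
    list(model = "ter", epithelium = result$epithelium,
         TER_ohm_cm2 = result$TER_mean * 1e4,
         R_bTJ_ohm_cm2 = result$R_bTJ_mean * 1e4,
         R_tTJ_ohm_cm2 = result$R_tTJ * 1e4,
         share_tTJ = result$share_tTJ, share_bTJ = result$share_bTJ,
         seed = config$seed)
  } else {
    list(model = "steady_state", P_TJ_nm_s = result$P_TJ * 1e9,
         TER_ohm_cm2 = result$TER * 1e4, seed = config$seed)
  }
}

run_trace <- function(config, result) {
  if (inherits(result, "tj_perm")) {
    data.frame(t_s = result$time, q_apical_mean = result$qa_mean)
  } else if (inherits(result, "tj_ter")) {
    data.frame(t_s = result$time, TER_ohm_cm2 = result$TER * 1e4)
  } else {
    NULL
  }
}
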