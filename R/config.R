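#' Read and validate a run configuration
#'
#' Parses a YAML run configuration for the command-line interface and
#' validates it against a simple schema: every physical quantity carries a
#' unit-suffixed key (e.g. `d_f_mm`, `mu_a_mm`), stochastic subcommands
#' require an explicit `seed`, and unknown keys are rejected with their
#' paths.
#'
#' @param path path to a YAML configuration file.
#' @return A validated configuration list of class `isfr_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  known_top <- c("subcommand", "seed", "output_dir", "geometry", "optical",
                 "phase_function", "mc", "fit", "invert", "spectrum",
                 "noise_rms_frac", "verbose")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop("unknown configuration keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sub <- cfg$subcommand
  if (is.null(sub) || !sub %in% c("grid", "forward", "simulate", "synth",
                                  "fit-model", "invert"))
    stop("'subcommand' must be one of grid, forward, simulate, synth, ",
         "fit-model, invert", call. = FALSE)
  stochastic <- sub %in% c("simulate", "synth", "invert")
  if (stochastic && is.null(cfg$seed))
    stop("subcommand '", sub, "' is stochastic: an explicit 'seed' is ",
         "required", call. = FALSE)
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    unknown <- setdiff(names(g), c("modality", "na", "d_f_mm", "n_tissue",
                                   "n_external"))
    if (length(unknown))
      stop("unknown geometry keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(cfg$optical)) {
    o <- cfg$optical
    unknown <- setdiff(names(o), c("mu_a_mm", "mu_s_prime_mm", "p_sb",
                                   "phase_function"))
    if (length(unknown))
      stop("unknown optical keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  structure(cfg, class = "isfr_config")
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g)) stop("configuration lacks a 'geometry' block",
                       call. = FALSE)
  sfr_geometry(modality = g$modality, na = g$na, d_f = g$d_f_mm,
               n_tissue = g$n_tissue %||% 1.35,
               n_external = g$n_external)
}

config_phase_function <- function(pf) {
  if (is.null(pf$family)) stop("phase function block needs a 'family'",
                               call. = FALSE)
  switch(toupper(pf$family),
    MHG = pf_mhg(pf$g_hg, pf$alpha),
    TTHG = pf_tthg(pf$alpha, pf$g_f, pf$g_b),
    RMC = pf_rmc(pf$alpha, pf$g_r),
    stop("unknown phase-function family: ", pf$family, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration
#'
#' Dispatches a validated configuration to the corresponding package
#' functionality and writes its artifacts (CSV/JSON) plus a small JSON
#' manifest (subcommand, seed, package version) into `output_dir`. This is
#' the engine behind the bundled command-line script
#' (`system.file("cli", "isfr.R", package = "isfr")`).
#'
#' @param cfg an `isfr_config` (or a path to one).
#' @return Invisibly, a list of the written file paths.
#' @export
run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "isfr_config"))
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (cfg$subcommand == "grid") {
    wr(pf_grid(), "phase_function_grid.csv")
  } else if (cfg$subcommand == "forward") {
    geom <- config_geometry(cfg)
    o <- cfg$optical
    psb <- o$p_sb %||% pf_psb(config_phase_function(o$phase_function))
    pred <- predict_reflectance(o$mu_a_mm, o$mu_s_prime_mm, psb, geom)
    wr(pred, "forward_reflectance.csv")
  } else if (cfg$subcommand == "simulate") {
    geom <- config_geometry(cfg)
    o <- cfg$optical
    pf <- config_phase_function(o$phase_function)
    args <- c(list(pf = pf, geometry = geom,
                   mu_s_prime = o$mu_s_prime_mm, seed = cfg$seed),
              cfg$mc)
    res <- mc_simulate(do.call(mc_config, args))
    wr(res$records, "photon_records.csv")
    meta <- list(n_launched = res$n_launched, n_batches = res$n_batches,
                 seed = cfg$seed)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      p <- file.path(out_dir, "simulation_meta.json")
      jsonlite::write_json(meta, p, auto_unbox = TRUE)
      paths[["simulation_meta.json"]] <- p
    }
  } else if (cfg$subcommand == "synth") {
    geom <- config_geometry(cfg)
    s <- cfg$spectrum %||% list()
    model <- tissue_model(s$preset %||% "skin")
    spec <- synthesize_spectrum(model, geom,
                                engine = s$engine %||% "model",
                                seed = cfg$seed)
    nz <- cfg$noise_rms_frac %||% 0
    if (nz > 0) spec <- add_noise(spec, nz, seed = cfg$seed + 1L)
    wr(as.data.frame(spec), "spectrum.csv")
  } else if (cfg$subcommand == "fit-model") {
    f <- cfg$fit
    dataset <- utils::read.csv(f$dataset_csv)
    fit <- fit_model(dataset, geometry_modality = f$modality)
    wr(fit$residuals, "fit_residuals.csv")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      p <- file.path(out_dir, "fit_params.json")
      jsonlite::write_json(
        list(params = fit$params[c("a1", "a2", "a3", "b1", "b2")],
             ci95 = as.list(fit$ci95),
             median_abs_rel_error = fit$median_abs_rel_error,
             frac_within_10pct = fit$frac_within_10pct),
        p, auto_unbox = TRUE, digits = NA)
      paths[["fit_params.json"]] <- p
    }
  } else if (cfg$subcommand == "invert") {
    geom <- config_geometry(cfg)
    iv <- cfg$invert
    spec_df <- utils::read.csv(iv$spectrum_csv)
    spec <- structure(spec_df, class = c("sfr_spectrum", "data.frame"))
    ret <- retrieve_properties(spec, geom,
                               n_starts = iv$n_starts %||% 50,
                               seed = cfg$seed)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      p <- file.path(out_dir, "retrieval.json")
      jsonlite::write_json(list(theta = as.list(ret$theta),
                                objective = ret$objective,
                                converged = ret$converged),
                           p, auto_unbox = TRUE, digits = NA)
      paths[["retrieval.json"]] <- p
    }
  }
  # manifest for reproducibility
  manifest <- list(subcommand = cfg$subcommand, seed = cfg$seed,
                   package_version =
                     as.character(utils::packageVersion("isfr")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE)
    paths[["manifest.json"]] <- p
  }
  invisible(paths)
}
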