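#' Validate a pipeline run configuration
#'
#' Fills defaults, checks types and value ranges before any computation,
#' and computes a reproducibility hash over the completed configuration.
#'
#' @param config Named list, or path to a YAML/JSON file. Recognized keys:
#'   \describe{
#'     \item{input}{PDB path, or `"toy"` for the built-in toy fold.}
#'     \item{map}{list: `kind` ("cutoff"|"shadow"), `cutoff`,
#'       `shadow_radius`, `min_sep` (for the SBM-facing map).}
#'     \item{metrics}{list: `lro_threshold`.}
#'     \item{simulate}{list: `enabled`, `t_bracket`, `n_steps`,
#'       `save_every`, `bins`.}
#'     \item{outdir}{output directory.}
#'     \item{seed}{integer seed.}
#'     \item{verbose}{logical.}
#'   }
#' @return Validated config (class `run_config`) with `config_hash`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(
    input = "toy",
    map = list(kind = "cutoff", cutoff = 6.0, shadow_radius = 1.0,
               min_sep = 2L, sbm_min_sep = 4L),
    metrics = list(lro_threshold = 12L),
    simulate = list(enabled = FALSE, t_bracket = c(0.8, 1.6),
                    n_steps = 2e6, save_every = 500L, bins = 50L),
    outdir = "kinstab_out",
    seed = 1L,
    verbose = FALSE
  )
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$map$kind %in% c("cutoff", "shadow")) {
    stop("invalid map kind '", cfg$map$kind, "' (cutoff|shadow)")
  }
  stopifnot(cfg$map$cutoff > 0, cfg$map$shadow_radius >= 0,
            cfg$map$cutoff > cfg$map$shadow_radius,
            cfg$metrics$lro_threshold >= 1,
            length(cfg$simulate$t_bracket) == 2L)
  cfg$seed <- as.integer(cfg$seed)
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

# hash over the computational configuration only: where outputs land and
# how chatty the run is do not affect any number
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  cfg$outdir <- NULL
  cfg$verbose <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

log_msg <- function(verbose, ...) {
  if (verbose) message("[kinstab] ", ...)
}

#' Run the analysis pipeline
#'
#' Contacts -> topology metrics -> rate prediction, and optionally an SBM
#' simulation at the located folding temperature with a reweighted
#' free-energy profile and barrier. All outputs are written under
#' `config$outdir` and every JSON report carries the config hash, so an
#' identical configuration (seed included) reproduces all numbers.
#'
#' @param config A list, file path, or `run_config` (see
#'   [validate_config()]).
#' @return Invisibly, a list with the in-memory results (`structure`,
#'   `map`, `report`, `rates`, and when simulated `tf`, `profile`,
#'   `barrier`) plus `files` written.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character(0)
  emit <- function(obj, name) {
    p <- file.path(cfg$outdir, name)
    obj$config_hash <- cfg$config_hash
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <<- c(files, p)
    p
  }

  s <- stage("input", {
    if (identical(cfg$input, "toy")) toy_fold(seed = cfg$seed)
    else read_structure(cfg$input)
  })
  log_msg(cfg$verbose, "structure: ", s$source_id, " (L = ", s$length, ")")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  map <- stage("contacts", {
    if (cfg$map$kind == "shadow") {
      shadow_residue_map(s, cutoff = cfg$map$cutoff,
                         shadow_radius = cfg$map$shadow_radius,
                         min_sep = cfg$map$min_sep)
    } else {
      cutoff_residue_map(atom_contacts(s, cutoff = cfg$map$cutoff,
                                       min_sep = cfg$map$min_sep), s$length)
    }
  })
  write_contact_map(map, file.path(cfg$outdir, "contact_map.txt"))
  files <- c(files, file.path(cfg$outdir, "contact_map.txt"))

  report <- stage("metrics", {
    topology_report(s, map_kind = cfg$map$kind, cutoff = cfg$map$cutoff,
                    shadow_radius = cfg$map$shadow_radius,
                    lro_threshold = cfg$metrics$lro_threshold)
  })
  emit(unclass(report), "topology_report.json")
  log_msg(cfg$verbose, sprintf("LRO = %.3f, ACO = %.3f", report$lro,
                               report$aco))

  rates <- stage("predict", predict_rates(report))
  emit(list(predictions = rates), "rate_predictions.json")

  out <- list(structure = s, map = map, report = report, rates = rates)

  if (isTRUE(cfg$simulate$enabled)) {
    sbm_map <- stage("contacts", {
      if (cfg$map$kind == "shadow") {
        shadow_residue_map(s, cutoff = cfg$map$cutoff,
                           shadow_radius = cfg$map$shadow_radius,
                           min_sep = cfg$map$sbm_min_sep)
      } else {
        cutoff_residue_map(atom_contacts(s, cutoff = cfg$map$cutoff,
                                         min_sep = cfg$map$sbm_min_sep),
                           s$length)
      }
    })
    topo <- stage("simulate", build_sbm(s, sbm_map,
                                        min_sep = cfg$map$sbm_min_sep))
    tf_res <- stage("simulate", {
      find_tf(topo, cfg$simulate$t_bracket, n_steps = cfg$simulate$n_steps,
              save_every = cfg$simulate$save_every, seed = cfg$seed)
    })
    log_msg(cfg$verbose, sprintf("Tf = %.4f (%d transitions)", tf_res$tf,
                                 tf_res$transitions))
    pooled <- stage("landscape", {
      tr <- tf_res$trajectories
      structure(list(q_series = c(tr[[1]]$q_series, tr[[2]]$q_series),
                     e_series = c(tr[[1]]$e_series, tr[[2]]$e_series),
                     temperature = tf_res$tf, seed = cfg$seed,
                     save_every = cfg$simulate$save_every,
                     timestep = tr[[1]]$timestep,
                     n_contacts = tr[[1]]$n_contacts),
                class = "sbm_trajectory")
    })
    prof <- stage("landscape", reweight_equal_basins(pooled,
                                                     bins = cfg$simulate$bins))
    bar <- barrier_height(prof)
    write_profile(prof, file.path(cfg$outdir, "free_energy_profile.tsv"))
    files <- c(files, file.path(cfg$outdir, "free_energy_profile.tsv"))
    emit(list(tf = tf_res$tf, folded_fraction = tf_res$folded_fraction,
              transitions = tf_res$transitions, barrier_kbtf = bar),
         "barrier_report.json")
    out$tf <- tf_res$tf
    out$profile <- prof
    out$barrier <- bar
  }
  out$files <- files
  out$config <- cfg
  invisible(out)
}
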