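#' Default pipeline configuration
#'
#' The configuration is a plain YAML-serializable list mirroring every
#' tunable default of the pipeline: simulation scenario, input paths, window
#' and scoring options, and the model set. [read_config()] merges a YAML
#' file over these defaults.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    simulate = TRUE,
    seed = 1L,
    outdir = "gorassoc_out",
    scenario = list(),   # overrides for scenario_config()
    paths = list(scans = NULL, agonistic = NULL, demography = NULL),
    options = list(
      node_strength = "weighted_degree",
      min_focals_per_window = 0,
      immigrant_cutoff = "07-01",
      lax = FALSE,
      backend = "student",
      gam_family = "gaussian",
      interval_level = 0.95
    ),
    models = c("individual", "dyadic", "infant_gam", "immigrant_gam")
  )
}

#' Read a pipeline configuration file
#'
#' @param path YAML file; keys override [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_cfg(default_config(), user)
}

merge_cfg <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_cfg(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

stage_log <- function(stage, ...) message("[", stage, "] ", ...)

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data (simulate a study or read the three input
#' tables), ranks (Elo trajectories, yearly means, standardized ranks,
#' alphas), networks (calendar-year association networks), covariates
#' (individual-year and dyad-year model tables), eventwindows (time-matched
#' series around second births and immigrations) and fit (hierarchical
#' models and event GAMs). Every stage writes its tables under `outdir` and
#' logs row counts; any stage failure aborts with the stage name. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config a config list ([default_config()] layout) or path to a YAML
#'   file.
#' @param seed,outdir optional overrides of the config values.
#' @param stages subset of
#'   `c("data","ranks","networks","covariates","eventwindows","fit")` or
#'   "all"; earlier prerequisite stages always run (their outputs are
#'   written only for requested stages).
#' @return (invisibly) a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         outdir = NULL, stages = "all") {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  config <- merge_cfg(default_config(), config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(outdir)) config$outdir <- outdir
  all_stages <- c("data", "ranks", "networks", "covariates", "eventwindows", "fit")
  if (identical(stages, "all")) stages <- all_stages
  alias <- c(simulate = "data", eventwindow = "eventwindows")
  stages <- unname(ifelse(stages %in% names(alias), alias[stages], stages))
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # prerequisites always run
  last <- max(match(stages, all_stages))
  run <- all_stages[seq_len(last)]
  want <- all_stages %in% stages
  names(want) <- all_stages
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  opt <- config$options
  out <- list(config = config)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(config$outdir, name), row.names = FALSE)
  }
  set.seed(config$seed)

  # -- data ------------------------------------------------------------
  run_stage("data", {
    if (isTRUE(config$simulate)) {
      scen <- do.call(scenario_config, c(config$scenario,
                                         list(seed = config$seed)))
      study <- simulate_study(scen)
      out$study <- study
      stage_log("data", "simulated ", nrow(study$scans), " scans, ",
                nrow(study$agonistic), " agonistic events, ",
                nrow(study$demography$individuals), " individuals")
      if (want["data"]) {
        write_demography(study$demography, file.path(config$outdir, "demography.csv"))
        write_scans(study$scans, file.path(config$outdir, "scans.csv"))
        write_agonistic(study$agonistic, file.path(config$outdir, "agonistic.csv"))
        wr(truth_long(study$truth), "truth.csv")
      }
    } else {
      p <- config$paths
      if (is.null(p$scans) || is.null(p$demography))
        stop("simulate is false but paths$scans/paths$demography not set")
      demography <- read_demography(p$demography)
      scans <- read_scans(p$scans, demography, lax = isTRUE(opt$lax))
      agonistic <- if (!is.null(p$agonistic))
        read_agonistic(p$agonistic, demography, lax = isTRUE(opt$lax))
      else data.frame(date = as.Date(character()), group_id = character(),
                      winner_id = character(), loser_id = character(),
                      behaviour = character(), sex_class = character())
      out$study <- list(demography = demography, scans = scans,
                        agonistic = agonistic)
      stage_log("data", "read ", nrow(scans), " scans, ",
                nrow(agonistic), " agonistic events")
    }
  })
  study <- out$study
  span_years <- sort(unique(as.integer(format(study$scans$date, "%Y"))))
  span <- c(as.Date(sprintf("%d-01-01", min(span_years))),
            as.Date(sprintf("%d-12-31", max(span_years))))

  # -- ranks -----------------------------------------------------------
  if ("ranks" %in% run) run_stage("ranks", {
    elo <- run_elo(study$agonistic, study$demography,
                   start_date = span[1], end_date = span[2])
    ranks <- rank_table(elo, study$demography)
    out$elo <- elo; out$ranks <- ranks
    stage_log("ranks", nrow(elo), " daily ratings, ",
              nrow(ranks), " individual-year ranks")
    if (want["ranks"]) { wr(elo, "elo_daily.csv"); wr(ranks, "ranks.csv") }
  })

  # -- networks --------------------------------------------------------
  if ("networks" %in% run) run_stage("networks", {
    nets <- yearly_networks(study$scans, study$demography, years = span_years,
                            node_strength_mode = opt$node_strength,
                            min_focals = opt$min_focals_per_window)
    out$networks <- nets
    stage_log("networks", nrow(nets$dyads), " dyad-year rows, ",
              nrow(nets$nodes), " node-year rows")
    if (want["networks"]) {
      wr(nets$dyads, "networks.csv"); wr(nets$nodes, "node_strength.csv")
    }
  })

  # -- covariates ------------------------------------------------------
  if ("covariates" %in% run) run_stage("covariates", {
    tabs <- build_model_tables(out$networks, out$ranks, study$demography,
                               cutoff_month_day = opt$immigrant_cutoff)
    out$model_tables <- tabs
    stage_log("covariates", nrow(tabs$individual), " individual-year rows, ",
              if (is.null(tabs$dyad)) 0 else nrow(tabs$dyad), " dyad-year rows")
    if (want["covariates"]) {
      wr(tabs$individual, "individual_year.csv")
      if (!is.null(tabs$dyad)) wr(tabs$dyad, "dyad_year.csv")
    }
  })

  # -- event windows ---------------------------------------------------
  if ("eventwindows" %in% run) run_stage("eventwindows", {
    ev <- find_events(study$demography, start_date = span[1],
                      end_date = span[2] + 1)
    series <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
      suppressMessages(event_strength_series(
        study$scans, study$demography, ev[i, ],
        node_strength_mode = opt$node_strength))))
    out$events <- ev
    out$event_tables <- if (!is.null(series) && nrow(series))
      suppressMessages(compile_event_tables(series))
    else list(infant = NULL, immigrant = NULL)
    stage_log("eventwindows", nrow(ev), " events, ",
              if (is.null(series)) 0 else nrow(series), " series rows")
    if (want["eventwindows"]) {
      et <- out$event_tables
      if (!is.null(et$infant)) wr(et$infant, "event_series_infant.csv")
      if (!is.null(et$immigrant)) wr(et$immigrant, "event_series_immigrant.csv")
    }
  })

  # -- fit -------------------------------------------------------------
  if ("fit" %in% run) run_stage("fit", {
    lvl <- opt$interval_level
    meta <- list()
    save_fit <- function(fit, id) {
      if (want["fit"]) {
        wr(fit$effects, paste0("fit_", id, ".csv"))
        if (!is.null(fit$smooths)) wr(fit$smooths, paste0("fit_", id, "_smooths.csv"))
        m <- fit$diagnostics
        m$r2 <- as.list(fit$r2)
        m$re_sd <- as.list(m$re_sd)
        jsonlite::write_json(m, file.path(config$outdir,
                                          paste0("fit_", id, "_meta.json")),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
    }
    if ("individual" %in% config$models && !is.null(out$model_tables$individual)) {
      fit <- fit_hierarchical(out$model_tables$individual, "individual",
                              backend = opt$backend, level = lvl,
                              seed = config$seed)
      out$fit_individual <- fit; save_fit(fit, "individual")
      stage_log("fit", "individual model: n = ", fit$diagnostics$n)
    }
    if ("dyadic" %in% config$models && !is.null(out$model_tables$dyad)) {
      fit <- fit_hierarchical(out$model_tables$dyad, "dyadic",
                              backend = opt$backend, level = lvl,
                              seed = config$seed)
      out$fit_dyadic <- fit; save_fit(fit, "dyadic")
      stage_log("fit", "dyadic model: n = ", fit$diagnostics$n)
    }
    fit_gam_safe <- function(tab, id) {
      if (is.null(tab)) {
        stage_log("fit", id, ": no events, skipped"); return(NULL)
      }
      f <- tryCatch(fit_event_gam(tab, level = lvl, family = opt$gam_family,
                                  seed = config$seed),
                    error = function(e) {
                      if (grepl("degenerate", conditionMessage(e))) {
                        stage_log("fit", id, ": ", conditionMessage(e),
                                  " - skipped")
                        NULL
                      } else stop(e)
                    })
      if (!is.null(f)) {
        save_fit(f, id)
        stage_log("fit", id, ": n = ", f$diagnostics$n)
      }
      f
    }
    if ("infant_gam" %in% config$models)
      out$fit_infant_gam <- fit_gam_safe(out$event_tables$infant, "infant_gam")
    if ("immigrant_gam" %in% config$models)
      out$fit_immigrant_gam <- fit_gam_safe(out$event_tables$immigrant,
                                            "immigrant_gam")
  })
  invisible(out)
}
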