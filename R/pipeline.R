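#' Pipeline run configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()]:
#' input paths, site coordinates, SPI scales and severity thresholds,
#' curated drought-event years, response-window lengths, significance level,
#' the master seed, and the synthetic-trial parameters used by the
#' \code{"simulate"} stage. Defaults follow the analysis conventions of the
#' rest of the package (SPI scales 1-48 months, severity thresholds -1 /
#' -1.5 / -2, a 9-year resistance window and 2-year recovery window).
#'
#' @param ring_csv,station_csv optional input paths; when \code{NULL} the
#'   pipeline uses the artifacts written by its own \code{"simulate"} stage.
#' @param site_lat,site_lon trial-site coordinates.
#' @param spi_scales SPI aggregation scales in months.
#' @param severity_thresholds strictly decreasing vector
#'   (moderate, severe, extreme).
#' @param event_years curated drought-event years (vector, or named list per
#'   site); \code{NULL} means detect from the SPI.
#' @param detection_threshold,detection_scales,detection_months SPI drought
#'   detection settings (see [detect_drought_years()]).
#' @param response_window,post_window Lloret index windows in years.
#' @param alpha significance level used in reports.
#' @param seed master seed; forwarded to the simulation config.
#' @param simulation named list of overrides for [simulation_config()].
#' @return validated list of class \code{run_config}.
#' @export
pipeline_config <- function(ring_csv = NULL, station_csv = NULL,
                            site_lat = 48.5, site_lon = 16.2,
                            spi_scales = c(1, 3, 6, 12, 24, 48),
                            severity_thresholds = c(-1, -1.5, -2),
                            event_years = c(1993, 2000, 2003),
                            detection_threshold = -1.5,
                            detection_scales = c(1, 3),
                            detection_months = 4:9,
                            response_window = 9, post_window = 2,
                            alpha = 0.05, seed = 1, simulation = list()) {
  cfg <- list(ring_csv = ring_csv, station_csv = station_csv,
              site_lat = site_lat, site_lon = site_lon,
              spi_scales = spi_scales,
              severity_thresholds = severity_thresholds,
              event_years = event_years,
              detection_threshold = detection_threshold,
              detection_scales = detection_scales,
              detection_months = detection_months,
              response_window = response_window, post_window = post_window,
              alpha = alpha, seed = as.integer(seed), simulation = simulation)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (any(diff(cfg$severity_thresholds) >= 0))
    stop("severity thresholds must be strictly decreasing")
  if (any(cfg$spi_scales < 1)) stop("SPI scales must be >= 1")
  if (cfg$response_window %% 2 == 0) stop("response window must be odd")
  for (p in c("ring_csv", "station_csv")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(sprintf("%s does not exist: %s", p, cfg[[p]]))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' The configuration is stored as a flat, human-editable YAML document.
#' A serialise-then-parse round trip reproduces an equivalent
#' configuration.
#'
#' @param path YAML file path.
#' @return [read_config()] returns a validated \code{run_config};
#'   [write_config()] returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  known <- setdiff(names(base), "simulation")
  unknown <- setdiff(names(raw), c(known, "simulation"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in intersect(names(raw), known)) {
    if (!is.null(raw[[nm]])) base[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$simulation)) base$simulation <- raw$simulation
  validate_run_config(unclass(base))
}

#' @rdname read_config
#' @param config a \code{run_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  s <- utf8ToInt(yaml::as.yaml(unclass(config)))
  sprintf("%08x", sum(s * (seq_along(s) %% 97 + 1)) %% 4294967291)
}

#' Run the drought-response analysis pipeline
#'
#' Orchestrates the pipeline stages and writes each stage's artifacts as
#' CSV (plus JSON sidecars) under \code{out_dir}. Stages:
#' \describe{
#'   \item{simulate}{synthetic stations, ring-width cores (CSV and rwl) and
#'     truth sidecar}
#'   \item{spi}{site precipitation by IDW, SPI per configured scale}
#'   \item{events}{drought years (curated list or SPI detection)}
#'   \item{response}{per-tree resistance/recovery table}
#'   \item{stability}{Finlay-Wilkinson slopes, species summary, rank
#'     correlations}
#'   \item{repeatability}{species- and provenance-level repeatability}
#'   \item{evolvability}{per-provenance CV_A}
#'   \item{report}{repeated-measures model-selection table and a run
#'     summary}
#'   \item{all}{all of the above, in order}
#' }
#' Reruns with an identical configuration reproduce identical artifacts.
#' Progress is logged to standard error; results never are.
#'
#' @param stage stage name (see above).
#' @param config a \code{run_config} from [pipeline_config()] or
#'   [read_config()].
#' @param out_dir output directory, created if needed.
#' @param verbose log progress messages to standard error.
#' @return named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "spi", "events",
                                   "response", "stability", "repeatability",
                                   "evolvability", "report"),
                         config = pipeline_config(), out_dir = ".",
                         verbose = TRUE) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  say("run_pipeline: stage=%s seed=%d config=%s", stage, config$seed,
      config_hash(config))
  stages <- if (stage == "all")
    c("simulate", "spi", "events", "response", "stability",
      "repeatability", "evolvability", "report") else stage
  art <- list()
  pth <- function(f) file.path(out_dir, f)

  for (st in stages) {
    say("stage %s ...", st)
    if (st == "simulate") {
      sim_args <- config$simulation
      sim_args$seed <- config$seed
      scfg <- do.call(simulation_config, sim_args)
      stations <- simulate_precip(scfg)
      sim <- simulate_ring_widths(scfg)
      utils::write.csv(as.data.frame(stations), pth("stations.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as.data.frame(sim$cores), pth("rings.csv"),
                       row.names = FALSE, quote = FALSE)
      write_rwl(sim$cores, pth("rings.rwl"), dialect = "0.001mm")
      jsonlite::write_json(
        list(r_true = sim$truth$r_true,
             provenance_effects = as.list(sim$truth$provenance_effects),
             tree_sensitivities = as.list(sim$truth$tree_sensitivities)),
        pth("truth.json"), auto_unbox = TRUE, digits = NA)
      art$stations <- pth("stations.csv"); art$rings <- pth("rings.csv")
      art$rwl <- pth("rings.rwl"); art$truth <- pth("truth.json")
    } else if (st == "spi") {
      stations <- read_station_csv(config$station_csv %||% pth("stations.csv"))
      site <- idw_interpolate(stations, config$site_lat, config$site_lon)
      utils::write.csv(site, pth("site_precip.csv"), row.names = FALSE,
                       quote = FALSE)
      art$site_precip <- pth("site_precip.csv")
      for (k in config$spi_scales) {
        s <- spi(site, k)
        f <- pth(sprintf("spi_%02d.csv", k))
        utils::write.csv(as.data.frame(s), f, row.names = FALSE, quote = FALSE)
        jsonlite::write_json(
          list(scale_k = k, calibration = attr(s, "calibration"),
               fit = attr(s, "fit")),
          pth(sprintf("spi_%02d_fit.json", k)), auto_unbox = TRUE,
          digits = NA, na = "null")
        art[[sprintf("spi_%02d", k)]] <- f
      }
    } else if (st == "events") {
      spi_set <- lapply(config$detection_scales, function(k) {
        s <- utils::read.csv(pth(sprintf("spi_%02d.csv", k)))
        attr(s, "scale_k") <- as.integer(k)
        s
      })
      ev <- detect_drought_years(spi_set,
                                 threshold = config$detection_threshold,
                                 scales = config$detection_scales,
                                 month_window = config$detection_months,
                                 events = config$event_years)
      utils::write.csv(ev, pth("events.csv"), row.names = FALSE, quote = FALSE)
      art$events <- pth("events.csv")
    } else if (st == "response") {
      cores <- read_ring_csv(config$ring_csv %||% pth("rings.csv"))
      collection <- average_cores(cores)
      ev <- utils::read.csv(pth("events.csv"))$event_year
      tab <- compute_response_table(collection, ev,
                                    window = config$response_window,
                                    post_window = config$post_window)
      write_response_csv(tab, pth("response.csv"))
      chron <- build_chronology(collection)
      utils::write.csv(as.data.frame(chron), pth("chronology.csv"),
                       row.names = FALSE, quote = FALSE)
      art$response <- pth("response.csv"); art$chronology <- pth("chronology.csv")
    } else if (st == "stability") {
      tab <- read_response_csv(pth("response.csv"))
      rows <- list(); summ <- list()
      for (tr in c("Res", "Rec")) {
        fw <- fw_regression(tab, tr)
        rows[[tr]] <- cbind(trait = tr, as.data.frame(fw))
        s <- stability_summary(fw$b)
        summ[[tr]] <- data.frame(trait = tr, b_dev = s$b_dev, b_ist = s$b_ist,
                                 n_provenances = s$n, n_unstable = s$n_unstable)
        rs <- rank_stability(tab, tr)
        utils::write.csv(as.data.frame(rs),
                         pth(sprintf("rank_stability_%s.csv", tr)),
                         quote = FALSE)
      }
      utils::write.csv(do.call(rbind, rows), pth("stability_provenances.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(do.call(rbind, summ), pth("stability_summary.csv"),
                       row.names = FALSE, quote = FALSE)
      art$stability <- pth("stability_provenances.csv")
      art$stability_summary <- pth("stability_summary.csv")
    } else if (st == "repeatability") {
      tab <- read_response_csv(pth("response.csv"))
      rows <- list()
      for (tr in c("Res", "Rec")) {
        sp <- species_repeatability(tab, tr)
        pr <- provenance_repeatability(tab, tr, alpha = config$alpha)
        rows[[tr]] <- cbind(trait = tr, scope = c("species",
                                                  rep("provenance", nrow(pr))),
                            rbind(data.frame(provenance_id = NA, r = sp$r,
                                             se_r = sp$se_r,
                                             n_trees = sp$n_trees,
                                             n_records = sp$n_obs,
                                             boundary = sp$boundary,
                                             significant = is.finite(sp$se_r) &&
                                               sp$se_r > 0 &&
                                               sp$r / sp$se_r >
                                                 stats::qnorm(1 - config$alpha / 2),
                                             reason = NA),
                                  pr[c("provenance_id", "r", "se_r", "n_trees",
                                       "n_records", "boundary", "significant",
                                       "reason")]))
      }
      utils::write.csv(do.call(rbind, rows), pth("repeatability.csv"),
                       row.names = FALSE, quote = FALSE)
      art$repeatability <- pth("repeatability.csv")
    } else if (st == "evolvability") {
      tab <- read_response_csv(pth("response.csv"))
      rows <- lapply(c("Res", "Rec"), function(tr)
        cbind(trait = tr, evolvability_table(tab, tr)))
      utils::write.csv(do.call(rbind, rows), pth("evolvability.csv"),
                       row.names = FALSE, quote = FALSE)
      art$evolvability <- pth("evolvability.csv")
    } else if (st == "report") {
      tab <- read_response_csv(pth("response.csv"))
      rows <- lapply(c("Res", "Rec"), function(tr)
        cbind(trait = tr, as.data.frame(repeated_measures_selection(tab, tr))))
      utils::write.csv(do.call(rbind, rows), pth("model_selection.csv"),
                       row.names = FALSE, quote = FALSE)
      write_config(config, pth("config_used.yaml"))
      art$model_selection <- pth("model_selection.csv")
      art$config_used <- pth("config_used.yaml")
    }
  }
  say("done: %d artifacts in %s", length(art), out_dir)
  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a response table written by the pipeline
#'
#' @param path CSV written by [write_response_csv()].
#' @return a \code{response_table}.
#' @export
read_response_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$flags[is.na(tab$flags)] <- ""
  attr(tab, "events") <- sort(unique(tab$event_year))
  class(tab) <- c("response_table", "data.frame")
  tab
}
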