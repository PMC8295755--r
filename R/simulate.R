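#' Configuration for the synthetic trial generator
#'
#' Bundles every parameter of the generative model with defaults that mirror
#' a single-species conifer provenance trial in a dry lowland region:
#' 11 provenances of 16 trees observed 1970-2010, three drought events
#' (1993, 2000, 2003), a modified negative-exponential age trend, and
#' monthly gamma precipitation of about 500 mm/year with embedded dry
#' spells in the event years.
#'
#' All random effects live on the log scale, so the generative model is
#' conjugate to the log-transformed analysis model: the implied true
#' repeatability of the drought response is
#' \code{r_true = tree_sensitivity_sd^2 / (tree_sensitivity_sd^2 +
#' residual_sd^2)}.
#'
#' @param seed integer seed; identical configurations reproduce identical
#'   data.
#' @param n_provenances,trees_per_provenance trial design counts.
#' @param years calendar years covered by the ring-width series.
#' @param age_trend \code{"negative_exponential"} or \code{"constant"}.
#' @param age_scale_mm,age_decay,age_floor_mm age-trend parameters: expected
#'   width is \code{age_scale_mm * exp(-age_decay * age) + age_floor_mm}.
#' @param provenance_effect_sd sd of provenance-level drought-sensitivity
#'   effects (log scale).
#' @param tree_sensitivity_sd sd of tree-level drought-sensitivity effects
#'   (log scale) -- the additive-genetic signal.
#' @param residual_sd sd of the event-by-tree residual (log scale).
#' @param event_years drought event calendar years.
#' @param event_log_reduction_mean mean log growth reduction in an event
#'   year; the mean drought multiplier is its negative exponential.
#' @param tree_baseline_sd sd of tree-level baseline growth (log scale).
#' @param growth_noise_sd year-to-year lognormal width noise (log scale).
#' @param core_noise_sd core-level lognormal measurement noise (log scale).
#' @param n_stations number of synthetic weather stations.
#' @param site_lat,site_lon trial-site coordinates (decimal degrees).
#' @param precip_shape,precip_scale per-calendar-month gamma parameters of
#'   monthly precipitation (mm).
#' @param spell_months calendar months of the embedded dry spells.
#' @param spell_factor multiplicative precipitation reduction applied in
#'   \code{spell_months} of each event year.
#' @return a validated list of class \code{sim_config}.
#' @export
simulation_config <- function(seed = 1,
                              n_provenances = 11,
                              trees_per_provenance = 16,
                              years = 1970:2010,
                              age_trend = c("negative_exponential", "constant"),
                              age_scale_mm = 2.5,
                              age_decay = 0.04,
                              age_floor_mm = 1.2,
                              provenance_effect_sd = 0.05,
                              tree_sensitivity_sd = 0.10,
                              residual_sd = 0.15,
                              event_years = c(1993, 2000, 2003),
                              event_log_reduction_mean = 0.4,
                              tree_baseline_sd = 0.10,
                              growth_noise_sd = 0.05,
                              core_noise_sd = 0.02,
                              n_stations = 4,
                              site_lat = 48.5,
                              site_lon = 16.2,
                              precip_shape = rep(4, 12),
                              precip_scale = c(7, 7, 9, 11, 13, 15, 15, 13, 11, 9, 7, 7),
                              spell_months = 4:9,
                              spell_factor = 0.3) {
  cfg <- list(seed = as.integer(seed), n_provenances = n_provenances,
              trees_per_provenance = trees_per_provenance, years = years,
              age_trend = match.arg(age_trend), age_scale_mm = age_scale_mm,
              age_decay = age_decay, age_floor_mm = age_floor_mm,
              provenance_effect_sd = provenance_effect_sd,
              tree_sensitivity_sd = tree_sensitivity_sd,
              residual_sd = residual_sd, event_years = event_years,
              event_log_reduction_mean = event_log_reduction_mean,
              tree_baseline_sd = tree_baseline_sd,
              growth_noise_sd = growth_noise_sd, core_noise_sd = core_noise_sd,
              n_stations = n_stations, site_lat = site_lat, site_lon = site_lon,
              precip_shape = precip_shape, precip_scale = precip_scale,
              spell_months = spell_months, spell_factor = spell_factor)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  sds <- c("provenance_effect_sd", "tree_sensitivity_sd", "residual_sd",
           "tree_baseline_sd", "growth_noise_sd", "core_noise_sd")
  for (nm in sds) if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (!all(cfg$event_years %in% cfg$years))
    stop("event_years must lie within years")
  if (any(cfg$precip_shape <= 0) || any(cfg$precip_scale <= 0))
    stop("gamma precipitation parameters must be positive")
  if (length(cfg$precip_shape) != 12 || length(cfg$precip_scale) != 12)
    stop("precip_shape and precip_scale must have length 12")
  if (cfg$n_provenances < 1 || cfg$trees_per_provenance < 1)
    stop("design counts must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Implied true repeatability of a simulation configuration
#'
#' @param config a \code{sim_config}.
#' @return \code{tree_sensitivity_sd^2 / (tree_sensitivity_sd^2 +
#'   residual_sd^2)} (0 when both are 0).
#' @export
true_repeatability <- function(config) {
  a <- config$tree_sensitivity_sd^2
  w <- config$residual_sd^2
  if (a + w == 0) return(0)
  a / (a + w)
}

#' Simulate monthly station precipitation
#'
#' Draws per-calendar-month gamma precipitation for each synthetic station
#' and multiplies \code{spell_months} of each configured event year by
#' \code{spell_factor}, embedding detectable dry spells. Stations sit on a
#' fixed ring around the site.
#'
#' @param config a \code{sim_config}.
#' @return a \code{station_table} (see [read_station_csv()]).
#' @export
simulate_precip <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  offs <- (seq_len(config$n_stations) - 1) * 2 * pi / config$n_stations
  rows <- lapply(seq_len(config$n_stations), function(s) {
    grid <- expand.grid(month = 1:12, year = config$years)[, c("year", "month")]
    p <- stats::rgamma(nrow(grid), shape = config$precip_shape[grid$month],
                       scale = config$precip_scale[grid$month])
    dry <- grid$year %in% config$event_years & grid$month %in% config$spell_months
    p[dry] <- p[dry] * config$spell_factor
    data.frame(station_id = sprintf("ST%02d", s),
               latitude = config$site_lat + 0.2 * sin(offs[s]),
               longitude = config$site_lon + 0.2 * cos(offs[s]),
               year = grid$year, month = grid$month, precip_mm = p,
               stringsAsFactors = FALSE)
  })
  validate_stations(do.call(rbind, rows))
}

#' Simulate a drought-response table directly
#'
#' Generates trait values straight from the random-effects model the
#' analysis assumes: \code{log y = mu + P_prov + A_tree + eps} with
#' independent normal effects, exponentiated to positive resistance- and
#' recovery-like values. This bypasses ring widths and is the reference
#' generator for estimator-recovery tests.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{table} (a \code{response_table} with \code{Res}
#'   and \code{Rec} filled) and \code{truth} (provenance effects, tree
#'   sensitivities per trait, \code{r_true}).
#' @export
simulate_response_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$event_years) < 2)
    stop("need >= 2 events for repeatability testing")
  set.seed(config$seed + 1L)
  np <- config$n_provenances; nt <- config$trees_per_provenance
  ne <- length(config$event_years)
  provs <- sprintf("P%02d", seq_len(np))
  ids <- expand.grid(tree = seq_len(nt), provenance_id = provs,
                     stringsAsFactors = FALSE)
  ids$tree_id <- sprintf("%s_T%02d", ids$provenance_id, ids$tree)
  mu <- c(Res = log(0.7), Rec = log(1.3))
  traits <- c("Res", "Rec")
  eff_p <- stats::setNames(lapply(traits, function(tr)
    stats::setNames(stats::rnorm(np, 0, config$provenance_effect_sd), provs)), traits)
  eff_t <- stats::setNames(lapply(traits, function(tr)
    stats::setNames(stats::rnorm(nrow(ids), 0, config$tree_sensitivity_sd),
                    ids$tree_id)), traits)
  grid <- merge(ids, data.frame(event_year = config$event_years))
  out <- data.frame(site_id = "SIM", provenance_id = grid$provenance_id,
                    tree_id = grid$tree_id, event_year = grid$event_year,
                    I_dr = NA_real_, I_window = NA_real_, I_postdr = NA_real_,
                    Res = NA_real_, Rec = NA_real_, flags = "",
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    eps <- stats::rnorm(nrow(grid), 0, config$residual_sd)
    out[[tr]] <- exp(mu[[tr]] + eff_p[[tr]][grid$provenance_id] +
                       eff_t[[tr]][grid$tree_id] + eps)
  }
  out <- out[order(out$tree_id, out$event_year), ]
  rownames(out) <- NULL
  attr(out, "events") <- sort(unique(out$event_year))
  attr(out, "completeness") <- list(n_records = nrow(out),
                                    n_res_defined = nrow(out),
                                    n_rec_defined = nrow(out),
                                    missing_by_reason = table(character(0)))
  class(out) <- c("response_table", "data.frame")
  list(table = out,
       truth = list(provenance_effects = eff_p, tree_sensitivities = eff_t,
                    r_true = true_repeatability(config), mu = mu))
}

#' Simulate increment-core ring widths for a provenance trial
#'
#' Generates widths from
#' \code{width(t) = G_tree * ageTrend(t) * eventMultiplier(t) * exp(noise)}:
#' a lognormal tree-level growth baseline, a deterministic age trend, a
#' drought multiplier \code{exp(-(reduction + P_prov + A_tree + eps))}
#' in event years (so event multipliers below 1 depress growth), and
#' lognormal year-to-year noise. Two cores per tree are produced with small
#' lognormal core-level noise and averaged into the returned collection.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{collection} (a `tree_collection` of averaged
#'   series), \code{cores} (the raw two-core table), and \code{truth}
#'   (tree sensitivities, provenance effects, per-tree event multipliers,
#'   \code{r_true}).
#' @export
simulate_ring_widths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  np <- config$n_provenances; nt <- config$trees_per_provenance
  yrs <- config$years
  age <- seq_along(yrs) - 1
  trend <- if (config$age_trend == "constant") {
    rep(config$age_floor_mm, length(yrs))
  } else {
    config$age_scale_mm * exp(-config$age_decay * age) + config$age_floor_mm
  }
  provs <- sprintf("P%02d", seq_len(np))
  n_trees <- np * nt
  tids <- sprintf("%s_T%02d", rep(provs, each = nt), rep(seq_len(nt), np))
  tree_prov <- rep(provs, each = nt)
  ny <- length(yrs)
  ev_idx <- match(config$event_years, yrs)
  # fixed-size draw blocks, event residuals last: dropping events leaves
  # every other draw identical under the same seed (counterfactual pairing)
  eff_p <- stats::setNames(stats::rnorm(np, 0, config$provenance_effect_sd), provs)
  G <- exp(stats::rnorm(n_trees, 0, config$tree_baseline_sd))
  A <- stats::setNames(stats::rnorm(n_trees, 0, config$tree_sensitivity_sd), tids)
  noise <- matrix(exp(stats::rnorm(n_trees * ny, 0, config$growth_noise_sd)),
                  nrow = n_trees)
  core_noise <- array(exp(stats::rnorm(2 * n_trees * ny, 0, config$core_noise_sd)),
                      dim = c(n_trees, ny, 2))
  eps <- matrix(stats::rnorm(n_trees * length(ev_idx), 0, config$residual_sd),
                nrow = n_trees)
  rows <- list(); core_rows <- list(); mults <- list()
  for (i in seq_len(n_trees)) {
    tid <- tids[[i]]
    mult <- rep(1, ny)
    if (length(ev_idx))
      mult[ev_idx] <- exp(-(config$event_log_reduction_mean +
                              eff_p[[tree_prov[[i]]]] + A[[tid]] + eps[i, ]))
    mults[[tid]] <- stats::setNames(mult[ev_idx], config$event_years)
    w <- G[[i]] * trend * mult * noise[i, ]
    rows[[tid]] <- data.frame(site_id = "SIM", provenance_id = tree_prov[[i]],
                              tree_id = tid, year = yrs, width_mm = w,
                              stringsAsFactors = FALSE)
    for (cidx in 1:2) {
      core_rows[[paste0(tid, cidx)]] <- data.frame(
        site_id = "SIM", provenance_id = tree_prov[[i]], tree_id = tid,
        core_id = sprintf("%s%s", tid, c("A", "B")[cidx]),
        year = yrs, width_mm = w * core_noise[i, , cidx],
        stringsAsFactors = FALSE)
    }
  }
  sens <- A
  cores <- do.call(rbind, core_rows)
  rownames(cores) <- NULL
  collection <- average_cores(cores)
  list(collection = collection, cores = cores,
       truth = list(tree_sensitivities = sens, provenance_effects = eff_p,
                    event_multipliers = mults,
                    r_true = true_repeatability(config)))
}
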