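# Shared fixture builders: everything is generated in code at test time.

# Minimal response table from an explicit provenance x event matrix of
# means; one tree per provenance unless trees_per_prov > 1, in which case
# per-tree values are mean + offsets (supplied or zero).
make_response_table <- function(means, events = seq_len(ncol(means)),
                                trees_per_prov = 1, offsets = NULL) {
  np <- nrow(means)
  provs <- sprintf("P%02d", seq_len(np))
  rows <- list()
  for (i in seq_len(np)) {
    for (t in seq_len(trees_per_prov)) {
      off <- if (is.null(offsets)) 0 else offsets[[i]][[t]]
      for (j in seq_along(events)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = "S", provenance_id = provs[i],
          tree_id = sprintf("%s_T%02d", provs[i], t),
          event_year = events[j], I_dr = NA_real_, I_window = NA_real_,
          I_postdr = NA_real_, Res = means[i, j] + off,
          Rec = means[i, j] + off, flags = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "events") <- sort(unique(out$event_year))
  class(out) <- c("response_table", "data.frame")
  out
}

# One tree's ring series as used by resistance()/recovery().
make_series <- function(years, widths) {
  data.frame(site_id = "S", provenance_id = "P01", tree_id = "T1",
             year = years, width_mm = widths, stringsAsFactors = FALSE)
}

# Balanced one-way repeated-measures data with known components.
make_one_way <- function(n_groups, k, s2a, s2w, seed) {
  set.seed(seed)
  g <- rep(sprintf("g%03d", seq_len(n_groups)), each = k)
  y <- rep(stats::rnorm(n_groups, 0, sqrt(s2a)), each = k) +
    stats::rnorm(n_groups * k, 0, sqrt(s2w))
  list(y = y, g = g)
}

# Closed-form balanced one-way ANOVA estimators (the REML oracle on
# balanced data with an interior optimum).
anova_components <- function(y, g) {
  k <- unique(table(g))
  stopifnot(length(k) == 1)
  m <- tapply(y, g, mean)
  msa <- k * stats::var(m)
  msw <- sum((y - m[g])^2) / (length(m) * (k - 1))
  c(tree = (msa - msw) / k, residual = msw)
}

# Monthly gamma precipitation data frame on a year range.
make_precip <- function(years, shape = 4, scale = 12, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  grid <- grid[order(grid$year, grid$month), ]
  data.frame(grid, precip_mm = stats::rgamma(nrow(grid), shape = shape,
                                             scale = scale))
}

# Independent brute-force SPI oracle: separate aggregation loop, gamma fit
# by direct likelihood maximisation (Brent on log-shape), mixture quantile.
spi_oracle <- function(p, k) {
  x <- p$precip_mm
  n <- length(x)
  sums <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i >= k && !anyNA(x[(i - k + 1):i])) sums[i] <- sum(x[(i - k + 1):i])
  }
  out <- rep(NA_real_, n)
  for (cm in 1:12) {
    sel <- which(p$month == cm)
    cal <- sums[sel]
    cal <- cal[!is.na(cal)]
    q <- sum(cal == 0) / (length(cal) + 1)
    pos <- cal[cal > 0]
    nll <- function(la) {
      -sum(stats::dgamma(pos, shape = exp(la), scale = mean(pos) / exp(la),
                         log = TRUE))
    }
    la <- stats::optim(0, nll, method = "Brent", lower = -12, upper = 12,
                       control = list(reltol = 1e-15))$par
    sh <- exp(la)
    sc <- mean(pos) / sh
    h <- q + (1 - q) * stats::pgamma(sums[sel], shape = sh, scale = sc)
    lo <- 1 / (2 * (length(cal) + 1))
    h <- pmin(pmax(h, lo), 1 - lo)
    out[sel] <- ifelse(is.na(sums[sel]), NA, stats::qnorm(h))
  }
  out
}
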