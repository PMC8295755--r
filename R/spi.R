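#' Standardized precipitation index (SPI)
#'
#' Computes the SPI of McKee and colleagues: monthly precipitation is
#' aggregated into backward-looking \code{scale_k}-month sums; for every
#' calendar month a gamma distribution is fitted by maximum likelihood to the
#' positive sums of the calibration window, zero sums are absorbed into a
#' point mass \code{q} at zero, and the mixture cumulative probability
#' \code{H(x) = q + (1 - q) G(x)} is mapped through the standard-normal
#' quantile function. Negative SPI values indicate drier-than-reference
#' conditions in units of standard deviations.
#'
#' The gamma shape is solved from the exact likelihood equation
#' \code{log(shape) - digamma(shape) = log(mean) - mean(log)} by Newton
#' iteration from Thom's closed-form approximation; the point mass uses the
#' plotting-position estimate \code{q = n_zero / (n + 1)} so it stays away
#' from 0 and 1. Calendar months whose calibration sums are all (numerically)
#' equal get SPI 0, the median of a degenerate distribution.
#'
#' @param precip data frame \code{year}, \code{month}, \code{precip_mm} on a
#'   contiguous monthly grid (missing values allowed as \code{NA}).
#' @param scale_k aggregation scale in months (>= 1).
#' @param calibration \code{c(first_year, last_year)} of the reference
#'   window; default the full series.
#' @param min_cal minimum number of defined calibration sums required per
#'   calendar month; months below it are returned missing.
#' @return data frame of class \code{spi_series} with columns \code{year},
#'   \code{month}, \code{spi}; the first \code{scale_k - 1} months and any
#'   window touching missing input are \code{NA}. Per-calendar-month fit
#'   parameters are stored in \code{attr(, "fit")}.
#' @export
spi <- function(precip, scale_k, calibration = NULL, min_cal = 20) {
  stopifnot(scale_k >= 1)
  p <- precip[order(precip$year, precip$month), ]
  mi <- p$year * 12L + (p$month - 1L)
  if (any(diff(mi) != 1L)) stop("precipitation grid not contiguous monthly")
  if (is.null(calibration)) calibration <- range(p$year)
  x <- p$precip_mm
  n <- length(x)
  sums <- rep(NA_real_, n)
  if (n >= scale_k) {
    cs <- cumsum(ifelse(is.na(x), 0, x))
    nb <- cumsum(is.na(x))
    idx <- scale_k:n
    prev <- c(0, cs)[idx - scale_k + 1L]
    prevb <- c(0, nb)[idx - scale_k + 1L]
    s <- cs[idx] - prev
    nbad <- nb[idx] - prevb
    sums[idx[nbad == 0]] <- s[nbad == 0]
  }
  out_spi <- rep(NA_real_, n)
  fits <- vector("list", 12)
  for (cm in 1:12) {
    sel <- which(p$month == cm)
    cal <- sel[p$year[sel] >= calibration[1] & p$year[sel] <= calibration[2]]
    cal_sums <- sums[cal]
    cal_sums <- cal_sums[!is.na(cal_sums)]
    nc <- length(cal_sums)
    if (nc < min_cal) {
      warning(sprintf("calendar month %d: only %d calibration sums (< %d); SPI left missing",
                      cm, nc, min_cal))
      fits[[cm]] <- list(n = nc, degenerate = NA)
      next
    }
    if (stats::sd(cal_sums) < 1e-8 * max(mean(cal_sums), 1)) {
      out_spi[sel][!is.na(sums[sel])] <- 0
      fits[[cm]] <- list(n = nc, degenerate = TRUE)
      next
    }
    nzero <- sum(cal_sums == 0)
    q <- nzero / (nc + 1)
    pos <- cal_sums[cal_sums > 0]
    fit <- gamma_fit_ml(pos)
    g <- stats::pgamma(sums[sel], shape = fit$shape, scale = fit$scale)
    h <- ifelse(sums[sel] > 0, q + (1 - q) * g, q)
    lo_clamp <- 1 / (2 * (nc + 1))
    h <- pmin(pmax(h, lo_clamp), 1 - lo_clamp)
    out_spi[sel] <- ifelse(is.na(sums[sel]), NA_real_, stats::qnorm(h))
    fits[[cm]] <- list(n = nc, degenerate = FALSE, q = q,
                       shape = fit$shape, scale = fit$scale)
  }
  out <- data.frame(year = p$year, month = p$month, spi = out_spi)
  attr(out, "scale_k") <- as.integer(scale_k)
  attr(out, "calibration") <- calibration
  attr(out, "fit") <- fits
  class(out) <- c("spi_series", "data.frame")
  out
}

# Exact gamma ML: solve log(a) - digamma(a) = log(mean) - mean(log) by Newton
# from Thom's starting value; scale = mean/shape.
gamma_fit_ml <- function(x, tol = 1e-12, max_iter = 100) {
  if (length(x) < 2) stop("need >= 2 positive values for gamma fit")
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (s <= 0) s <- .Machine$double.eps  # numerically constant data guard
  a <- (1 + sqrt(1 + 4 * s / 3)) / (4 * s)
  for (i in seq_len(max_iter)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * a) {
      a <- a_new
      break
    }
    a <- a_new
  }
  list(shape = a, scale = m / a)
}

#' Classify SPI drought severity
#'
#' Thresholds (strict inequalities): moderate below -1, severe below -1.5,
#' extreme below -2.
#'
#' @param spi_value numeric vector of SPI values.
#' @return character vector in \code{none < moderate < severe < extreme};
#'   \code{NA} stays \code{NA}.
#' @export
classify_severity <- function(spi_value) {
  out <- rep(NA_character_, length(spi_value))
  ok <- is.finite(spi_value)
  out[ok] <- "none"
  out[ok & spi_value < -1] <- "moderate"
  out[ok & spi_value < -1.5] <- "severe"
  out[ok & spi_value < -2] <- "extreme"
  out
}

#' Identify drought years from SPI series
#'
#' A calendar year is flagged when any month of \code{month_window} at any of
#' the requested scales falls below \code{threshold}; its severity is the
#' class of the year's minimum SPI over those months and scales. Site-level
#' drought selection in practice is curated by inspection, so an explicit
#' \code{events} list overrides detection and is passed through verbatim
#' (severity still annotated from the SPI where available).
#'
#' @param spi_set named list of \code{spi_series}, names = scale in months.
#' @param threshold SPI threshold (default -1.5, "severe").
#' @param scales scales (months) to consult; default 1 and 3.
#' @param month_window calendar months to scan; default April-September.
#' @param events optional curated event years overriding detection.
#' @return data frame \code{event_year}, \code{severity}, \code{min_spi},
#'   \code{source} (\code{"detected"} or \code{"curated"}).
#' @export
detect_drought_years <- function(spi_set, threshold = -1.5, scales = c(1, 3),
                                 month_window = 4:9, events = NULL) {
  if (!length(scales)) stop("empty scales set")
  have <- vapply(spi_set, function(s) attr(s, "scale_k"), integer(1))
  if (!all(scales %in% have))
    stop("requested scales not present: ",
         paste(setdiff(scales, have), collapse = ", "))
  use <- spi_set[match(scales, have)]
  all_years <- sort(unique(unlist(lapply(use, function(s) s$year))))
  year_min <- vapply(all_years, function(y) {
    v <- unlist(lapply(use, function(s)
      s$spi[s$year == y & s$month %in% month_window]))
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else min(v)
  }, numeric(1))
  names(year_min) <- all_years
  if (!is.null(events)) {
    mn <- year_min[as.character(events)]
    return(data.frame(event_year = as.integer(events),
                      severity = classify_severity(unname(mn)),
                      min_spi = unname(mn), source = "curated",
                      stringsAsFactors = FALSE))
  }
  hit <- which(!is.na(year_min) & year_min < threshold)
  data.frame(event_year = as.integer(all_years[hit]),
             severity = classify_severity(unname(year_min[hit])),
             min_spi = unname(year_min[hit]),
             source = rep("detected", length(hit)),
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two sites' SPI series
#'
#' Computed over the jointly defined months; used to check that drought
#' occurrence coincides across trial sites.
#'
#' @param a,b two \code{spi_series} at the same scale.
#' @return Pearson correlation, or \code{NA} when either series has zero
#'   variance over the overlap.
#' @export
spi_site_correlation <- function(a, b) {
  ka <- attr(a, "scale_k"); kb <- attr(b, "scale_k")
  if (!is.null(ka) && !is.null(kb) && ka != kb)
    stop("SPI series have different scales")
  m <- merge(a[c("year", "month", "spi")], b[c("year", "month", "spi")],
             by = c("year", "month"))
  ok <- is.finite(m$spi.x) & is.finite(m$spi.y)
  if (sum(ok) < 3) stop("fewer than 3 jointly defined months")
  if (stats::sd(m$spi.x[ok]) == 0 || stats::sd(m$spi.y[ok]) == 0) {
    warning("zero variance in an SPI series; correlation undefined")
    return(NA_real_)
  }
  stats::cor(m$spi.x[ok], m$spi.y[ok])
}
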