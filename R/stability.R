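#' Provenance-by-event mean responses
#'
#' @param table a \code{response_table}.
#' @param trait \code{"Res"} or \code{"Rec"}.
#' @return data frame \code{provenance_id}, \code{event_year}, \code{mean},
#'   \code{n} (defined tree records behind the mean).
#' @export
provenance_event_means <- function(table, trait = c("Res", "Rec")) {
  trait <- match.arg(trait)
  v <- table[[trait]]
  ok <- !is.na(v)
  agg <- stats::aggregate(list(mean = v[ok]),
                          by = list(provenance_id = table$provenance_id[ok],
                                    event_year = table$event_year[ok]),
                          FUN = mean)
  n <- stats::aggregate(list(n = v[ok]),
                        by = list(provenance_id = table$provenance_id[ok],
                                  event_year = table$event_year[ok]),
                        FUN = length)
  merge(agg, n, by = c("provenance_id", "event_year"))
}

#' Environmental index for Finlay-Wilkinson regression
#'
#' The baseline drought response of each event: the unweighted mean over
#' provenance means (each provenance mean taken over its trees' defined
#' values). Weighting provenances equally, not trees, keeps unbalanced
#' provenances from dominating the index.
#'
#' @inheritParams provenance_event_means
#' @return data frame \code{event_year}, \code{index}.
#' @export
environmental_index <- function(table, trait = c("Res", "Rec")) {
  trait <- match.arg(trait)
  pm <- provenance_event_means(table, trait)
  events <- sort(unique(table$event_year))
  missing_ev <- setdiff(events, pm$event_year)
  if (length(missing_ev))
    stop("no defined records for event(s): ", paste(missing_ev, collapse = ", "))
  idx <- stats::aggregate(list(index = pm$mean),
                          by = list(event_year = pm$event_year), FUN = mean)
  idx[order(idx$event_year), ]
}

#' Finlay-Wilkinson phenotypic stability regression
#'
#' Each provenance's event means are regressed by ordinary least squares on
#' the environmental index (the all-provenance mean per event). A slope
#' b of about 1 marks average stability: such a provenance tracks whatever
#' the site-wide response is. b > 1 marks instability (above-average response
#' in good events, below-average under strong drought); b < 1 marks
#' above-average stability.
#'
#' @inheritParams provenance_event_means
#' @return data frame of class \code{fw_stability}: \code{provenance_id},
#'   \code{b}, \code{intercept}, \code{n_events}, \code{complete} (whether
#'   the provenance had a defined mean at every event). The index is stored
#'   in \code{attr(, "index")}.
#' @export
fw_regression <- function(table, trait = c("Res", "Rec")) {
  trait <- match.arg(trait)
  idx <- environmental_index(table, trait)
  if (nrow(idx) < 2) stop("need >= 2 events for stability regression")
  if (stats::var(idx$index) == 0) stop("environmental index has zero variance")
  pm <- provenance_event_means(table, trait)
  provs <- sort(unique(pm$provenance_id))
  n_events <- nrow(idx)
  if (n_events < 4)
    warning(sprintf("only %d events: stability slopes are noisy", n_events))
  rows <- lapply(provs, function(p) {
    d <- merge(pm[pm$provenance_id == p, ], idx, by = "event_year")
    if (nrow(d) < 2)
      return(data.frame(provenance_id = p, b = NA_real_, intercept = NA_real_,
                        n_events = nrow(d), complete = FALSE))
    fit <- stats::lm(mean ~ index, data = d)
    data.frame(provenance_id = p, b = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), n_events = nrow(d),
               complete = nrow(d) == n_events)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "index") <- idx
  class(out) <- c("fw_stability", "data.frame")
  out
}

#' @export
print.fw_stability <- function(x, ...) {
  cat(sprintf("Finlay-Wilkinson stability (%s), %d provenances x %d events\n",
              attr(x, "trait"), nrow(x), nrow(attr(x, "index"))))
  print.data.frame(x, ...)
  s <- stability_summary(x$b)
  cat(sprintf("b_dev = %.3f, b_ist = %s\n", s$b_dev,
              if (is.na(s$b_ist)) "NA (no provenance with b > 1)" else sprintf("%.3f", s$b_ist)))
  invisible(x)
}

#' Species-level stability summaries from Finlay-Wilkinson slopes
#'
#' \code{b_dev} is the mean absolute deviation of all provenance slopes from
#' 1. \code{b_ist} summarises only the unstable provenances (b > 1); under
#' the default \code{"deviation"} definition it is their mean deviation from
#' 1, under \code{"mean_b"} it is their mean slope.
#'
#' @param slopes numeric vector of per-provenance slopes b (NAs dropped).
#' @param instability \code{"deviation"} (default) or \code{"mean_b"}.
#' @return list with \code{b_dev}, \code{b_ist} (\code{NA} when no
#'   provenance has b > 1), \code{n}, \code{n_unstable}.
#' @export
stability_summary <- function(slopes, instability = c("deviation", "mean_b")) {
  instability <- match.arg(instability)
  b <- slopes[!is.na(slopes)]
  if (!length(b)) stop("no defined slopes")
  unstable <- b[b > 1]
  b_ist <- if (!length(unstable)) NA_real_
           else if (instability == "deviation") mean(abs(1 - unstable))
           else mean(unstable)
  list(b_dev = mean(abs(1 - b)), b_ist = b_ist,
       n = length(b), n_unstable = length(unstable))
}

#' Rank stability of provenances between drought events
#'
#' Spearman rank correlations of provenance mean responses between every
#' pair of events; ties get average ranks. High correlations mean the
#' provenance ranking is preserved across droughts.
#'
#' @inheritParams provenance_event_means
#' @return symmetric matrix of Spearman correlations, events as dimnames.
#' @export
rank_stability <- function(table, trait = c("Res", "Rec")) {
  trait <- match.arg(trait)
  pm <- provenance_event_means(table, trait)
  wide <- stats::reshape(pm[c("provenance_id", "event_year", "mean")],
                         idvar = "provenance_id", timevar = "event_year",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^mean\\.", "", colnames(m))
  if (nrow(m) < 3)
    warning("fewer than 3 provenances: rank correlations have low power")
  o <- order(as.integer(colnames(m)))
  stats::cor(m[, o, drop = FALSE], method = "spearman",
             use = "pairwise.complete.obs")
}
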