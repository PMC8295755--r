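#' Lloret resistance of a tree to a drought event
#'
#' Resistance is the ratio of the annual increment in the drought year
#' (\code{I_dr}) to the mean increment over a window of \code{window} years
#' centred on the event (\code{I_9yr} for the default 9): \code{Res = I_dr /
#' I_9yr}. A value of 1 means no deviation from the reference growth level;
#' smaller values mean stronger growth reduction. Computed on raw,
#' untransformed widths: the age-related growth trend is negligible over a
#' 9-year frame, and dimensional transforms would distort downstream variance
#' components.
#'
#' @param series one tree's rows of a `tree_collection` (columns \code{year},
#'   \code{width_mm}).
#' @param event_year drought calendar year.
#' @param window odd window length in years centred on the event; the event
#'   year itself is included in the mean unless \code{include_event = FALSE}.
#' @param include_event include the drought year in the window mean.
#' @return list with \code{I_dr}, \code{I_window} (the window mean),
#'   \code{Res}, and \code{reason} (\code{NA} when defined; otherwise why
#'   the value is missing).
#' @export
resistance <- function(series, event_year, window = 9, include_event = TRUE) {
  if (window %% 2 == 0) stop("window must be odd")
  half <- (window - 1) / 2
  yrs <- (event_year - half):(event_year + half)
  w <- series$width_mm[match(yrs, series$year)]
  miss <- list(I_dr = NA_real_, I_window = NA_real_, Res = NA_real_)
  if (anyNA(w))
    return(c(miss, reason = "incomplete window"))
  i_dr <- w[half + 1]
  i_win <- if (include_event) mean(w) else mean(w[-(half + 1)])
  if (i_win == 0)
    return(c(miss, reason = "degenerate: zero window mean"))
  list(I_dr = i_dr, I_window = i_win, Res = i_dr / i_win, reason = NA_character_)
}

#' Lloret recovery of a tree after a drought event
#'
#' Recovery is the ratio of the mean increment over the \code{post_window}
#' years following the drought (\code{I_postdr}, default 2 years) to the
#' drought-year increment: \code{Rec = I_postdr / I_dr}. Higher recovery
#' means faster revitalisation.
#'
#' @inheritParams resistance
#' @param post_window number of post-event years averaged.
#' @return list with \code{I_dr}, \code{I_postdr}, \code{Rec},
#'   \code{reason}.
#' @export
recovery <- function(series, event_year, post_window = 2) {
  yrs <- (event_year + 1):(event_year + post_window)
  i_dr <- series$width_mm[match(event_year, series$year)]
  w <- series$width_mm[match(yrs, series$year)]
  miss <- list(I_dr = NA_real_, I_postdr = NA_real_, Rec = NA_real_)
  if (is.na(i_dr) || anyNA(w))
    return(c(miss, reason = "incomplete post window"))
  if (i_dr == 0)
    return(list(I_dr = i_dr, I_postdr = mean(w), Rec = NA_real_,
                reason = "degenerate: zero drought-year increment"))
  list(I_dr = i_dr, I_postdr = mean(w), Rec = mean(w) / i_dr,
       reason = NA_character_)
}

#' Per-tree drought-response table
#'
#' Attempts one resistance and recovery record per tree and configured
#' drought event. Event years may differ between sites (consecutive dry
#' years can hit species a year apart), so \code{events} is either a single
#' vector applied to every site or a named list keyed by \code{site_id}.
#' Records whose post-drought window contains another configured event are
#' flagged \code{biased}: their recovery mixes in the next drought and
#' overestimates revitalisation.
#'
#' @param collection a `tree_collection`.
#' @param events integer vector of event years, or named list per site.
#' @param window,post_window window lengths passed to [resistance()] and
#'   [recovery()].
#' @param include_event passed to [resistance()].
#' @return data frame of class \code{response_table}: one row per tree x
#'   event with columns \code{site_id}, \code{provenance_id}, \code{tree_id},
#'   \code{event_year}, \code{I_dr}, \code{I_window}, \code{I_postdr},
#'   \code{Res}, \code{Rec}, \code{flags}. A completeness report (counts of
#'   missing values by reason) is stored in \code{attr(, "completeness")}.
#' @export
compute_response_table <- function(collection, events, window = 9,
                                   post_window = 2, include_event = TRUE) {
  if (!length(events)) stop("events must be nonempty")
  trees <- split(as.data.frame(collection), collection$tree_id)
  rows <- list()
  for (s in trees) {
    site <- s$site_id[[1]]
    evs <- if (is.list(events)) {
      if (is.null(events[[site]])) stop(sprintf("no events configured for site %s", site))
      events[[site]]
    } else events
    evs <- sort(as.integer(evs))
    for (ev in evs) {
      res <- resistance(s, ev, window = window, include_event = include_event)
      rec <- recovery(s, ev, post_window = post_window)
      flags <- character(0)
      if (!is.na(res$reason)) flags <- c(flags, paste0("Res:", res$reason))
      if (!is.na(rec$reason)) flags <- c(flags, paste0("Rec:", rec$reason))
      if (any((ev + seq_len(post_window)) %in% setdiff(evs, ev)))
        flags <- c(flags, "biased")
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site, provenance_id = s$provenance_id[[1]],
        tree_id = s$tree_id[[1]], event_year = ev,
        I_dr = res$I_dr, I_window = res$I_window, I_postdr = rec$I_postdr,
        Res = res$Res, Rec = rec$Rec,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  reasons <- unlist(strsplit(out$flags[nzchar(out$flags)], ";"))
  attr(out, "completeness") <- list(
    n_records = nrow(out),
    n_res_defined = sum(!is.na(out$Res)),
    n_rec_defined = sum(!is.na(out$Rec)),
    missing_by_reason = if (length(reasons)) table(reasons) else table(character(0)))
  attr(out, "events") <- sort(unique(out$event_year))
  class(out) <- c("response_table", "data.frame")
  out
}

#' @export
print.response_table <- function(x, ...) {
  cp <- attr(x, "completeness")
  cat(sprintf("Drought-response table: %d tree x event records (%d Res, %d Rec defined), events %s\n",
              cp$n_records, cp$n_res_defined, cp$n_rec_defined,
              paste(attr(x, "events"), collapse = ", ")))
  invisible(x)
}

#' Write a response table as tidy CSV
#'
#' @param table a \code{response_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_response_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
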