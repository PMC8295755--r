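#' Read a Tucson (rwl) ring-width file
#'
#' Parses the decadal Tucson format used by tree-ring measurement software.
#' Each text row carries a series (core) identifier in the first eight
#' characters, the calendar year of the first value on the row, and up to ten
#' ring widths. Two unit dialects circulate in the community and are
#' distinguished only by the end-of-series marker: files ending a series with
#' \code{999} store hundredths of a millimetre, files ending with \code{-9999}
#' store thousandths.
#'
#' @param source path to an rwl file, or a character vector of its lines.
#' @param dialect \code{"auto"} (detect per series from the terminator),
#'   \code{"0.01mm"} or \code{"0.001mm"}.
#' @return a data frame of class \code{core_table} with columns
#'   \code{core_id}, \code{year}, \code{width_mm}. Width 0 encodes a locally
#'   missing ring and is retained.
#' @examples
#' txt <- c("CORE1A  1990   100   200   999")
#' read_rwl(txt)
#' @export
read_rwl <- function(source, dialect = c("auto", "0.01mm", "0.001mm")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_core_table())
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1L, 8L))
    rest <- strsplit(trimws(substr(ln, 9L, nchar(ln))), "\\s+")[[1]]
    if (!nzchar(id) || length(rest) < 2L)
      stop(sprintf("rwl parse error at line %d: expected <id> <decade year> <values>", i))
    year0 <- suppressWarnings(as.integer(rest[[1]]))
    vals <- suppressWarnings(as.numeric(rest[-1]))
    if (is.na(year0) || anyNA(vals))
      stop(sprintf("rwl parse error at line %d: malformed decade header or value", i))
    recs[[i]] <- list(id = id, year0 = year0, vals = vals)
  }
  ids <- vapply(recs, `[[`, "", "id")
  out <- lapply(unique(ids), function(id) {
    rows <- recs[ids == id]
    years <- integer(0)
    raw <- numeric(0)
    terminated <- FALSE
    term <- NA_real_
    for (r in rows) {
      if (terminated)
        stop(sprintf("core %s: data after series terminator", id))
      v <- r$vals
      stop_at <- which(v == 999 | v == -9999)
      if (length(stop_at)) {
        term <- v[stop_at[[1]]]
        v <- v[seq_len(stop_at[[1]] - 1L)]
        terminated <- TRUE
      }
      if (length(v)) {
        yrs <- r$year0 + seq_along(v) - 1L
        if (length(years) && yrs[[1]] != years[[length(years)]] + 1L)
          stop(sprintf("core %s: non-consecutive years (%d after %d)",
                       id, yrs[[1]], years[[length(years)]]))
        years <- c(years, yrs)
        raw <- c(raw, v)
      }
    }
    div <- switch(dialect,
      "0.01mm"  = 100,
      "0.001mm" = 1000,
      "auto" = if (!is.na(term) && term == -9999) 1000 else 100)
    data.frame(core_id = id, year = years, width_mm = raw / div,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$width_mm < 0))
    stop("negative ring width after unit conversion; wrong dialect?")
  rownames(out) <- NULL
  class(out) <- c("core_table", "data.frame")
  out
}

empty_core_table <- function() {
  out <- data.frame(core_id = character(0), year = integer(0),
                    width_mm = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("core_table", "data.frame")
  out
}

#' Write ring-width series to a Tucson (rwl) file
#'
#' Inverse of [read_rwl()]: decadal rows, 8-character identifier field,
#' series terminated by \code{999} (0.01 mm dialect) or \code{-9999}
#' (0.001 mm dialect).
#'
#' @param cores data frame with columns \code{core_id}, \code{year},
#'   \code{width_mm}.
#' @param path output file path.
#' @param dialect storage unit, \code{"0.01mm"} or \code{"0.001mm"}.
#' @return \code{path}, invisibly.
#' @export
write_rwl <- function(cores, path, dialect = c("0.01mm", "0.001mm")) {
  dialect <- match.arg(dialect)
  mult <- if (dialect == "0.01mm") 100 else 1000
  term <- if (dialect == "0.01mm") 999 else -9999
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(cores$core_id)) {
    s <- cores[cores$core_id == id, ]
    s <- s[order(s$year), ]
    if (any(diff(s$year) != 1L))
      stop(sprintf("core %s: years not consecutive", id))
    vals <- as.integer(round(s$width_mm * mult))
    years <- s$year
    i <- 1L
    while (i <= length(vals)) {
      decade_end <- (years[[i]] %/% 10L) * 10L + 9L
      j <- min(which(years > decade_end) - 1L, length(vals))
      if (!length(j) || is.infinite(j)) j <- length(vals)
      row_vals <- vals[i:j]
      last_row <- j == length(vals)
      if (last_row) row_vals <- c(row_vals, term)
      writeLines(sprintf("%-8s%5d%s", substr(id, 1L, 8L), years[[i]],
                         paste0(sprintf("%6d", row_vals), collapse = "")), con)
      i <- j + 1L
    }
  }
  invisible(path)
}

#' Read ring widths from long-form CSV
#'
#' Column contract: \code{site_id}, \code{provenance_id}, \code{tree_id},
#' \code{core_id}, \code{year}, \code{width_mm}.
#'
#' @param path CSV file path.
#' @return a \code{core_table} data frame carrying the id columns.
#' @export
read_ring_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "provenance_id", "tree_id", "core_id", "year", "width_mm")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop("ring CSV missing columns: ", paste(missing_cols, collapse = ", "))
  validate_core_years(out)
  class(out) <- c("core_table", "data.frame")
  out
}

validate_core_years <- function(cores) {
  for (id in unique(cores$core_id)) {
    yrs <- sort(cores$year[cores$core_id == id])
    if (any(diff(yrs) != 1L))
      stop(sprintf("core %s: years not strictly consecutive", id))
  }
  if (any(cores$width_mm < 0, na.rm = TRUE)) stop("negative ring widths")
  invisible(cores)
}

#' Average increment cores into single-tree series
#'
#' Radial growth is usually measured on two cores per tree; averaging them
#' reduces non-climatic noise such as reaction wood. Years covered by only
#' one core keep that core's value; years covered by none are absent from the
#' output. Any number of cores per tree is accepted.
#'
#' @param cores data frame with columns \code{tree_id}, \code{core_id},
#'   \code{year}, \code{width_mm}; optional \code{provenance_id},
#'   \code{site_id} must be constant within a tree.
#' @return a `tree_collection`: long data frame with one averaged series per
#'   tree (columns \code{site_id}, \code{provenance_id}, \code{tree_id},
#'   \code{year}, \code{width_mm}).
#' @export
average_cores <- function(cores) {
  if (!nrow(cores)) stop("no cores supplied")
  if (is.null(cores$tree_id)) stop("cores need a tree_id column")
  if (is.null(cores$provenance_id)) cores$provenance_id <- NA_character_
  if (is.null(cores$site_id)) cores$site_id <- NA_character_
  pieces <- lapply(split(cores, cores$tree_id), function(s) {
    prov <- unique(s$provenance_id)
    site <- unique(s$site_id)
    if (length(prov) > 1L)
      stop(sprintf("tree %s: conflicting provenance labels (%s)",
                   s$tree_id[[1]], paste(prov, collapse = ", ")))
    if (length(site) > 1L)
      stop(sprintf("tree %s: conflicting site labels", s$tree_id[[1]]))
    m <- tapply(s$width_mm, s$year, mean, na.rm = TRUE)
    yrs <- as.integer(names(m))
    o <- order(yrs)
    data.frame(site_id = site, provenance_id = prov, tree_id = s$tree_id[[1]],
               year = yrs[o], width_mm = as.numeric(m)[o],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  as_tree_collection(out)
}

#' Assemble a tree collection
#'
#' A `tree_collection` is the per-tree ring-width table used by every
#' downstream stage: one averaged series per tree, each tree belonging to
#' exactly one provenance and site.
#'
#' @param series long data frame with columns \code{site_id},
#'   \code{provenance_id}, \code{tree_id}, \code{year}, \code{width_mm}.
#' @return the validated data frame with class \code{tree_collection}.
#' @export
as_tree_collection <- function(series) {
  need <- c("site_id", "provenance_id", "tree_id", "year", "width_mm")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols))
    stop("tree collection missing columns: ", paste(missing_cols, collapse = ", "))
  prov_per_tree <- tapply(series$provenance_id, series$tree_id,
                          function(p) length(unique(p)))
  if (any(prov_per_tree > 1L))
    stop("trees mapped to more than one provenance: ",
         paste(names(prov_per_tree)[prov_per_tree > 1L], collapse = ", "))
  if (any(series$width_mm < 0, na.rm = TRUE)) stop("negative ring widths")
  series <- series[order(series$tree_id, series$year), ]
  rownames(series) <- NULL
  class(series) <- c("tree_collection", "data.frame")
  series
}

#' @export
print.tree_collection <- function(x, ...) {
  cat(sprintf("Tree collection: %d trees, %d provenances, years %d-%d\n",
              length(unique(x$tree_id)), length(unique(x$provenance_id)),
              min(x$year), max(x$year)))
  invisible(x)
}

#' Extract one tree's series from a collection
#'
#' @param collection a `tree_collection`.
#' @param tree_id tree identifier.
#' @return data frame with that tree's rows, years ascending.
#' @export
tree_series <- function(collection, tree_id) {
  s <- collection[collection$tree_id == tree_id, , drop = FALSE]
  if (!nrow(s)) stop(sprintf("tree %s not in collection", tree_id))
  s[order(s$year), ]
}
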