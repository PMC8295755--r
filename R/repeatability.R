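#' Species-level repeatability of a drought-response trait
#'
#' Fits the nested random-intercept model with provenances and trees as
#' random effects to the log-standardized trait and computes repeatability
#' from the tree and residual components (the provenance component is
#' reported separately): the assumption is a common selection regime across
#' provenances, so tree-level variance within provenances carries the
#' genetic signal.
#'
#' @param table a \code{response_table}.
#' @param trait \code{"Res"} or \code{"Rec"}.
#' @return a \code{repeatability} object with the underlying \code{varcomp}
#'   attached as \code{$components} (including \code{sigma2_provenance}).
#' @export
species_repeatability <- function(table, trait = c("Res", "Rec")) {
  trait <- match.arg(trait)
  d <- defined_records(table, trait)
  if (length(unique(d$provenance_id)) < 2)
    stop("single provenance supplied; use provenance_repeatability()")
  y <- standardize_log(d$value)
  vc <- reml_varcomp(y, d$tree_id, d$provenance_id)
  rep <- repeatability(vc)
  rep$components <- vc
  rep$sigma2_provenance <- vc$sigma2[["provenance"]]
  rep$trait <- trait
  rep
}

#' Provenance-level repeatability of a drought-response trait
#'
#' Fits a univariate tree random-intercept model within each provenance,
#' allowing repeatability to differ where the provenance origins experienced
#' different selection pressures. A provenance is labelled significant when
#' \code{r / se_r} exceeds the two-sided normal criterion.
#'
#' @inheritParams species_repeatability
#' @param provenance_id provenances to fit; default all in the table.
#' @param alpha significance level for the r / se criterion.
#' @return data frame of class \code{provenance_repeatability}: one row per
#'   provenance with \code{r}, \code{se_r}, \code{n_trees}, \code{n_records},
#'   \code{boundary}, \code{significant}, \code{reason} (why missing, when
#'   missing).
#' @export
provenance_repeatability <- function(table, trait = c("Res", "Rec"),
                                     provenance_id = NULL, alpha = 0.05) {
  trait <- match.arg(trait)
  d <- defined_records(table, trait)
  provs <- if (is.null(provenance_id)) sort(unique(d$provenance_id)) else provenance_id
  crit <- stats::qnorm(1 - alpha / 2)
  rows <- lapply(provs, function(p) {
    dp <- d[d$provenance_id == p, ]
    base <- data.frame(provenance_id = p, r = NA_real_, se_r = NA_real_,
                       n_trees = length(unique(dp$tree_id)),
                       n_records = nrow(dp), boundary = NA,
                       significant = NA, reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (length(unique(dp$tree_id)) < 2) {
      base$reason <- "fewer than 2 trees"
      return(base)
    }
    if (max(base::table(dp$tree_id)) < 2) {
      base$reason <- "no repeated records"
      return(base)
    }
    y <- tryCatch(standardize_log(dp$value), error = function(e) NULL)
    if (is.null(y)) {
      base$reason <- "degenerate trait"
      return(base)
    }
    rep <- repeatability(reml_varcomp(y, dp$tree_id))
    base$r <- rep$r
    base$se_r <- rep$se_r
    base$boundary <- rep$boundary
    base$significant <- !rep$boundary && is.finite(rep$se_r) &&
      rep$se_r > 0 && rep$r / rep$se_r > crit
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "alpha") <- alpha
  class(out) <- c("provenance_repeatability", "data.frame")
  out
}

#' @export
print.provenance_repeatability <- function(x, ...) {
  ok <- !is.na(x$significant)
  cat(sprintf("Provenance repeatability (%s): %d of %d provenances significant at alpha = %g\n",
              attr(x, "trait"), sum(x$significant[ok]), nrow(x), attr(x, "alpha")))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

# Defined records of one trait, positive values only, with ids.
defined_records <- function(table, trait) {
  v <- table[[trait]]
  ok <- !is.na(v) & v > 0
  data.frame(provenance_id = table$provenance_id[ok],
             tree_id = table$tree_id[ok],
             event_year = table$event_year[ok],
             value = v[ok], stringsAsFactors = FALSE)
}

#' Evolvability from repeatability and phenotypic variance
#'
#' Repeatability bounds heritability from above, so \code{V_A = r * V_P} is
#' the potential (upper-bound) additive genetic variance and the coefficient
#' of additive genetic variation \code{CV_A = 100 * sqrt(V_A) / mean} is the
#' upper bound of evolvability: a mean-standardized, dimensionless measure
#' of a population's capacity to respond to selection, comparable across
#' traits, provenances and species.
#'
#' @param r repeatability (a number in \code{[0, 1]} or a
#'   \code{repeatability} object).
#' @param V_P phenotypic variance on the raw trait scale.
#' @param trait_mean provenance mean of the raw trait; must be positive.
#' @return list with \code{V_A}, \code{V_P}, \code{trait_mean}, \code{CV_A}
#'   (percent).
#' @export
evolvability <- function(r, V_P, trait_mean) {
  if (inherits(r, "repeatability")) r <- r$r
  if (!is.finite(trait_mean) || trait_mean <= 0)
    stop("trait mean must be positive")
  if (V_P < 0) stop("phenotypic variance must be nonnegative")
  V_A <- r * V_P
  list(V_A = V_A, V_P = V_P, trait_mean = trait_mean,
       CV_A = 100 * sqrt(V_A) / trait_mean)
}

#' Per-provenance evolvability table
#'
#' Combines provenance-level repeatability (on the transformed scale) with
#' the phenotypic variance and mean of the raw trait within each provenance,
#' following the convention that \code{V_P} and the mean are taken on the
#' scale the trait is reported on.
#'
#' @inheritParams species_repeatability
#' @param rep_table optional precomputed [provenance_repeatability()]
#'   result.
#' @return data frame: \code{provenance_id}, \code{r}, \code{se_r},
#'   \code{V_P}, \code{trait_mean}, \code{V_A}, \code{CV_A},
#'   \code{significant}.
#' @export
evolvability_table <- function(table, trait = c("Res", "Rec"),
                               rep_table = NULL) {
  trait <- match.arg(trait)
  if (is.null(rep_table)) rep_table <- provenance_repeatability(table, trait)
  d <- defined_records(table, trait)
  rows <- lapply(seq_len(nrow(rep_table)), function(i) {
    p <- rep_table$provenance_id[[i]]
    v <- d$value[d$provenance_id == p]
    out <- data.frame(provenance_id = p, r = rep_table$r[[i]],
                      se_r = rep_table$se_r[[i]],
                      V_P = stats::var(v), trait_mean = mean(v),
                      V_A = NA_real_, CV_A = NA_real_,
                      significant = rep_table$significant[[i]],
                      stringsAsFactors = FALSE)
    if (is.finite(out$r) && is.finite(out$V_P) && out$trait_mean > 0) {
      ev <- evolvability(out$r, out$V_P, out$trait_mean)
      out$V_A <- ev$V_A
      out$CV_A <- ev$CV_A
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "trait") <- trait
  out
}
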