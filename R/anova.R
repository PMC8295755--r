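#' Two-way ANOVA of drought response across species
#'
#' Fixed-effects ANOVA of individual-tree responses with tree species and
#' drought year as crossed factors, allowing for their interaction. With
#' one trial site per species, the species factor is the site factor of the
#' combined response table.
#'
#' @param table a \code{response_table} combined across species/sites.
#' @param trait \code{"Res"} or \code{"Rec"}.
#' @param species species label per record; defaults to \code{site_id}.
#' @return data frame of class \code{anova_table}: \code{term}, \code{df},
#'   \code{F}, \code{p} for species, drought year and their interaction,
#'   plus the residual row.
#' @export
two_way_anova <- function(table, trait = c("Res", "Rec"),
                          species = table$site_id) {
  trait <- match.arg(trait)
  v <- table[[trait]]
  ok <- !is.na(v)
  d <- data.frame(y = v[ok], species = factor(species[ok]),
                  event = factor(table$event_year[ok]))
  if (nlevels(d$species) < 2 || nlevels(d$event) < 2)
    stop("need >= 2 species and >= 2 drought years")
  cells <- base::table(d$species, d$event)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell in species x event grid: %s x %s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  fit <- stats::aov(y ~ species * event, data = d)
  a <- stats::anova(fit)
  out <- data.frame(
    term = c("species", "drought_year", "species:drought_year", "residual"),
    df = a$Df, F = a$`F value`, p = a$`Pr(>F)`)
  attr(out, "fit") <- fit
  attr(out, "trait") <- trait
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (%s):\n", attr(x, "trait")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Pairwise post-hoc comparisons with a compact letter display
#'
#' All pairwise group comparisons by Tukey's honestly significant
#' difference, summarised as letters: groups that share a letter do not
#' differ significantly. Letters are assigned by the insert-and-absorb
#' construction on the significant pairs, with groups ordered by decreasing
#' mean.
#'
#' @param values numeric responses.
#' @param groups group label per response.
#' @param alpha significance level for the Tukey-adjusted p-values.
#' @return named character vector of letter strings, one per group; the
#'   Tukey p-value matrix is attached as \code{attr(, "p_matrix")}.
#' @export
posthoc_letters <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) {
    out <- stats::setNames(rep("a", nlevels(g)), levels(g))
    return(out)
  }
  d <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = d)
  tk <- stats::TukeyHSD(fit)$g
  lev <- levels(g)
  p <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  for (i in seq_len(nrow(tk))) {
    p[pairs[i, 1], pairs[i, 2]] <- p[pairs[i, 2], pairs[i, 1]] <- tk[i, "p adj"]
  }
  means <- tapply(values, g, mean, na.rm = TRUE)
  ord <- names(sort(means, decreasing = TRUE))
  letters_for_groups(p[ord, ord, drop = FALSE] < alpha)
}

# Insert-and-absorb compact letter display from a logical "significantly
# different" matrix (groups in display order).
letters_for_groups <- function(signif_mat) {
  nms <- rownames(signif_mat)
  sets <- list(nms)
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i || !signif_mat[i, j]) next
      for (k in seq_along(sets)) {
        s <- sets[[k]]
        if (all(c(nms[i], nms[j]) %in% s)) {
          sets[[k]] <- setdiff(s, nms[i])
          sets[[length(sets) + 1L]] <- setdiff(s, nms[j])
        }
      }
      # absorb sets fully contained in another
      keep <- rep(TRUE, length(sets))
      for (k in seq_along(sets)) {
        for (l in seq_along(sets)) {
          if (k != l && keep[l] && all(sets[[k]] %in% sets[[l]]) &&
              (length(sets[[k]]) < length(sets[[l]]) || k > l))
            keep[k] <- FALSE
        }
      }
      sets <- sets[keep]
    }
  }
  out <- stats::setNames(rep("", length(nms)), nms)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) out[m] <- paste0(out[m], letters[k])
  }
  out
}

#' Stepwise repeated-measures model selection
#'
#' Repeated drought responses of the same tree are modelled with a tree
#' random intercept; the fixed between-group structure is grown stepwise
#' (intercept, + drought event, + provenance, + drought x provenance) and
#' each step is judged by AIC, log-likelihood and the likelihood-ratio test
#' against the previous model. Fits use maximum likelihood, not REML,
#' because likelihood ratios between models with different fixed effects
#' are only valid under ML.
#'
#' @param table a \code{response_table} for one species.
#' @param trait \code{"Res"} or \code{"Rec"}.
#' @return data frame of class \code{model_comparison}: \code{model},
#'   \code{df} (fixed parameters + variance components), \code{AIC},
#'   \code{logLik}, \code{L_ratio}, \code{p} (each step vs the previous
#'   model). Fitted models are attached as \code{attr(, "fits")}.
#' @export
repeated_measures_selection <- function(table, trait = c("Res", "Rec")) {
  trait <- match.arg(trait)
  d <- defined_records(table, trait)
  if (length(unique(d$event_year)) < 2) stop("need >= 2 drought events")
  if (length(unique(d$provenance_id)) < 2) stop("need >= 2 provenances")
  d$y <- as.numeric(standardize_log(d$value))
  d$drought <- factor(d$event_year)
  d$provenance <- factor(d$provenance_id)
  d$tree <- factor(d$tree_id)
  forms <- list(intercept = y ~ 1,
                drought = y ~ drought,
                provenance = y ~ drought + provenance,
                interaction = y ~ drought * provenance)
  fits <- list()
  for (nm in names(forms)) {
    fit <- tryCatch(
      nlme::lme(forms[[nm]], random = ~ 1 | tree, data = d, method = "ML",
                control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                           msMaxIter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("model '%s' failed to converge: %s; returning partial sequence",
                      nm, conditionMessage(fit)))
      break
    }
    fits[[nm]] <- fit
  }
  if (!length(fits)) stop("no model converged")
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  df <- vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1))
  lr <- c(NA, 2 * diff(ll))
  ddf <- c(NA, diff(df))
  p <- ifelse(is.na(lr), NA, stats::pchisq(lr, ddf, lower.tail = FALSE))
  out <- data.frame(model = names(fits), df = df, AIC = 2 * df - 2 * ll,
                    logLik = ll, L_ratio = lr, p = p)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "trait") <- trait
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Repeated-measures model selection (%s), ML fits:\n",
              attr(x, "trait")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
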