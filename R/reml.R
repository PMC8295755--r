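#' Standardize drought-response values on the log scale
#'
#' Natural log followed by centering to mean 0 and scaling to sample
#' standard deviation 1 (divisor n - 1). Drought-response ratios are
#' positive and right-skewed; the log brings them close to normal, which the
#' downstream Gaussian mixed models assume. The transform constants are
#' recorded so the mapping is invertible.
#'
#' @param values positive numeric vector (degenerate records must be
#'   excluded upstream).
#' @return numeric vector with mean 0 and sample sd 1; attributes
#'   \code{center} and \code{scale} hold the constants applied after the
#'   log.
#' @export
standardize_log <- function(values) {
  if (any(!is.finite(values)))
    stop("nonfinite values at positions: ",
         paste(which(!is.finite(values)), collapse = ", "))
  if (any(values <= 0))
    stop("nonpositive values at positions: ",
         paste(which(values <= 0), collapse = ", "))
  lv <- log(values)
  s <- stats::sd(lv)
  if (!is.finite(s) || s < .Machine$double.eps^0.5)
    stop("degenerate trait: zero variance after log transform")
  out <- (lv - mean(lv)) / s
  attr(out, "center") <- mean(lv)
  attr(out, "scale") <- s
  out
}

# Sufficient statistics for the one-way random-intercept model.
one_way_stats <- function(y, group) {
  g <- split(y, group)
  n_i <- vapply(g, length, integer(1))
  ybar <- vapply(g, mean, numeric(1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  list(n_i = n_i, ybar = ybar, ssw = ssw, N = sum(n_i), a = length(g))
}

# Profiled restricted log-likelihood pieces at variance ratio
# gamma = sigma2_between / sigma2_within.
one_way_profile <- function(gamma, st) {
  den <- 1 + gamma * st$n_i
  w <- st$n_i / den
  mu <- sum(w * st$ybar) / sum(w)
  d <- st$ybar - mu
  Q <- st$ssw + sum(st$n_i * d^2 / den)
  s2w <- Q / (st$N - 1)
  ll <- -0.5 * ((st$N - 1) * (log(s2w) + 1 + log(2 * pi)) +
                  sum(log(den)) + log(sum(w)))
  list(mu = mu, Q = Q, s2w = s2w, loglik = ll, w = w, d = d, den = den)
}

# Analytic derivative of the profiled restricted log-likelihood w.r.t.
# gamma (envelope theorem: mu is the GLS minimiser of Q).
one_way_score <- function(gamma, st) {
  pr <- one_way_profile(gamma, st)
  dQ <- -sum(st$n_i^2 * pr$d^2 / pr$den^2)
  dsumw <- -sum(st$n_i^2 / pr$den^2)
  -0.5 * ((st$N - 1) * dQ / pr$Q + sum(st$n_i / pr$den) + dsumw / sum(pr$w))
}

# Unprofiled restricted log-likelihood as a function of the variance
# components themselves (used for the observed-information matrix).
one_way_loglik <- function(theta, st) {
  a <- theta[1]; w <- theta[2]
  if (w <= 0) return(-Inf)
  gamma <- max(a, 0) / w
  den <- 1 + gamma * st$n_i
  wt <- st$n_i / den
  mu <- sum(wt * st$ybar) / sum(wt)
  Q <- st$ssw + sum(st$n_i * (st$ybar - mu)^2 / den)
  -0.5 * ((st$N - 1) * (log(w) + log(2 * pi)) + sum(log(den)) +
            log(sum(wt)) + Q / w)
}

#' REML variance components of tree random-intercept models
#'
#' Fits the random-intercept model underlying repeatability estimation by
#' restricted maximum likelihood. With only \code{tree} given, the model is
#' the one-way layout \code{y = mu + A_tree + e}; the restricted likelihood
#' is profiled down to the single variance ratio
#' \code{gamma = sigma2_A / sigma2_W} and the score equation is solved
#' exactly (closed-form profile, analytic derivative, root bracketing), so
#' balanced interior optima reproduce the classical mean-squares estimators
#' to numerical precision. With \code{provenance} given, trees are nested in
#' provenances (\code{y = mu + P_prov + A_tree + e}) and the profiled
#' restricted likelihood over the two variance ratios is maximised
#' quasi-Newton on the log-ratio scale from three deterministic starts,
#' using dense per-provenance blocks.
#'
#' Negative component estimates are truncated at zero and flagged as
#' boundary estimates. The asymptotic covariance of the components is the
#' inverse observed-information matrix (central finite differences of the
#' restricted log-likelihood at the optimum).
#'
#' @param y numeric response (typically [standardize_log()]-transformed).
#' @param tree tree identifier per observation (the repeated-measures
#'   group).
#' @param provenance optional provenance identifier per observation for the
#'   nested two-component model.
#' @return object of class \code{varcomp}: list with \code{sigma2} (named
#'   vector: optionally \code{provenance}, then \code{tree},
#'   \code{residual}), \code{loglik} (restricted), \code{vcov},
#'   \code{boundary} (named logical), \code{n_groups}, \code{n_obs},
#'   \code{method = "REML"}.
#' @export
reml_varcomp <- function(y, tree, provenance = NULL) {
  keep <- is.finite(y)
  y <- y[keep]; tree <- as.character(tree)[keep]
  if (!is.null(provenance)) provenance <- as.character(provenance)[keep]
  if (length(unique(tree)) < 2) stop("need >= 2 trees")
  if (max(table(tree)) < 2) stop("need repeated observations for >= 1 tree")
  if (is.null(provenance)) reml_one_way(y, tree) else reml_nested(y, tree, provenance)
}

reml_one_way <- function(y, group) {
  st <- one_way_stats(y, group)
  gamma_cap <- 1e12
  s0 <- one_way_score(0, st)
  boundary <- c(tree = FALSE, residual = FALSE)
  if (s0 <= 0) {
    gamma_hat <- 0
    boundary["tree"] <- TRUE
  } else {
    hi <- 1
    while (one_way_score(hi, st) > 0 && hi < gamma_cap) hi <- hi * 4
    if (hi >= gamma_cap) {
      gamma_hat <- gamma_cap  # no within-group variance: residual at boundary
      boundary["residual"] <- TRUE
    } else {
      gamma_hat <- stats::uniroot(one_way_score, c(0, hi), st = st,
                                  tol = .Machine$double.eps^0.75)$root
    }
  }
  pr <- one_way_profile(gamma_hat, st)
  s2w <- pr$s2w
  s2a <- gamma_hat * s2w
  theta <- c(tree = s2a, residual = s2w)
  V <- observed_info_cov(function(th) one_way_loglik(th, st), theta)
  structure(list(sigma2 = theta, loglik = pr$loglik, vcov = V,
                 boundary = boundary, n_groups = c(tree = st$a),
                 n_obs = st$N, method = "REML"),
            class = "varcomp")
}

# Restricted log-likelihood of the nested (provenance/tree) model, computed
# from dense per-provenance blocks: Vtilde_j = I + g_t * J_trees + g_p * J.
nested_loglik_pieces <- function(g_p, g_t, blocks) {
  logdet <- 0; xtvx <- 0; xtvy <- 0; ytvy <- 0
  for (b in blocks) {
    n <- length(b$y)
    Vt <- diag(n) + g_t * b$ZZt + g_p
    ch <- tryCatch(chol(Vt), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    sol <- backsolve(ch, forwardsolve(t(ch), cbind(1, b$y)))
    xtvx <- xtvx + sum(sol[, 1])
    xtvy <- xtvy + sum(sol[, 2] * 1)
    ytvy <- ytvy + sum(b$y * sol[, 2])
  }
  Q <- ytvy - xtvy^2 / xtvx
  list(logdet = logdet, xtvx = xtvx, Q = Q)
}

nested_profile_loglik <- function(g_p, g_t, blocks, N) {
  p <- nested_loglik_pieces(g_p, g_t, blocks)
  if (is.null(p) || p$Q <= 0) return(-Inf)
  s2w <- p$Q / (N - 1)
  -0.5 * ((N - 1) * (log(s2w) + 1 + log(2 * pi)) + p$logdet + log(p$xtvx))
}

nested_full_loglik <- function(theta, blocks, N) {
  sp <- theta[1]; sa <- theta[2]; sw <- theta[3]
  if (sw <= 0) return(-Inf)
  p <- nested_loglik_pieces(max(sp, 0) / sw, max(sa, 0) / sw, blocks)
  if (is.null(p)) return(-Inf)
  -0.5 * ((N - 1) * (log(sw) + log(2 * pi)) + p$logdet + log(p$xtvx) + p$Q / sw)
}

reml_nested <- function(y, tree, provenance) {
  prov_per_tree <- tapply(provenance, tree, function(p) length(unique(p)))
  if (any(prov_per_tree > 1)) stop("trees must be nested within provenances")
  blocks <- lapply(split(seq_along(y), provenance), function(ix) {
    tr <- tree[ix]
    Z <- outer(tr, unique(tr), `==`) * 1
    list(y = y[ix], ZZt = Z %*% t(Z))
  })
  N <- length(y)
  obj <- function(par) -nested_profile_loglik(exp(par[1]), exp(par[2]), blocks, N)
  starts <- list(log(c(0.3, 0.3)), log(c(0.02, 0.5)), log(c(0.5, 0.02)))
  fits <- lapply(starts, function(s)
    stats::optim(s, obj, method = "L-BFGS-B",
                 lower = log(1e-10), upper = log(1e8),
                 control = list(factr = 10)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  g_p <- exp(best$par[1]); g_t <- exp(best$par[2])
  boundary <- c(provenance = g_p <= 1.0001e-10, tree = g_t <= 1.0001e-10,
                residual = FALSE)
  if (boundary["provenance"]) g_p <- 0
  if (boundary["tree"]) g_t <- 0
  p <- nested_loglik_pieces(g_p, g_t, blocks)
  s2w <- p$Q / (N - 1)
  theta <- c(provenance = g_p * s2w, tree = g_t * s2w, residual = s2w)
  V <- observed_info_cov(function(th) nested_full_loglik(th, blocks, N), theta)
  structure(list(sigma2 = theta,
                 loglik = nested_profile_loglik(g_p, g_t, blocks, N),
                 vcov = V, boundary = boundary,
                 n_groups = c(provenance = length(blocks),
                              tree = length(unique(tree))),
                 n_obs = N, method = "REML"),
            class = "varcomp")
}

# Covariance of variance-component estimates: inverse of the negative
# finite-difference Hessian of the restricted log-likelihood. Components at
# the zero boundary are evaluated just inside the parameter space; a
# non-invertible information matrix yields NA covariances.
observed_info_cov <- function(loglik, theta) {
  k <- length(theta)
  scale <- max(mean(abs(theta)), 1e-6)
  h <- pmax(1e-4 * abs(theta), 1e-6 * scale)
  th0 <- pmax(theta, 2 * h)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (loglik(th0 + ei) - 2 * loglik(th0) + loglik(th0 - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (loglik(th0 + ei + ej) - loglik(th0 + ei - ej) -
             loglik(th0 - ei + ej) + loglik(th0 - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, k, k))
  if (any(is.finite(diag(V)) & diag(V) < 0)) V[] <- NA_real_
  dimnames(V) <- list(names(theta), names(theta))
  V
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components (%d obs, %s):\n", x$n_obs,
              paste(sprintf("%d %s groups", x$n_groups, names(x$n_groups)),
                    collapse = ", ")))
  for (nm in names(x$sigma2))
    cat(sprintf("  sigma2_%-10s %.6f%s\n", nm, x$sigma2[[nm]],
                if (isTRUE(x$boundary[nm])) " (boundary)" else ""))
  cat(sprintf("  restricted logLik %.4f\n", x$loglik))
  invisible(x)
}

#' Repeatability from variance components
#'
#' Repeatability \code{r = sigma2_A / (sigma2_A + sigma2_W)} is the
#' intraclass correlation of repeated drought responses of the same tree:
#' the share of phenotypic variance attributable to consistent differences
#' among trees, and the upper limit of narrow-sense heritability. Its
#' standard error comes from the delta method applied to the asymptotic
#' covariance of the two components.
#'
#' @param components a \code{varcomp} object from [reml_varcomp()]; the
#'   among-group variance is the \code{tree} component, the within-group
#'   variance the \code{residual} one.
#' @return object of class \code{repeatability}: list with \code{r},
#'   \code{se_r}, \code{sigma2_A}, \code{sigma2_W}, \code{boundary},
#'   \code{n_trees}, \code{n_obs}.
#' @export
repeatability <- function(components) {
  stopifnot(inherits(components, "varcomp"))
  a <- components$sigma2[["tree"]]
  w <- components$sigma2[["residual"]]
  tot <- a + w
  if (tot <= 0) stop("total variance is zero; repeatability undefined")
  r <- a / tot
  V <- components$vcov[c("tree", "residual"), c("tree", "residual")]
  grad <- c(w, -a) / tot^2
  se <- if (all(is.finite(V))) sqrt(max(drop(t(grad) %*% V %*% grad), 0)) else NA_real_
  boundary <- isTRUE(components$boundary[["tree"]]) ||
    isTRUE(components$boundary[["residual"]])
  if (boundary && !is.finite(se)) se <- 0
  structure(list(r = r, se_r = se, sigma2_A = a, sigma2_W = w,
                 boundary = boundary,
                 n_trees = components$n_groups[["tree"]],
                 n_obs = components$n_obs),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability r = %.3f +/- %.3f (%d trees, %d records)%s\n",
              x$r, x$se_r, x$n_trees, x$n_obs,
              if (x$boundary) " [boundary estimate]" else ""))
  invisible(x)
}
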