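test_that("standardize_log maps {1, e, e^2} to {-1, 0, 1} and guards input", {
  z <- standardize_log(c(1, exp(1), exp(2)))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 1)
  expect_equal(attr(z, "scale"), 1)

  set.seed(1)
  z2 <- standardize_log(stats::rgamma(50, 5, 2))
  expect_equal(mean(z2), 0)
  expect_equal(stats::sd(z2), 1)

  expect_error(standardize_log(rep(2, 5)), "degenerate")
  expect_error(standardize_log(c(1, 0, 2)), "nonpositive")
  expect_error(standardize_log(c(1, -3)), "nonpositive")
})

test_that("REML equals the balanced one-way ANOVA closed form", {
  d <- make_one_way(30, 4, 0.4, 0.6, seed = 21)
  vc <- reml_varcomp(d$y, d$g)
  expect_equal(unname(vc$sigma2), unname(anova_components(d$y, d$g)),
               tolerance = 1e-8)
})

test_that("REML agrees with lme4 on unbalanced one-way and nested data", {
  skip_if_not_installed("lme4")
  set.seed(14)
  d <- make_one_way(25, 3, 0.3, 0.7, seed = 14)
  drop <- sample(length(d$y), 12)
  y <- d$y[-drop]; g <- d$g[-drop]
  vc <- reml_varcomp(y, g)
  fm <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vl <- as.data.frame(lme4::VarCorr(fm))$vcov
  expect_equal(unname(vc$sigma2), vl, tolerance = 1e-5)
  expect_equal(vc$loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-6)

  # nested provenance/tree model
  np <- 6; nt <- 7; k <- 3
  set.seed(15)
  prov <- rep(sprintf("p%d", 1:np), each = nt * k)
  tree <- rep(sprintf("p%d_t%d", rep(1:np, each = nt), rep(1:nt, np)), each = k)
  y2 <- stats::rnorm(np, 0, sqrt(0.15))[rep(1:np, each = nt * k)] +
    stats::rnorm(np * nt, 0, sqrt(0.3))[rep(1:(np * nt), each = k)] +
    stats::rnorm(np * nt * k, 0, sqrt(0.55))
  keep <- -sample(length(y2), 15)
  dd <- data.frame(y = y2, tree = tree, prov = prov)[keep, ]
  vc2 <- reml_varcomp(dd$y, dd$tree, dd$prov)
  fm2 <- lme4::lmer(y ~ 1 + (1 | prov) + (1 | tree), data = dd, REML = TRUE)
  vl2 <- as.data.frame(lme4::VarCorr(fm2))
  expect_equal(vc2$sigma2[["tree"]],
               vl2$vcov[vl2$grp == "tree"], tolerance = 1e-4)
  expect_equal(vc2$sigma2[["provenance"]],
               vl2$vcov[vl2$grp == "prov"], tolerance = 1e-4)
  expect_equal(vc2$loglik, as.numeric(stats::logLik(fm2)), tolerance = 1e-5)
})

test_that("degenerate layouts hit the documented boundaries", {
  # identical repeats per tree, trees differ: residual variance -> 0, r -> 1
  y <- rep(c(1, 2, 5), each = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  vc <- reml_varcomp(y, g)
  expect_lte(vc$sigma2[["residual"]], 1e-8)
  expect_equal(repeatability(vc)$r, 1, tolerance = 1e-6)

  # no between-tree signal: tree component truncated at zero
  d <- make_one_way(40, 3, 0, 1, seed = 3)
  vc0 <- reml_varcomp(d$y, d$g)
  if (vc0$boundary[["tree"]]) expect_equal(vc0$sigma2[["tree"]], 0)
  expect_lt(repeatability(vc0)$r, 0.15)

  expect_error(reml_varcomp(1:4, c("a", "a", "a", "a")), ">= 2 trees")
  expect_error(reml_varcomp(1:4, c("a", "b", "c", "d")), "repeated")
})

test_that("repeatability arithmetic and the delta-method SE are sound", {
  vc <- structure(list(sigma2 = c(tree = 1, residual = 3),
                       vcov = diag(c(0.04, 0.09)),
                       boundary = c(tree = FALSE, residual = FALSE),
                       n_groups = c(tree = 10L), n_obs = 30L,
                       loglik = NA_real_, method = "REML"),
                  class = "varcomp")
  dimnames(vc$vcov) <- list(c("tree", "residual"), c("tree", "residual"))
  r <- repeatability(vc)
  expect_equal(r$r, 0.25)
  # delta method: grad = (w, -a)/(a+w)^2 = (3, -1)/16
  expect_equal(r$se_r, sqrt(9 / 256 * 0.04 + 1 / 256 * 0.09))

  vc$sigma2 <- c(tree = 0, residual = 3)
  expect_equal(repeatability(vc)$r, 0)
  vc$sigma2 <- c(tree = 2, residual = 0)
  expect_equal(repeatability(vc)$r, 1)
})

test_that("repeatability is invariant to affine changes of the response", {
  d <- make_one_way(25, 3, 0.3, 0.7, seed = 33)
  r1 <- repeatability(reml_varcomp(d$y, d$g))$r
  r2 <- repeatability(reml_varcomp(3.2 * d$y + 17, d$g))$r
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("the delta-method SE tracks the sampling spread of r-hat", {
  set.seed(77)
  rhat <- numeric(120)
  sehat <- numeric(120)
  for (i in 1:120) {
    d <- make_one_way(200, 3, 0.3, 0.7, seed = 1000 + i)
    r <- repeatability(reml_varcomp(d$y, d$g))
    rhat[i] <- r$r
    sehat[i] <- r$se_r
  }
  ratio <- mean(sehat) / stats::sd(rhat)
  expect_gt(ratio, 1 / 1.3)
  expect_lt(ratio, 1.3)
})
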