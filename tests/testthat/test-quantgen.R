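sim_table <- function(seed, r_true = 0.3, np = 6, nt = 30,
                      prov_sd = 0.03, resid_sd = 0.15) {
  tree_sd <- sqrt(r_true * resid_sd^2 / (1 - r_true))
  cfg <- simulation_config(seed = seed, n_provenances = np,
                           trees_per_provenance = nt,
                           provenance_effect_sd = prov_sd,
                           tree_sensitivity_sd = tree_sd,
                           residual_sd = resid_sd)
  simulate_response_table(cfg)
}

test_that("species repeatability recovers the simulated truth", {
  sim <- sim_table(101, r_true = 0.3, np = 8, nt = 60)
  sp <- species_repeatability(sim$table, "Res")
  expect_lt(abs(sp$r - 0.3), 0.07)
  expect_true(is.finite(sp$sigma2_provenance))

  # with no provenance effect the nested fit collapses to the one-way fit
  sim0 <- sim_table(102, r_true = 0.3, np = 8, nt = 60, prov_sd = 0)
  sp0 <- species_repeatability(sim0$table, "Res")
  d <- defined_records(sim0$table, "Res")
  r1 <- repeatability(reml_varcomp(standardize_log(d$value), d$tree_id))
  expect_lt(abs(sp0$r - r1$r), 0.02)

  one_prov <- sim0$table[sim0$table$provenance_id == "P01", ]
  class(one_prov) <- c("response_table", "data.frame")
  expect_error(species_repeatability(one_prov, "Res"),
               "provenance_repeatability")
})

test_that("provenance repeatability recovers truth and reports reasons", {
  sim <- sim_table(103, r_true = 0.4, np = 4, nt = 16)
  pr <- provenance_repeatability(sim$table, "Res")
  expect_equal(nrow(pr), 4L)
  expect_true(all(is.finite(pr$r)))
  # noisy at 16 trees, but centred near truth on average
  expect_lt(abs(mean(pr$r) - 0.4), 0.2)

  # a provenance with a single tree is missing with a reason
  tab <- sim$table[sim$table$provenance_id == "P01" &
                     sim$table$tree_id %in% "P01_T01" |
                     sim$table$provenance_id == "P02", ]
  class(tab) <- c("response_table", "data.frame")
  pr2 <- provenance_repeatability(tab, "Res")
  expect_equal(pr2$reason[pr2$provenance_id == "P01"], "fewer than 2 trees")
  expect_true(is.na(pr2$r[pr2$provenance_id == "P01"]))
})

test_that("evolvability arithmetic, guards and scale invariance hold", {
  ev <- evolvability(0.25, 0.04, 0.5)
  expect_equal(ev$V_A, 0.01)
  expect_equal(ev$CV_A, 20)
  expect_equal(evolvability(0, 0.04, 0.5)$CV_A, 0)
  # scaling the trait by c > 0 leaves CV_A unchanged
  c0 <- 3.7
  expect_equal(evolvability(0.25, 0.04 * c0^2, 0.5 * c0)$CV_A, 20)
  expect_error(evolvability(0.25, 0.04, 0), "positive")
  expect_error(evolvability(0.25, -1, 0.5), "nonnegative")

  sim <- sim_table(104, np = 5, nt = 20)
  et <- evolvability_table(sim$table, "Res")
  expect_equal(nrow(et), 5L)
  expect_true(all(et$V_A <= et$V_P + 1e-12))
  expect_true(all(et$CV_A >= 0))
})

test_that("the two-way species ANOVA has the right structure", {
  tabs <- lapply(1:4, function(i) {
    s <- sim_table(110 + i, np = 3, nt = 10)$table
    s$site_id <- sprintf("SP%d", i)
    s
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("response_table", "data.frame")
  a <- two_way_anova(tab, "Res")
  expect_equal(a$df[1:3], c(3, 2, 6))
  expect_true(all(a$F[1:3] >= 0))

  # sums of squares match an explicit design-matrix projection oracle
  v <- tab$Res
  ok <- !is.na(v)
  sp <- factor(tab$site_id[ok]); evf <- factor(tab$event_year[ok]); y <- v[ok]
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  X0 <- stats::model.matrix(~ 1, data.frame(y))
  X1 <- stats::model.matrix(~ sp)
  X2 <- stats::model.matrix(~ sp + evf)
  X3 <- stats::model.matrix(~ sp * evf)
  fit <- attr(a, "fit")
  ss <- stats::anova(fit)$`Sum Sq`
  expect_equal(ss[1:3], c(rss(X0) - rss(X1), rss(X1) - rss(X2),
                          rss(X2) - rss(X3)), tolerance = 1e-8)

  # balanced design: sequential equals partial sums of squares
  ss_part <- c(rss(stats::model.matrix(~ evf)) - rss(X2),
               rss(X1) - rss(X2))
  expect_equal(ss[1:2], ss_part, tolerance = 1e-8)

  empty <- tab[!(tab$site_id == "SP1" & tab$event_year == 1993), ]
  class(empty) <- c("response_table", "data.frame")
  expect_error(two_way_anova(empty, "Res"), "empty cell")
})

test_that("compact letter displays separate what Tukey separates", {
  expect_equal(unname(posthoc_letters(c(1, 2, 1.5), rep("a", 3))), "a")

  # two groups many residual SDs apart, verified against direct Tukey maths
  set.seed(9)
  y <- c(stats::rnorm(20, 0, 0.1), stats::rnorm(20, 5, 0.1))
  g <- rep(c("lo", "hi"), each = 20)
  lt <- posthoc_letters(y, g)
  expect_false(lt[["lo"]] == lt[["hi"]])
  # direct Tukey computation: studentized range on the group means
  msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / 38
  q_obs <- abs(diff(tapply(y, g, mean))) / sqrt(msw / 20)
  expect_lt(stats::ptukey(q_obs, 2, 38, lower.tail = FALSE), 0.05)

  # three groups, middle overlapping both ends
  set.seed(10)
  y3 <- c(stats::rnorm(40, 0), stats::rnorm(40, 0.5), stats::rnorm(40, 4))
  g3 <- rep(c("a0", "a5", "b"), each = 40)
  lt3 <- posthoc_letters(y3, g3)
  expect_false(grepl(substr(lt3[["b"]], 1, 1), lt3[["a0"]], fixed = TRUE))

  skip_if_not_installed("multcomp")
  fit <- stats::aov(y3 ~ g, data = data.frame(y3 = y3, g = factor(g3)))
  cld <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(g = "Tukey")))$mcletters
  same_letter <- function(l, a, b) {
    any(strsplit(l[[a]], "")[[1]] %in% strsplit(l[[b]], "")[[1]])
  }
  for (pair in list(c("a0", "a5"), c("a0", "b"), c("a5", "b"))) {
    expect_equal(same_letter(lt3, pair[1], pair[2]),
                 same_letter(cld$Letters, pair[1], pair[2]))
  }
})

test_that("identical groups share a letter in most null replicates", {
  set.seed(11)
  share <- replicate(60, {
    y <- stats::rnorm(45)
    g <- rep(c("a", "b", "c"), each = 15)
    lt <- posthoc_letters(y, g)
    length(unique(lt)) == 1
  })
  expect_gte(mean(share), 0.9)
})

test_that("stepwise model selection has valid likelihood structure", {
  sim <- sim_table(120, np = 8, nt = 16)
  ms <- repeated_measures_selection(sim$table, "Res")
  expect_equal(ms$model, c("intercept", "drought", "provenance", "interaction"))
  # parameter counts: intercept + 2 variance components, then +2 events,
  # +7 provenance contrasts, +14 interaction contrasts
  expect_equal(ms$df, c(3, 5, 12, 26))
  expect_true(all(diff(ms$logLik) >= -1e-6))
  expect_equal(ms$L_ratio[-1], 2 * diff(ms$logLik), tolerance = 1e-10)
  expect_equal(ms$AIC, 2 * ms$df - 2 * ms$logLik)
  expect_true(all(ms$p[-1] >= 0 & ms$p[-1] <= 1))

  one_event <- sim$table[sim$table$event_year == 1993, ]
  class(one_event) <- c("response_table", "data.frame")
  expect_error(repeated_measures_selection(one_event, "Res"), ">= 2")
})

test_that("a strong drought effect is detected and absent effects are not", {
  # inject a drought-year mean shift, keep no provenance effect
  sim <- sim_table(121, np = 6, nt = 20, prov_sd = 0)
  tab <- sim$table
  shift <- c("1993" = 0, "2000" = -0.3, "2003" = 0.15)
  tab$Res <- tab$Res * exp(shift[as.character(tab$event_year)])
  ms <- repeated_measures_selection(tab, "Res")
  expect_lt(ms$p[ms$model == "drought"], 0.001)
  expect_gt(ms$p[ms$model == "provenance"], 0.05)
})
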