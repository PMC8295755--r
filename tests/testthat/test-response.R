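test_that("resistance and recovery hit their closed forms", {
  flat <- make_series(1990:2009, rep(1.4, 20))
  r <- resistance(flat, 2000)
  expect_equal(r$Res, 1)
  expect_equal(recovery(flat, 2000)$Rec, 1)

  # 8 window years at 2 mm, event year 1 mm: I_9yr = 17/9, Res = 9/17
  w <- rep(2, 20)
  w[1990:2009 == 2000] <- 1
  dip <- make_series(1990:2009, w)
  r2 <- resistance(dip, 2000)
  expect_equal(r2$I_window, 17 / 9)
  expect_equal(r2$Res, 9 / 17)

  # event 1 mm, post years 1.5 and 2.5 mm: Rec = 2
  w3 <- rep(2, 20)
  w3[1990:2009 %in% 2000:2002] <- c(1, 1.5, 2.5)
  expect_equal(recovery(make_series(1990:2009, w3), 2000)$Rec, 2)
})

test_that("incomplete windows and zero increments are missing with reasons", {
  short <- make_series(1998:2009, rep(1, 12))
  r <- resistance(short, 2000)  # event 2 years from series start
  expect_true(is.na(r$Res))
  expect_equal(r$reason, "incomplete window")

  tail_event <- recovery(make_series(1990:2000, rep(1, 11)), 2000)
  expect_equal(tail_event$reason, "incomplete post window")

  zero <- make_series(1990:2009, c(rep(1, 10), 0, rep(1, 9)))
  rec0 <- recovery(zero, 2000)
  expect_true(is.na(rec0$Rec))
  expect_match(rec0$reason, "degenerate")

  all0 <- make_series(1990:2009, rep(0, 20))
  res0 <- resistance(all0, 2000)
  expect_match(res0$reason, "degenerate")
  expect_error(resistance(short, 2000, window = 8), "odd")
})

test_that("indices are scale invariant and local to their windows", {
  set.seed(3)
  w <- stats::rgamma(30, 8, 4)
  s <- make_series(1981:2010, w)
  base_res <- resistance(s, 1995)$Res
  base_rec <- recovery(s, 1995)$Rec
  s2 <- s
  s2$width_mm <- s$width_mm * 7.3
  expect_equal(resistance(s2, 1995)$Res, base_res)
  expect_equal(recovery(s2, 1995)$Rec, base_rec)

  # perturbing years outside the windows changes nothing
  s3 <- s
  s3$width_mm[s3$year < 1991 | s3$year > 1999] <- 99
  expect_equal(resistance(s3, 1995)$Res, base_res)
  s4 <- s
  s4$width_mm[s4$year != 1995 & !(s4$year %in% 1996:1997)] <- 99
  expect_equal(recovery(s4, 1995)$Rec, base_rec)
})

test_that("excluding the event year from the window mean is available", {
  w <- rep(2, 20)
  w[1990:2009 == 2000] <- 1
  s <- make_series(1990:2009, w)
  r <- resistance(s, 2000, include_event = FALSE)
  expect_equal(r$I_window, 2)
  expect_equal(r$Res, 0.5)
})

test_that("the response table counts records, reasons and bias flags", {
  yrs <- 1985:2010
  col <- as_tree_collection(rbind(
    make_series(yrs, rep(2, length(yrs))),
    within(make_series(1999:2010, rep(2, 12)), tree_id <- "T2")))
  tab <- compute_response_table(col, c(1993, 2000, 2003))
  expect_equal(nrow(tab), 6L)
  # T2 starts 1999: 1993 fully missing, 2000 resistance window incomplete
  t2_93 <- tab[tab$tree_id == "T2" & tab$event_year == 1993, ]
  expect_true(is.na(t2_93$Res) && is.na(t2_93$Rec))
  cp <- attr(tab, "completeness")
  expect_equal(cp$n_records, 6L)
  expect_equal(cp$n_res_defined, 4L)
  # consecutive events 2002/2003 would overlap a 2-year recovery window
  tab2 <- compute_response_table(col, c(2001, 2003))
  expect_match(tab2$flags[tab2$event_year == 2001 & tab2$tree_id == "T1"],
               "biased")
  expect_false(grepl("biased", tab2$flags[tab2$event_year == 2003 &
                                            tab2$tree_id == "T1"]))
})

test_that("per-site event lists are honoured", {
  yrs <- 1985:2010
  s1 <- make_series(yrs, rep(2, length(yrs)))
  s2 <- within(make_series(yrs, rep(2, length(yrs))), {
    tree_id <- "T2"; site_id <- "LARCH"
  })
  col <- as_tree_collection(rbind(s1, s2))
  tab <- compute_response_table(col, list(S = 1993, LARCH = 1992))
  expect_equal(tab$event_year[tab$site_id == "S"], 1993)
  expect_equal(tab$event_year[tab$site_id == "LARCH"], 1992)
  expect_error(compute_response_table(col, list(S = 1993)), "no events")
  expect_error(compute_response_table(col, integer(0)), "nonempty")
})

test_that("simulated drought multipliers propagate to the Lloret closed form", {
  cfg <- simulation_config(seed = 5, n_provenances = 2, trees_per_provenance = 3,
                           age_trend = "constant", provenance_effect_sd = 0,
                           tree_sensitivity_sd = 0, residual_sd = 0,
                           tree_baseline_sd = 0, growth_noise_sd = 0,
                           core_noise_sd = 0, event_years = 2000,
                           event_log_reduction_mean = log(2))
  sim <- simulate_ring_widths(cfg)
  tab <- compute_response_table(sim$collection, 2000)
  m <- 0.5
  expect_equal(tab$Res, rep(m * 9 / (8 + m), nrow(tab)), tolerance = 1e-12)
  expect_equal(tab$Rec, rep(1 / m, nrow(tab)), tolerance = 1e-12)
})
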