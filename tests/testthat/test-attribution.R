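test_that("first differences detrend exactly and respect year gaps", {
  # linear series -> constant differences equal to the slope
  fd <- first_difference(3 * (1:10) + 2, 2001:2010)
  expect_equal(fd$delta, rep(3, 9))
  expect_equal(fd$year, 2002:2010)
  # constant series -> zeros
  expect_equal(first_difference(rep(5, 6))$delta, rep(0, 5))
  # a gap splits the series: no difference across it
  fd2 <- first_difference(c(1, 2, 4, 10, 11), c(2000, 2001, 2002, 2005, 2006))
  expect_equal(fd2$year, c(2001, 2002, 2006))
  expect_equal(fd2$delta, c(1, 2, 1))

  set.seed(401)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    fd <- first_difference(x, seq_len(n))
    # telescoping identity
    expect_equal(mean(fd$delta), (x[n] - x[1]) / (n - 1), tolerance = 1e-12)
    # cumulative reconstruction
    expect_equal(x[1] + cumsum(fd$delta), x[-1], tolerance = 1e-12)
  }
})

test_that("temperature zones partition the positive axis left-closed", {
  expect_equal(classify_zone(2192), "TZ-2")
  expect_equal(classify_zone(1999.9), "TZ-1")
  expect_equal(classify_zone(2000.0), "TZ-2")
  expect_equal(classify_zone(2500.0), "TZ-3")
  expect_equal(classify_zone(3000.0), "TZ-4")
  expect_equal(classify_zone(3499.99), "TZ-4")
  expect_equal(classify_zone(3500.0), "TZ-5")
  expect_equal(classify_zone(9000), "TZ-5")
  expect_equal(classify_zone(1), "TZ-1")
  # total and single-valued over a fuzz grid
  vals <- seq(0.5, 6000, by = 7.3)
  z <- classify_zone(vals)
  expect_true(all(z %in% paste0("TZ-", 1:5)))
  expect_error(classify_zone(0), "positive")
  expect_error(classify_zone(-10), "positive")
})

test_that("zone panels pool within-station consecutive-year differences", {
  yields <- data.frame(
    station_id = rep(c("A", "B"), each = 4),
    year = rep(2001:2004, 2),
    yield_kg_ha = c(5000, 5100, 5050, 5200, 4000, 4100, 4300, 4250)
  )
  seasonal <- data.frame(
    station_id = rep(c("A", "B"), each = 4),
    year = rep(2001:2004, 2),
    tave = rep(c(12, 14), each = 4) + rep(c(0, .1, .2, .3), 2),
    tmax = 20, tmin = 6, tdr = 14,
    EAT = 1700, RA = 3000,
    annual_AT0 = rep(c(2200, 3600), each = 4)
  )
  panel <- build_zone_panel(yields, seasonal)
  expect_equal(nrow(panel), 6)                  # (4-1) rows per station
  expect_setequal(unique(panel$zone), c("TZ-2", "TZ-5"))
  a <- panel[panel$station_id == "A", ]
  expect_equal(a$dYp, c(100, -50, 150))
  expect_equal(a$dTave, rep(0.1, 3), tolerance = 1e-12)
  expect_equal(a$dEAT, rep(0, 3))
})

test_that("correlations match a two-pass oracle and flag exact relations", {
  cfg <- panel_gen_config(seed = 402, n = 200,
                          beta = c(dRA = 2), noise_sd = 0)
  panel <- gen_yield_panel(cfg)
  pm <- pearson_matrix(panel)
  expect_equal(pm$r[pm$predictor == "dRA"], 1, tolerance = 1e-12)

  cfg2 <- panel_gen_config(seed = 403, n = 150, beta = c(dRA = 1.5),
                           noise_sd = 150)
  p2 <- gen_yield_panel(cfg2)
  pm2 <- pearson_matrix(p2)
  for (v in pm2$predictor) {
    r_oracle <- sum((p2[[v]] - mean(p2[[v]])) * (p2$dYp - mean(p2$dYp))) /
      sqrt(sum((p2[[v]] - mean(p2[[v]]))^2) * sum((p2$dYp - mean(p2$dYp))^2))
    expect_equal(pm2$r[pm2$predictor == v], r_oracle, tolerance = 1e-10)
    ct <- stats::cor.test(p2[[v]], p2$dYp)
    expect_equal(pm2$p[pm2$predictor == v], unname(ct$p.value),
                 tolerance = 1e-10)
  }

  degenerate <- p2
  degenerate$dTDR <- 0
  pmd <- pearson_matrix(degenerate)
  expect_true(is.na(pmd$r[pmd$predictor == "dTDR"]))
  expect_equal(pmd$significance_class[pmd$predictor == "dTDR"], "undefined")
})

test_that("stepwise regression recovers a single-predictor truth", {
  cfg <- panel_gen_config(seed = 404, n = 500, beta = c(dRA = 2.34),
                          noise_sd = 100)
  panel <- gen_yield_panel(cfg)
  fit <- stepwise_mlr(panel)
  expect_identical(fit$selected, "dRA")
  expect_equal(unname(fit$coefficients["dRA"]), 2.34, tolerance = 0.05 * 2.34)
  expect_gt(fit$R2, 0.5)
  # selected-model coefficients equal a direct OLS refit
  refit <- stats::lm(dYp ~ dRA, data = panel)
  expect_equal(fit$coefficients, stats::coef(refit), tolerance = 1e-8)
})

test_that("stepwise recovers two active predictors and drops the rest", {
  cfg <- panel_gen_config(seed = 405, n = 600,
                          beta = c(dRA = 2.0, dTDR = 400), noise_sd = 120)
  panel <- gen_yield_panel(cfg)
  fit <- stepwise_mlr(panel)
  expect_setequal(fit$selected, c("dRA", "dTDR"))
  expect_equal(unname(fit$coefficients["dTDR"]), 400, tolerance = 40)
})

test_that("zero-noise single predictor is recovered exactly", {
  cfg <- panel_gen_config(seed = 406, n = 100, beta = c(dTDR = 420.30),
                          noise_sd = 0)
  panel <- gen_yield_panel(cfg)
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(stepwise_mlr(panel))
  expect_identical(fit$selected, "dTDR")
  expect_equal(unname(fit$coefficients["dTDR"]), 420.30, tolerance = 1e-8)
})

test_that("an exact affine copy of a predictor cannot enter twice", {
  cfg <- panel_gen_config(seed = 407, n = 300, beta = c(dTave = 300),
                          noise_sd = 80)
  panel <- gen_yield_panel(cfg)
  panel$dEAT <- 150 * panel$dTave + 20        # perfectly collinear
  fit <- stepwise_mlr(panel)
  expect_lte(sum(c("dTave", "dEAT") %in% fit$selected), 1)
  # the fit is full rank: no NA coefficients
  expect_false(any(is.na(fit$coefficients)))
})

test_that("intercept-only result is flagged when nothing explains yield", {
  set.seed(408)
  cfg <- panel_gen_config(seed = 408, n = 60, beta = c(dRA = 0),
                          noise_sd = 500)
  panel <- gen_yield_panel(cfg)
  # decouple dYp entirely
  panel$dYp <- rnorm(60, 0, 500)
  fit <- stepwise_mlr(panel, p_enter = 1e-6)
  expect_length(fit$selected, 0)
  expect_equal(fit$R2, 0)
})

test_that("attribute_zones reports per-zone correlations and fits", {
  cfg <- panel_gen_config(seed = 409, n = 120, beta = c(dRA = 2.5),
                          noise_sd = 120)
  panel <- gen_yield_panel(cfg)
  panel$zone <- rep(c("TZ-2", "TZ-3"), each = 60)
  rep <- attribute_zones(panel)
  expect_setequal(unique(rep$correlations$zone), c("TZ-2", "TZ-3", "ALL"))
  expect_true(all(c("TZ-2", "TZ-3", "ALL") %in% names(rep$regressions)))
  expect_identical(rep$regressions$ALL$selected, "dRA")
})
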