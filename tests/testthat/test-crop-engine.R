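test_that("thermal-time phenology matches the cumulative-threshold oracle", {
  p <- crop_params("Chaiqing-1")
  # constant 10 degC: TSUM_em = 100 -> emergence 10 days after sowing
  w <- constant_weather(tave = 10, doys = 1:330)
  r <- run_potential(w, p, sowing_doy = 50)
  expect_equal(r$emergence_doy, 60)
  # anthesis after a further 65 days, maturity after a further 85
  expect_equal(r$anthesis_doy, 60 + 65)
  expect_equal(r$maturity_doy, 60 + 65 + 85)
  expect_equal(r$duration, 150)
  expect_equal(r$termination_reason, "maturity")

  # oracle agreement on fluctuating synthetic series, all varieties
  syn <- synthetic_station_year(seed = 21)
  d <- syn$daily
  for (v in c("Chaiqing-1", "Zangqing-2000", "Diqing-1")) {
    pv <- crop_params(v)
    r <- run_potential(d, pv, sowing_doy = 100, latitude = syn$meta$lat[1])
    o <- phen_oracle(d$tave, d$doy, 100, pv)
    expect_equal(r$emergence_doy, o$emergence)
    expect_equal(r$anthesis_doy, o$anthesis)
    expect_equal(r$maturity_doy, o$maturity)
  }
})

test_that("development freezes below the base temperature", {
  p <- crop_params("Chaiqing-1")
  st <- barleyclim:::new_crop_state(p)
  for (i in 1:50) st <- phenology_step(st, -3, p)
  expect_equal(st$cum_em, 0)
  expect_equal(st$DVS, 0)
  expect_equal(st$stage, "pre_emergence")
})

test_that("variety heat requirements total as calibrated", {
  totals <- vapply(c("Chaiqing-1", "Zangqing-2000", "Diqing-1"),
                   function(v) {
                     p <- crop_params(v)
                     p$TSUM_em + p$TSUM1 + p$TSUM2
                   }, numeric(1))
  # the grand totals printed in the calibration table
  expect_equal(unname(totals), c(1600, 1750, 1950))
})

test_that("canopy assimilation limits, monotonicity and quadrature accuracy", {
  p <- crop_params("Chaiqing-1")
  expect_equal(daily_gross_assimilation(20000, 13, 0, p), 0)
  expect_equal(daily_gross_assimilation(0, 13, 3, p), 0)

  # strictly monotone in Ra and LAI for the homogeneous scheme; the
  # diffuse/direct split permits sub-0.1% ripples in Ra where a clearer
  # sky shifts light from shaded to saturated sunlit leaves
  for (geom in list(NULL, c(30, 172))) {
    lat <- geom[1]; doy <- geom[2]
    vals <- vapply(seq(1000, 30000, length.out = 20), function(ra) {
      daily_gross_assimilation(ra, 13, 3, p, lat = lat, doy = doy)
    }, numeric(1))
    if (is.null(lat)) {
      expect_true(all(diff(vals) > 0))
    } else {
      expect_true(all(diff(vals) > -1e-3 * vals[-1]))
      expect_gt(vals[20], vals[1])
    }
    vals <- vapply(seq(0.1, 8, length.out = 15), function(lai) {
      daily_gross_assimilation(15000, 13, lai, p, lat = lat, doy = doy)
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }

  # bounded by light-saturated canopy running all daylight hours
  expect_lt(daily_gross_assimilation(30000, 13, 4, p),
            p$AMAX * 4 * 13 * 30 / 44)

  # 3-point Gaussian vs 100-point composite integration of the same
  # leaf-level response: within 2%
  cases <- expand.grid(Ra = c(8000, 15000, 25000), LAI = c(0.5, 2, 5))
  for (i in seq_len(nrow(cases))) {
    for (geom in list(NULL, c(30, 172))) {
      g3 <- daily_gross_assimilation(cases$Ra[i], 13.5, cases$LAI[i], p,
                                     lat = geom[1], doy = geom[2])
      g100 <- daily_gross_assimilation(cases$Ra[i], 13.5, cases$LAI[i], p,
                                       lat = geom[1], doy = geom[2],
                                       n_gauss = 100)
      expect_lt(abs(g3 - g100) / g100, 0.02)
    }
  }
})

test_that("maintenance respiration follows the Q10 law and the gross cap", {
  p <- crop_params("Chaiqing-1")
  st <- barleyclim:::new_crop_state(p)
  st$WLV <- st$WST <- st$WSO <- st$WRT <- 0
  expect_equal(maintenance_respiration(st, 20, p), 0)

  st$WLV <- 1000; st$WST <- st$WSO <- st$WRT <- 0
  # at the reference temperature the Q10 factor is 1
  expect_equal(maintenance_respiration(st, p$TREF, p), 0.03 * 1000)
  # +10 degC doubles it
  expect_equal(maintenance_respiration(st, p$TREF + 10, p), 0.03 * 1000 * 2)
  # mixed organs at reference temperature
  st$WST <- 500; st$WSO <- 200; st$WRT <- 300
  expect_equal(maintenance_respiration(st, p$TREF, p),
               0.03 * 1000 + 0.015 * 500 + 0.01 * 200 + 0.01 * 300)
  # cap at gross assimilation
  expect_equal(maintenance_respiration(st, p$TREF, p, gross = 10), 10)
})

test_that("partitioning converts and splits assimilate as configured", {
  p <- crop_params("Chaiqing-1",
                   FRTB = cbind(dvs = c(0, 2), fr = c(0, 0)),
                   FLTB = cbind(dvs = c(0, 2), f = c(0.5, 0.5)),
                   FSTB = cbind(dvs = c(0, 2), f = c(0.3, 0.3)),
                   FOTB = cbind(dvs = c(0, 2), f = c(0.2, 0.2)),
                   CVL = 0.7, CVS = 0.7, CVO = 0.7)
  st <- barleyclim:::new_crop_state(p)
  g <- partition_and_grow(100, st, p)
  expect_equal(g$dWLV, 0.7 * 0.5 * 100)
  expect_equal(g$dWST, 0.7 * 0.3 * 100)
  expect_equal(g$dWSO, 0.7 * 0.2 * 100)
  expect_equal(g$dWRT, 0)
  expect_equal(g$conversion_loss, 100 - 70)
  # zero assimilate: zero increments
  g0 <- partition_and_grow(0, st, p)
  expect_equal(g0$dWLV + g0$dWST + g0$dWSO + g0$dWRT, 0)
  # near maturity the storage organ dominates
  pd <- crop_params("Chaiqing-1")
  st$DVS <- 1.9
  gm <- partition_and_grow(100, st, pd)
  expect_gt(gm$dWSO, 0)
  expect_equal(gm$dWLV, 0)
  expect_equal(gm$dWST, 0)
})

test_that("shoot fractions must sum to one", {
  expect_error(
    crop_params("Chaiqing-1",
                FLTB = cbind(dvs = c(0, 2), f = c(0.7, 0.7)),
                FSTB = cbind(dvs = c(0, 2), f = c(0.5, 0.5)),
                FOTB = cbind(dvs = c(0, 2), f = c(0.0, 0.0))),
    "sum to 1")
})

test_that("a leaf cohort lives exactly SPAN physiological days at 35 degC", {
  p <- crop_params("Chaiqing-1")
  st <- barleyclim:::new_crop_state(p)
  st$LV <- 100; st$LVAGE <- 0; st$WLV <- 100; st$LAI <- p$SLA * 100
  for (d in 1:24) {
    st <- leaf_dynamics(st, 35, p)
    expect_equal(st$senesced_today, 0)
  }
  st <- leaf_dynamics(st, 35, p)   # 25th day: age reaches SPAN
  expect_equal(st$senesced_today, 100)
  expect_equal(st$WLV, 0)
  expect_equal(st$LAI, 0)
})

test_that("juvenile LAI growth is capped by the exponential bound", {
  p <- crop_params("Chaiqing-1")
  st <- barleyclim:::new_crop_state(p)
  st$DVS <- 0.1
  lai0 <- st$LAI
  # a huge leaf increment cannot push LAI past the exponential envelope
  st2 <- leaf_dynamics(st, 20, p, new_leaf_weight = 1e5)
  expect_lte(st2$LAI, lai0 * exp(p$RGRLAI * 20) + 1e-12)
})

test_that("LAI trajectory is unimodal on a standard synthetic season", {
  syn <- synthetic_station_year(seed = 23)
  p <- crop_params(syn$meta$variety[1])
  r <- run_potential(syn$daily, p, sowing_doy = 100,
                     latitude = syn$meta$lat[1], save_trajectory = TRUE)
  lai <- r$trajectory$LAI
  pk <- which.max(lai)
  expect_gt(pk, 5)
  expect_lt(pk, length(lai))
  # rise then fall, allowing only cohort-senescence ripples (< 5% of peak)
  rise <- lai[1:pk]; fall <- lai[pk:length(lai)]
  expect_lt(max(cummax(rise) - rise), 0.05 * max(lai))
  expect_lt(max(fall - cummin(fall)), 0.05 * max(lai))
})

test_that("carbon balance closes to numerical precision", {
  for (seed in c(24, 25)) {
    syn <- synthetic_station_year(seed = seed)
    p <- crop_params(syn$meta$variety[1])
    r <- run_potential(syn$daily, p, sowing_doy = 100,
                       latitude = syn$meta$lat[1])
    expect_lt(r$balance$relative_closure, 1e-6)
  }
})

test_that("radiation scaling monotonicity and the no-light limit", {
  syn <- synthetic_station_year(seed = 26)
  p <- crop_params(syn$meta$variety[1])
  d <- syn$daily
  base <- run_potential(d, p, sowing_doy = 100, latitude = syn$meta$lat[1])
  d_up <- d; d_up$Ra <- d$Ra * 1.2
  up <- run_potential(d_up, p, sowing_doy = 100, latitude = syn$meta$lat[1])
  expect_gte(up$potential_yield, base$potential_yield)

  d_dark <- d; d_dark$Ra <- 0
  dark <- run_potential(d_dark, p, sowing_doy = 100,
                        latitude = syn$meta$lat[1])
  expect_lt(dark$potential_yield, p$TDWI)   # nothing beyond seed reserves

  p0 <- crop_params(syn$meta$variety[1], AMAX = 0)
  off <- run_potential(d, p0, sowing_doy = 100, latitude = syn$meta$lat[1])
  expect_lt(off$potential_yield, p$TDWI)
})

test_that("identical weather and parameters give bit-identical results", {
  syn <- synthetic_station_year(seed = 27)
  p <- crop_params(syn$meta$variety[1])
  r1 <- run_potential(syn$daily, p, sowing_doy = 100,
                      latitude = syn$meta$lat[1], save_trajectory = TRUE)
  r2 <- run_potential(syn$daily, p, sowing_doy = 100,
                      latitude = syn$meta$lat[1], save_trajectory = TRUE)
  expect_identical(r1, r2)
})

test_that("weather gaps inside the run are reported with the missing day", {
  p <- crop_params("Chaiqing-1")
  w <- constant_weather(doys = c(100:150, 152:330))
  expect_error(run_potential(w, p, sowing_doy = 100), "151")
  expect_error(run_potential(constant_weather(doys = 150:330), p,
                             sowing_doy = 100), "sowing")
})
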