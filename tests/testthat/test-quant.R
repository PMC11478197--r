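test_that("calibration fitting recovers exact and noisy lines", {
  x <- c(6.62, 30, 55, 80, 109.11)
  pts <- data.frame(concentration = x, area = 2463.0 * x - 127.53)
  cv <- fit_calibration(pts, "adenosine")
  expect_equal(cv$slope, 2463.0)
  expect_equal(cv$intercept, -127.53)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$range, c(6.62, 109.11))
  two <- fit_calibration(data.frame(concentration = c(1, 2),
                                    area = c(5, 9)))
  expect_equal(two$r_squared, 1)
  expect_error(fit_calibration(data.frame(concentration = rep(3, 4),
                                          area = 1:4)), "degenerate")
  set.seed(21)
  slopes <- vapply(1:10, function(s) {
    ser <- simulate_calibration_series(ref_spec("macrostemonoside_A"),
                                       table2_levels("macrostemonoside_A"),
                                       replicate_cv = 0.01, seed = s)
    fit_calibration(ser)$slope
  }, numeric(1))
  expect_true(all(abs(slopes / 2223.2 - 1) < 0.03))
})

test_that("external-standard quantification inverts the line", {
  cv <- reference_curve("macrostemonoside_A")
  content <- esm_quantify(2223.2 * 50 - 117.7, cv)
  expect_equal(as.numeric(content), 50)
  expect_false(attr(content, "extrapolated"))
  expect_equal(as.numeric(esm_quantify(cv$intercept, cv)), 0)
  expect_warning(out <- esm_quantify(cv$intercept - 1000, cv), "clipping")
  expect_equal(as.numeric(out), 0)
  big <- esm_quantify(2223.2 * 500 - 117.7, cv)
  expect_true(attr(big, "extrapolated"))
  # round trip through a noiseless calibration series
  ser <- simulate_calibration_series(ref_spec("macrostemonoside_A"),
                                     table2_levels("macrostemonoside_A"))
  fit <- fit_calibration(ser)
  for (i in seq_len(nrow(ser)))
    expect_equal(as.numeric(esm_quantify(ser$area[i], fit)),
                 ser$concentration[i], tolerance = 1e-10)
})

test_that("relative correction factors follow the response-ratio form", {
  # identical responses give RCF 1 with zero dispersion
  pts <- data.frame(concentration = c(10, 20, 30), area = c(100, 200, 300))
  r <- compute_rcf(pts, pts)
  expect_equal(r$mean_rcf, 1)
  expect_equal(r$rcf_rsd, 0)
  # intercept-free responses: RCF is the slope ratio at every level
  cs <- table2_levels("macrostemonoside_A")
  ct <- table2_levels("macrostemonoside_T")
  rT <- compute_rcf(data.frame(concentration = cs, area = 2223.2 * cs),
                    data.frame(concentration = ct, area = 861.0 * ct))
  expect_equal(rT$per_level_rcf, rep(2223.2 / 861.0, 5), tolerance = 1e-12)
  expect_error(compute_rcf(pts, pts[1:2, ]), "mismatched")
  expect_error(compute_rcf(pts[1:2, ], pts[1:2, ]), "3 levels")
  # ratio invariance: a common multiplicative factor cancels
  pts2 <- pts; pts2$area <- pts2$area * 3.7
  pts3 <- data.frame(concentration = c(5, 9, 14), area = c(40, 75, 110))
  pts3b <- pts3; pts3b$area <- pts3b$area * 3.7
  expect_equal(compute_rcf(pts2, pts3b)$per_level_rcf,
               compute_rcf(pts, pts3)$per_level_rcf)
})

test_that("RCFs from the published response lines sit in the known bands", {
  mk <- function(a) {
    lv <- table2_levels(a)
    simulate_calibration_series(ref_spec(a), lv)
  }
  rT <- compute_rcf(mk("macrostemonoside_A"), mk("macrostemonoside_T"))
  rU <- compute_rcf(mk("macrostemonoside_A"), mk("macrostemonoside_U"))
  # frozen from an independent closed-form computation over the printed
  # ranges: 2.5832 and 1.6993
  expect_equal(rT$mean_rcf, 2.5832, tolerance = 1e-4)
  expect_equal(rU$mean_rcf, 1.6993, tolerance = 1e-4)
  expect_lt(abs(rT$mean_rcf - 2.56) / 2.56, 0.02)
  expect_lt(abs(rU$mean_rcf - 1.74) / 1.74, 0.03)
})

test_that("relative retention time localizes the intended peak", {
  pk <- data.frame(apex_time = c(37.58, 41.00),
                   area = c(100, 200))
  hit <- locate_peak_by_rrt(pk, 40.00, expected_rrt = 0.9394)
  expect_equal(hit$apex_time, 37.58)
  expect_equal(attr(hit, "rrt"), 0.9395)
  same <- locate_peak_by_rrt(data.frame(apex_time = 40, area = 1), 40, 1)
  expect_equal(attr(same, "rrt"), 1)
  expect_error(
    locate_peak_by_rrt(data.frame(apex_time = 38, area = 1), 40, 0.9394),
    "not located")
})

test_that("QAMS inverts the RCF definition exactly", {
  expect_equal(qams_quantify(100, 100, 30, 1), 30)
  # exact round trip: noiseless series -> RCF -> QAMS recovers C_i
  ref <- simulate_calibration_series(ref_spec("macrostemonoside_A"),
                                     table2_levels("macrostemonoside_A"))
  ana <- simulate_calibration_series(ref_spec("macrostemonoside_U"),
                                     table2_levels("macrostemonoside_U"))
  rec <- compute_rcf(ref, ana)
  for (i in 1:5) {
    got <- qams_quantify(ana$area[i], ref$area[i], ref$concentration[i],
                         rec$per_level_rcf[i])
    expect_equal(got, ana$concentration[i], tolerance = 1e-10)
  }
  expect_error(qams_quantify(10, 0, 5, 2), "missing")
  expect_error(qams_quantify(-1, 10, 5, 2), "positive")
})

test_that("QAMS and ESM agree within 1% on synthetic batches", {
  ref <- simulate_calibration_series(ref_spec("macrostemonoside_A"),
                                     table2_levels("macrostemonoside_A"))
  reffit <- fit_calibration(ref, "macrostemonoside_A")
  for (an in c("macrostemonoside_T", "macrostemonoside_U")) {
    ser <- simulate_calibration_series(ref_spec(an), table2_levels(an))
    anafit <- fit_calibration(ser, an)
    rec <- compute_rcf(ref, ser)
    # a batch with known concentrations inside both ranges
    c_s <- 50; c_i <- 60
    a_s <- 2223.2 * c_s - 117.7
    a_i <- anafit$slope * c_i + anafit$intercept
    esm <- as.numeric(esm_quantify(a_i, anafit))
    qams <- qams_quantify(a_i, a_s, as.numeric(esm_quantify(a_s, reffit)),
                          rec)
    expect_equal(esm, c_i, tolerance = 1e-8)
    expect_lt(abs(qams - esm) / esm, 0.01)
  }
})

test_that("relative deviation reproduces the reference table's arithmetic", {
  expect_equal(relative_deviation(102.20, 101.73), -0.46)
  expect_equal(relative_deviation(79.35, 80.11), 0.96)
  expect_equal(relative_deviation(77, 77), 0)
  expect_error(relative_deviation(0, 10), "> 0")
})

test_that("durability: retention-only and common-bias perturbations are null", {
  specs <- list(ref_spec("macrostemonoside_A"),
                ref_spec("macrostemonoside_T"))
  # all levels share the same area scale: RCFs identical, RSD 0
  fac <- list(column = c(a = 1, b = 1, c = 1),
              bias = c(lo = 1.05, hi = 1.05))
  d <- durability_study(specs[[1]], specs[2], factors = fac,
                        area_noise_cv = 0, seed = 1)
  expect_true(all(d$summary$rsd < 1e-10))
  # a systematic 5% bias on both analytes leaves the RCF unchanged
  rc <- split(d$conditions$rcf, d$conditions$factor)
  expect_equal(max(abs(unlist(rc) - d$conditions$rcf[1])), 0,
               tolerance = 1e-12)
  expect_warning(
    durability_study(specs[[1]], specs[2],
                     factors = c(fac, list(empty = numeric(0))),
                     area_noise_cv = 0),
    "skipping")
})

test_that("durability RSD stays under 2% with 1% area noise", {
  ok <- vapply(1:5, function(s) {
    d <- durability_study(ref_spec("macrostemonoside_A"),
                          list(ref_spec("macrostemonoside_T"),
                               ref_spec("macrostemonoside_U")),
                          area_noise_cv = 0.01, seed = s)
    all(d$summary$pass)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("validation statistics follow their definitions", {
  expect_equal(rsd(c(100, 100, 100)), 0)
  expect_equal(rsd(c(98, 100, 102)), 2.00)
  expect_error(rsd(5), "2 replicates")
  expect_error(rsd(c(-1, 1)), "zero mean")
  expect_equal(recovery(101.63, 50, 50), 103.26)
  expect_error(recovery(10, 0, 5), "> 0")
  vm <- validation_metrics(c(98, 100, 102), base = 50, spiked = 50,
                           measured_total = 101.63)
  expect_equal(vm$rsd, 2)
  expect_equal(vm$recovery, 103.26)
})
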