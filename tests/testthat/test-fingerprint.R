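fake_peaks <- function(times, areas = rep(100, length(times))) {
  structure(data.frame(peak_id = seq_along(times), apex_time = times,
                       left = times - 0.1, right = times + 0.1,
                       height = areas, area = areas,
                       snr = rep(Inf, length(times))),
            class = c("peak_list", "data.frame"))
}

test_that("retention warping is exact for identity and uniform shift", {
  ref <- c(a = 10, b = 30)
  pk <- list(B1 = fake_peaks(c(5, 10, 22, 30, 35)))
  idw <- correct_retention_times(pk, list(B1 = ref), ref)
  expect_equal(idw$B1$apex_time, pk$B1$apex_time)
  shifted <- list(B2 = fake_peaks(c(5, 10, 22, 30, 35) + 0.3))
  out <- correct_retention_times(shifted,
                                 list(B2 = ref + 0.3), ref)
  expect_equal(out$B2$apex_time, c(5, 10, 22, 30, 35), tolerance = 1e-9)
})

test_that("quadratic drift is largely removed by 4 markers", {
  true_t <- c(6, 11, 18, 23, 27, 33, 38, 44, 49)
  drift <- function(t) t + 0.002 * (t - 5)^2 / 5
  mk_names <- c("m1", "m2", "m3", "m4")
  mk_ref <- stats::setNames(true_t[c(1, 4, 6, 9)], mk_names)
  observed <- drift(true_t)
  out <- correct_retention_times(
    list(B = fake_peaks(observed)),
    list(B = stats::setNames(drift(mk_ref), mk_names)), mk_ref)
  raw_err <- max(abs(observed - true_t))
  corr_err <- max(abs(out$B$apex_time - true_t))
  expect_lt(corr_err, raw_err / 10)
})

test_that("non-monotone marker correspondence is rejected", {
  expect_error(warp_times(1:10, c(5, 10), c(10, 5)), "non-monotone")
  expect_error(warp_times(1:10, 5, 5), "2 marker")
})

test_that("common-peak matching respects the window and uniqueness", {
  ref <- fake_peaks(c(10, 20, 30))
  same <- list(A = ref, B = ref)
  tab <- match_common_peaks(same, "A", window = 0.1)
  expect_identical(length(tab$peak_ids), 3L)
  # one peak displaced beyond the window drops from the common set
  moved <- list(A = ref, B = fake_peaks(c(10, 20.2, 30)))
  tab2 <- match_common_peaks(moved, "A", window = 0.1)
  expect_identical(length(tab2$peak_ids), 2L)
  expect_error(match_common_peaks(list(A = ref, B = fake_peaks(numeric(0))),
                                  "A"), "empty peak list")
  expect_message(
    tab3 <- match_common_peaks(list(A = ref, B = fake_peaks(numeric(0))),
                               "A", allow_missing = TRUE), "dropping")
  expect_identical(tab3$batches, "A")
  expect_error(match_common_peaks(same, "A", window = 0), "window")
})

test_that("the default panel's common set is exactly the shared set", {
  tab <- match_panel(cached_panel())
  expect_identical(length(tab$peak_ids), 30L)
  # marker annotations land on the canonical fingerprint numbering
  expect_identical(unname(tab$markers[c("adenosine", "syringin",
                                        "macrostemonoside_T",
                                        "macrostemonoside_A",
                                        "macrostemonoside_U",
                                        "macrostemonoside_V")]),
                   c("peak_01", "peak_02", "peak_22", "peak_26", "peak_27",
                     "peak_28"))
  # matched areas agree with the seeded shared areas
  expect_equal(unname(tab$areas), unname(cached_panel()$truth$areas),
               tolerance = 0.01)
})

test_that("the averaged fingerprint is the column mean", {
  ref <- fake_peaks(c(10, 20))
  two <- list(A = fake_peaks(c(10, 20), c(10, 100)),
              B = fake_peaks(c(10, 20), c(30, 300)))
  tab <- match_common_peaks(two, "A")
  fp <- build_reference_fingerprint(tab)
  expect_equal(unname(fp$mean_areas), c(20, 200))
  one <- match_common_peaks(list(A = fake_peaks(c(10, 20), c(7, 9))), "A")
  expect_equal(unname(build_reference_fingerprint(one)$mean_areas), c(7, 9))
  expect_error(build_reference_fingerprint(tab, method = "median"),
               "unsupported")
})

test_that("cosine similarity identities hold", {
  expect_equal(similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(similarity(c(1, 1), c(1, 0)), 0.70711, tolerance = 1e-5)
  expect_error(similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(similarity(1:3, 1:2), "equal")
  set.seed(7)
  for (i in 1:20) {
    x <- stats::runif(12); y <- stats::runif(12)
    expect_equal(similarity(x, x), 1)
    expect_equal(similarity(3.7 * x, y), similarity(x, 0.2 * y))
    expect_equal(similarity(x, y), similarity(y, x))
  }
})

test_that("noiseless no-effect panel scores similarity 1 everywhere", {
  cfg <- panel_config(origin_effect = 1, processing_effect = 1,
                      area_noise_cv = 0, rt_shift_sd = 0, rt_jitter_sd = 0,
                      extras_per_batch = 0)
  areas <- simulate_panel(cfg)$truth$areas
  ref <- colMeans(areas)
  sims <- apply(areas, 1, similarity, ref)
  expect_equal(unname(sims), rep(1, 18))
})

test_that("similarity degrades monotonically with area noise", {
  med_sim <- function(cv) {
    vals <- vapply(1:3, function(s) {
      areas <- simulate_panel(panel_config(
        area_noise_cv = cv, extras_per_batch = 0, seed = s))$truth$areas
      stats::median(apply(areas, 1, similarity, colMeans(areas)))
    }, numeric(1))
    stats::median(vals)
  }
  sims <- vapply(c(0.01, 0.2, 0.6), med_sim, numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("peak table round-trips through its CSV interface", {
  tab <- match_panel(cached_panel())
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(tab, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(back$batch, tab$batches)
  expect_equal(as.matrix(back[, -1]), tab$areas, ignore_attr = TRUE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_identical(side$markers$macrostemonoside_A, "peak_26")
})
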