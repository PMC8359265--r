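mask_from_counts <- function(counts, nx = 6, ny = 6) {
  m <- array(FALSE, c(nx, ny, length(counts)))
  for (z in seq_along(counts)) {
    if (counts[z] > 0) m[seq_len(counts[z]), 1, z] <- TRUE
  }
  m
}

test_that("measurement slices are the most inferior contiguous visible triple", {
  expect_equal(select_measurement_slices(
    mask_from_counts(c(0, 5, 5, 5, 0, 0))), 2:4)
  expect_equal(select_measurement_slices(
    mask_from_counts(c(2, 2, 0, 3, 3, 3, 0))), 4:6)
  expect_equal(select_measurement_slices(
    mask_from_counts(rep(4, 10))), 1:3)
  # superior-to-inferior stored volumes pick the other end
  expect_equal(select_measurement_slices(
    mask_from_counts(rep(4, 10)), orientation = "SI"), 8:10)
  # visibility threshold
  expect_equal(select_measurement_slices(
    mask_from_counts(c(1, 1, 1, 5, 5, 5)), min_voxels = 2), 4:6)
  expect_error(select_measurement_slices(
    mask_from_counts(c(5, 5, 0, 5, 5, 0))),
    "longest available run: 2")
})

test_that("slice selection equals exhaustive scan over all contiguous triples", {
  set.seed(42)
  for (i in 1:60) {
    counts <- rpois(sample(4:12, 1), lambda = 1.2)
    orient <- sample(c("IS", "SI"), 1)
    mask <- mask_from_counts(counts)
    want <- oracle_slice_triple(counts, 1, orient)
    if (is.null(want)) {
      expect_error(select_measurement_slices(mask, orient), "not measurable")
    } else {
      expect_equal(select_measurement_slices(mask, orient), want)
    }
  }
})

test_that("slice summaries compute per-slice ROI means and background SD", {
  img <- nm_image(array(100, c(4, 4, 4)))
  sn <- array(FALSE, c(4, 4, 4)); sn[1:2, 1, ] <- TRUE
  bnd <- array(FALSE, c(4, 4, 4)); bnd[3:4, 4, ] <- TRUE
  masks <- roi_mask_pair(sn, bnd)
  sm <- summarize_slices(img, masks, 1:3)
  expect_equal(sm$sig_sn, rep(100, 3))
  expect_equal(sm$sig_bnd, rep(100, 3))
  expect_equal(sm$std_bnd, rep(0, 3))

  arr <- array(0, c(4, 4, 1))
  arr[1, 1, 1] <- 110; arr[2, 1, 1] <- 114
  arr[3, 4, 1] <- 98; arr[4, 4, 1] <- 102
  img2 <- nm_image(arr)
  masks2 <- roi_mask_pair(array(c(TRUE, TRUE, rep(FALSE, 14)), c(4, 4, 1)),
                          array(c(rep(FALSE, 14), TRUE, TRUE), c(4, 4, 1)))
  sm2 <- summarize_slices(img2, masks2, 1)
  expect_equal(sm2$sig_sn, 112)
  expect_equal(sm2$sig_bnd, 100)
  expect_equal(sm2$std_bnd, sqrt(8))     # sample SD over {98, 102}
  expect_equal(summarize_slices(img2, masks2, 1, "population")$std_bnd, 2)

  # adding a constant shifts the means, leaves the SD alone
  img3 <- nm_image(arr + 7)
  sm3 <- summarize_slices(img3, masks2, 1)
  expect_equal(sm3$sig_sn, sm2$sig_sn + 7)
  expect_equal(sm3$sig_bnd, sm2$sig_bnd + 7)
  expect_equal(sm3$std_bnd, sm2$std_bnd)
})

test_that("volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 3)); m[1:10, 1:10, 1] <- TRUE
  expect_equal(compute_volume(m, 1:3, c(0.4, 0.4, 3)), 48)
  expect_equal(569 * 0.48, 273.12)   # scale of healthy-volunteer means
  expect_equal(compute_volume(m, 1:3, c(0.8, 0.8, 6)),
               8 * compute_volume(m, 1:3, c(0.4, 0.4, 3)))
  # oracle: explicit enumeration over random masks
  set.seed(7)
  for (i in 1:20) {
    mm <- random_mask(c(5, 6, 7))
    sl <- sort(sample(7, 3))
    cnt <- 0
    for (x in 1:5) for (y in 1:6) for (z in sl) cnt <- cnt + mm[x, y, z]
    expect_equal(compute_volume(mm, sl, c(0.4, 0.4, 3)), cnt * 0.48)
  }
})

test_that("TIV correction divides mm^3 volume by cm^3 TIV", {
  expect_equal(round(compute_cvol(273.2, 1438), 2), 0.19)
  expect_equal(compute_cvol(0, 1400), 0)
  expect_equal(compute_cvol(250, 2800), compute_cvol(250, 1400) / 2)
  expect_error(compute_cvol(250, 0), "positive")
  expect_error(compute_cvol(250, -1), "positive")
})

test_that("SNR and CNR follow the slice-mean formulas and scale invariances", {
  sm <- data.frame(sig_sn = c(110, 112, 114), sig_bnd = c(100, 100, 100),
                   std_bnd = c(10, 10, 10))
  expect_equal(compute_snr(sm), 112)
  sm_eq <- transform(sm, sig_sn = sig_bnd)
  expect_equal(compute_snr(sm_eq), 100)
  expect_equal(compute_cnr(sm_eq), 0)
  sm_cnr <- data.frame(sig_sn = c(115, 112, 118), sig_bnd = 100,
                       std_bnd = 10)
  expect_equal(compute_cnr(sm_cnr), 1.5)
  # rescaling all intensities by k > 0 changes neither
  k <- 3.7
  sm_k <- data.frame(sig_sn = sm$sig_sn * k, sig_bnd = sm$sig_bnd * k,
                     std_bnd = sm$std_bnd * k)
  expect_equal(compute_snr(sm_k), compute_snr(sm))
  expect_equal(compute_cnr(sm_k), compute_cnr(sm))
  expect_error(compute_snr(transform(sm, sig_bnd = -1)), "background")
  expect_error(compute_cnr(transform(sm, std_bnd = 0)), "zero background SD")
})

test_that("SNR is 100 and CNR 0 whenever SN and background share a mean", {
  set.seed(13)
  for (i in 1:10) {
    arr <- array(rnorm(6 * 6 * 3, 100, 5), c(6, 6, 3))
    sn <- array(FALSE, c(6, 6, 3)); sn[1:2, 1:2, ] <- TRUE
    bnd <- array(FALSE, c(6, 6, 3)); bnd[5:6, 5:6, ] <- TRUE
    for (z in 1:3) {  # pin SN values at that slice's background mean
      arr[, , z][sn[, , z]] <- mean(arr[, , z][bnd[, , z]])
    }
    sm <- summarize_slices(nm_image(arr), roi_mask_pair(sn, bnd), 1:3)
    expect_equal(compute_snr(sm), 100)
    expect_equal(compute_cnr(sm), 0)
  }
})

test_that("percent differences use plain ratios except background-referenced SNR", {
  expect_equal(round(percent_difference(242.5, 273.2, "vol"), 1), -11.2)
  expect_equal(round(percent_difference(110.0, 112.1, "snr"), 1), -17.4)
  for (k in c("vol", "cvol", "cnr", "snr"))
    expect_equal(percent_difference(112, 112, k), 0)
  # raw-ratio option for SNR
  expect_equal(percent_difference(110, 112.1, "snr", snr_referenced = FALSE),
               (110 - 112.1) / 112.1 * 100)
  expect_error(percent_difference(105, 100, "snr"), "background floor")
  expect_error(percent_difference(105, 0, "vol"), "zero reference")
})

test_that("annualized rates divide the percent change by the delay", {
  expect_equal(annual_rate(300, 300, 2, "vol"), 0)
  expect_equal(annual_rate(300, 270, 2.0, "vol"), -5)
  expect_error(annual_rate(300, 270, 0, "vol"), "positive")
  # cohort helper excludes subjects missing a visit, with a message
  tab <- data.frame(
    subject_id = c("a", "a", "b", "c", "c"),
    group = c("PD", "PD", "PD", "PD", "PD"),
    visit = c("V1", "V2", "V1", "V1", "V2"),
    delay_years = c(0, 2, 0, 0, 2),
    vol_mm3 = c(300, 270, 250, 200, 190))
  expect_message(rc <- annual_rate_cohort(tab, "vol_mm3"), "1 subject")
  expect_equal(rc$n, 2)
  expect_equal(rc$mean_rate, mean(c(-5, -2.5)))
  expect_equal(attr(rc, "n_excluded"), 1L)
})

test_that("quantifying a rendered phantom recovers the cohort ground truth", {
  co <- generate_cohort(tiny_design(), seed = 17)
  row <- co$truth[3, ]
  ph <- generate_phantom(phantom_spec_for(row), seed = 23)
  q <- quantify_scan(ph$image, ph$masks, tiv_cm3 = 1400)
  expect_lt(abs(q$vol_mm3 - row$vol_true_mm3), 0.48 + 1e-9)
  expect_lt(abs(q$snr - row$snr_true), 1.5)
  expect_lt(abs(q$cnr - row$cnr_true), 0.35)
})
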