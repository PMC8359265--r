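#' Select the three lowest contiguous slices in which the SN is visible
#'
#' SN volumetry on neuromelanin-sensitive images is performed over the three
#' most inferior contiguous axial slices showing the structure; this routine
#' finds that run deterministically. A slice counts as "visible" when the SN
#' mask holds at least `min_voxels` voxels on it.
#'
#' @param sn_mask logical 3-D array.
#' @param orientation `"IS"` (slice 1 most inferior) or `"SI"`.
#' @param min_voxels minimum SN voxels per slice for visibility (default 1).
#' @return Integer vector of 3 slice indices, ascending.
#' @export
select_measurement_slices <- function(sn_mask, orientation = c("IS", "SI"),
                                      min_voxels = 1L) {
  orientation <- match.arg(orientation)
  counts <- apply(sn_mask, 3, sum)
  ok <- counts >= min_voxels
  nz <- length(ok)
  starts <- which(ok[seq_len(max(nz - 2, 0))] &
                    ok[seq_len(max(nz - 2, 0)) + 1L] &
                    ok[seq_len(max(nz - 2, 0)) + 2L])
  if (!length(starts)) {
    r <- rle(ok)
    longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    stop("SN not measurable: no run of 3 contiguous visible slices ",
         "(longest available run: ", longest, ")", call. = FALSE)
  }
  start <- if (orientation == "IS") min(starts) else max(starts)
  seq.int(start, length.out = 3L)
}

#' Per-slice signal summaries over the SN and background ROIs
#'
#' For each selected slice, the mean SN signal, the mean background signal,
#' and the background standard deviation — the ingredients of the slice-wise
#' SNR and CNR.
#'
#' @param image an [nm_image].
#' @param masks an [roi_mask_pair] on the image grid.
#' @param slices integer slice indices (normally from
#'   [select_measurement_slices()]).
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`
#'   for the background SD.
#' @return Data frame with columns `slice_index`, `sig_sn`, `sig_bnd`,
#'   `std_bnd`, `n_sn_voxels`.
#' @export
summarize_slices <- function(image, masks, slices,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  check_mask_grid(image, masks)
  out <- lapply(slices, function(z) {
    sn <- image$intensities[, , z][masks$sn_mask[, , z]]
    bnd <- image$intensities[, , z][masks$bnd_mask[, , z]]
    if (!length(sn))
      stop("SN mask empty on selected slice ", z, call. = FALSE)
    if (!length(bnd))
      stop("background mask empty on selected slice ", z, call. = FALSE)
    s2 <- if (length(bnd) > 1) stats::var(bnd) else 0
    if (sd_type == "population") s2 <- s2 * (length(bnd) - 1) / length(bnd)
    data.frame(slice_index = z, sig_sn = mean(sn), sig_bnd = mean(bnd),
               std_bnd = sqrt(s2), n_sn_voxels = length(sn))
  })
  do.call(rbind, out)
}

#' SN volume over the measurement slices
#'
#' @param sn_mask logical 3-D array.
#' @param slices the 3 measurement slice indices.
#' @param voxel_size voxel dimensions in mm.
#' @return Volume in mm^3: SN voxel count on those slices times voxel volume.
#' @export
compute_volume <- function(sn_mask, slices, voxel_size) {
  n <- sum(sn_mask[, , slices])
  n * prod(voxel_size)
}

#' TIV-corrected SN volume
#'
#' Head size is normalized by dividing the SN volume (mm^3) by the total
#' intracranial volume in cm^3; with a ~1.4 L TIV this puts C_vol on the
#' ~0.2 scale conventional in the field.
#'
#' @param vol_mm3 SN volume, mm^3.
#' @param tiv_cm3 total intracranial volume, cm^3 (> 0).
#' @return `vol_mm3 / tiv_cm3` (mm^3/cm^3).
#' @export
compute_cvol <- function(vol_mm3, tiv_cm3) {
  if (any(tiv_cm3 <= 0)) stop("TIV must be positive (cm^3)", call. = FALSE)
  vol_mm3 / tiv_cm3
}

#' Signal-to-noise ratio of the SN
#'
#' Mean over the measurement slices of (mean SN signal / mean background
#' signal) x 100; 100 means no neuromelanin contrast.
#'
#' @param summaries output of [summarize_slices()].
#' @return SNR (dimensionless, x100 scale).
#' @export
compute_snr <- function(summaries) {
  if (any(summaries$sig_bnd <= 0))
    stop("non-positive background signal: SNR undefined", call. = FALSE)
  mean(summaries$sig_sn / summaries$sig_bnd * 100)
}

#' Contrast-to-noise ratio of the SN
#'
#' Mean over the measurement slices of (mean SN signal - mean background
#' signal) / background SD.
#'
#' @param summaries output of [summarize_slices()].
#' @return CNR (dimensionless).
#' @export
compute_cnr <- function(summaries) {
  if (any(summaries$std_bnd <= 0))
    stop("zero background SD (noiseless background): CNR undefined",
         call. = FALSE)
  mean((summaries$sig_sn - summaries$sig_bnd) / summaries$std_bnd)
}

#' Quantify one scan: Vol, C_vol, SNR, CNR
#'
#' Runs slice selection, per-slice summaries, and the four SN measurements
#' on a single image/mask pair.
#'
#' @param image an [nm_image].
#' @param masks an [roi_mask_pair].
#' @param tiv_cm3 total intracranial volume (cm^3) for C_vol.
#' @param min_voxels slice-visibility threshold.
#' @param sd_type background SD estimator, see [summarize_slices()].
#' @return One-row data frame: `vol_mm3`, `cvol`, `snr`, `cnr`, and
#'   `slice_lo`/`slice_hi`, the bounds of the measurement run.
#' @export
quantify_scan <- function(image, masks, tiv_cm3, min_voxels = 1L,
                          sd_type = "sample") {
  slices <- select_measurement_slices(masks$sn_mask, image$orientation,
                                      min_voxels)
  sm <- summarize_slices(image, masks, slices, sd_type)
  vol <- compute_volume(masks$sn_mask, slices, image$voxel_size)
  cnr <- if (all(sm$std_bnd > 0)) compute_cnr(sm) else NA_real_
  data.frame(vol_mm3 = vol, cvol = compute_cvol(vol, tiv_cm3),
             snr = compute_snr(sm), cnr = cnr,
             slice_lo = min(slices), slice_hi = max(slices))
}

#' Percent difference between two measurement values
#'
#' For volume, corrected volume and CNR this is the plain relative change
#' `(value - reference)/reference x 100`. SNR is referenced to background:
#' since 100 is the no-contrast floor, changes are expressed relative to the
#' contrast actually carried, `(value - reference)/(reference - 100) x 100`.
#'
#' @param value,reference measurement values (e.g. PD and HV group means, or
#'   V2 and V1 values). Vectorized.
#' @param measure_kind one of `"vol"`, `"cvol"`, `"cnr"`, `"snr"`.
#' @param snr_referenced if `FALSE`, treat SNR like the other measures (raw
#'   ratio change) instead of background-referenced.
#' @return Percent difference.
#' @export
percent_difference <- function(value, reference,
                               measure_kind = c("vol", "cvol", "cnr", "snr"),
                               snr_referenced = TRUE) {
  measure_kind <- match.arg(measure_kind)
  if (measure_kind == "snr" && snr_referenced) {
    if (any(reference == 100))
      stop("SNR reference equals the background floor (100): ",
           "percent difference undefined", call. = FALSE)
    (value - reference) / (reference - 100) * 100
  } else {
    if (any(reference == 0))
      stop("zero reference value: percent difference undefined",
           call. = FALSE)
    (value - reference) / reference * 100
  }
}

#' Annualized rate of change of a measurement
#'
#' Per-subject percent change from V1 to V2 divided by the inter-visit delay
#' in years. Vectorized over subjects.
#'
#' @param value_v1,value_v2 measurement at each visit.
#' @param delay_years inter-visit delay (> 0), years.
#' @param measure_kind as in [percent_difference()].
#' @param snr_referenced as in [percent_difference()].
#' @return Percent per year.
#' @export
annual_rate <- function(value_v1, value_v2, delay_years,
                        measure_kind = c("vol", "cvol", "cnr", "snr"),
                        snr_referenced = TRUE) {
  if (any(delay_years <= 0))
    stop("`delay_years` must be positive", call. = FALSE)
  percent_difference(value_v2, value_v1, measure_kind, snr_referenced) /
    delay_years
}

#' Cohort mean annual rates of change
#'
#' Computes each retained subject's annualized rate (V1 -> V2) for one
#' measurement column and averages over subjects, per group. Subjects missing
#' either visit are excluded; the exclusion count is attached and messaged.
#'
#' @param measurements long table with `subject_id`, `visit` (V1/V2),
#'   `group`, `delay_years` and the measurement column.
#' @param measure column name (`"vol_mm3"`, `"cvol"`, `"snr"`, `"cnr"`).
#' @param measure_kind as in [percent_difference()]; defaults to the kind
#'   inferred from `measure`.
#' @return Data frame with columns `group`, `mean_rate`, `sd_rate`, `n`;
#'   attribute `n_excluded` counts subjects without both visits. The
#'   per-subject rates are attached as attribute `rates`.
#' @export
annual_rate_cohort <- function(measurements, measure,
                               measure_kind = infer_kind(measure)) {
  w <- stats::reshape(
    measurements[, c("subject_id", "group", "visit", "delay_years", measure)],
    direction = "wide", idvar = c("subject_id", "group"), timevar = "visit")
  v1 <- w[[paste0(measure, ".V1")]]
  v2 <- w[[paste0(measure, ".V2")]]
  keep <- !is.na(v1) & !is.na(v2)
  n_excluded <- sum(!keep)
  if (n_excluded)
    message(n_excluded, " subject(s) without both visits excluded from ",
            "annual-rate estimation")
  delay <- w[["delay_years.V2"]][keep]
  rates <- annual_rate(v1[keep], v2[keep], delay, measure_kind)
  grp <- w$group[keep]
  out <- do.call(rbind, lapply(split(rates, grp), function(r)
    data.frame(mean_rate = mean(r), sd_rate = stats::sd(r), n = length(r))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  attr(out, "rates") <- data.frame(subject_id = w$subject_id[keep],
                                   group = grp, rate = rates)
  out
}

infer_kind <- function(measure) {
  switch(measure,
         vol_mm3 = "vol", vol = "vol", cvol = "cvol",
         snr = "snr", cnr = "cnr",
         stop("cannot infer measure kind from column `", measure,
              "`; pass `measure_kind`", call. = FALSE))
}
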