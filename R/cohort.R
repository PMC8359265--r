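#' Design of a synthetic neuromelanin MRI cohort
#'
#' Parameterizes the generative model behind [generate_cohort()]: group sizes,
#' baseline SN measurement distributions for healthy volunteers (HV), the
#' fractional deficits applied to the Parkinson's disease (PD) group,
#' annualized progression rates, demographics, scanner labelling, the target
#' correlation between motor severity and TIV-corrected volume, and follow-up
#' dropout. Two presets reproduce the study conditions of an early-PD cohort
#' (PRISMA scanner, ~2-year follow-up of both groups) and a progressing-PD
#' cohort (TRIO scanner, longer disease duration, PD-only follow-up); any
#' field can be overridden.
#'
#' SNR is handled throughout on its background-referenced excess scale
#' (SNR - 100, the contrast actually carried by neuromelanin): the PD deficit
#' and the annual rates apply to the excess, not to the raw ratio.
#' TIV-corrected volume is never generated directly; it is the quotient of
#' the generated volume and TIV, so its group deficit and decline follow
#' volume, and its sex difference arises from the male-female TIV gap.
#'
#' @param cohort `"cohort1"` (early PD) or `"cohort2"` (progressing PD)
#'   preset.
#' @param ... named overrides of any design field.
#' @return An object of class `cohort_design`.
#' @examples
#' d <- cohort_design("cohort1", n_pd = 20, n_hv = 10)
#' @export
cohort_design <- function(cohort = c("cohort1", "cohort2"), ...) {
  cohort <- match.arg(cohort)
  base <- list(
    cohort_label      = "early",
    scanner           = "PRISMA",
    n_hv              = 41L,
    n_pd              = 99L,
    male_frac_hv      = 17 / 41,
    male_frac_pd      = 66 / 99,
    age_mean_sd       = c(mean = 61, sd = 9),
    vol_hv_mean_sd    = c(mean = 273.2, sd = 48.4),
    vol_sd_pd         = 50.2,
    pd_vol_deficit_frac = (273.2 - 242.5) / 273.2,
    snr_hv_mean_sd    = c(mean = 112.1, sd = 1.6),
    snr_sd_pd         = 1.6,
    snr_deficit_frac  = (112.1 - 110.0) / (112.1 - 100),
    cnr_hv_mean_sd    = c(mean = 1.56, sd = 0.23),
    cnr_sd_pd         = 0.27,
    cnr_deficit_frac  = (1.56 - 1.25) / 1.56,
    annual_decline_pd = c(vol = -5.8, snr = 1.5, cnr = 1.9),
    annual_decline_hv = c(vol = 0.4, snr = 0.8, cnr = 3.9),
    rate_sd           = c(vol = 4, snr = 2.5, cnr = 3),
    sex_effect        = c(vol = 0, snr = 0, cnr = 0),
    scanner_offset    = c(vol = 0, snr = 0, cnr = 0),
    tiv_mean_sd       = c(mean = 1370, sd = 110),
    tiv_male_offset   = 140,
    visit_delay       = c(mean = 2.0, sd = 0.2),
    clinical_corr_rho = -0.4,
    dropout_frac      = 0.2,
    hv_followup       = TRUE,
    updrs_pd_mean_sd  = c(mean = 30.3, sd = 7.9),
    updrs_hv_mean_sd  = c(mean = 5.7, sd = 5.8),
    updrs_slope_mean_sd = c(mean = 1.65, sd = 1.0),
    duration_mean_sd  = c(mean = 1.5, sd = 1.0),
    hy_mean_sd        = c(mean = 2.0, sd = 0.2),
    ledd_mean_sd      = c(mean = 309, sd = 258),
    seed              = 1L
  )
  if (cohort == "cohort2") {
    base <- utils::modifyList(base, list(
      cohort_label      = "progressing",
      scanner           = "TRIO",
      n_hv              = 23L,
      n_pd              = 41L,
      male_frac_hv      = 12 / 23,
      male_frac_pd      = 27 / 41,
      vol_hv_mean_sd    = c(mean = 260.4, sd = 37.0),
      vol_sd_pd         = 63.6,
      pd_vol_deficit_frac = (260.4 - 160.3) / 260.4,
      snr_hv_mean_sd    = c(mean = 109.8, sd = 2.4),
      snr_sd_pd         = 2.1,
      snr_deficit_frac  = (109.8 - 107.7) / (109.8 - 100),
      cnr_hv_mean_sd    = c(mean = 1.30, sd = 0.39),
      cnr_sd_pd         = 0.29,
      cnr_deficit_frac  = (1.30 - 1.01) / 1.30,
      annual_decline_pd = c(vol = -10.2, snr = -3.7, cnr = -3.0),
      visit_delay       = c(mean = 2.4, sd = 0.5),
      dropout_frac      = 11 / 41,
      hv_followup       = FALSE,
      updrs_pd_mean_sd  = c(mean = 38.8, sd = 10.8),
      duration_mean_sd  = c(mean = 9.3, sd = 3.7),
      hy_mean_sd        = c(mean = 2.0, sd = 0.6),
      ledd_mean_sd      = c(mean = 761, sd = 292)
    ))
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    stop("unknown cohort_design field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  d <- utils::modifyList(base, over)
  validate_cohort_design(d)
  structure(d, class = "cohort_design")
}

validate_cohort_design <- function(d) {
  fr <- c(pd_vol_deficit_frac = d$pd_vol_deficit_frac,
          snr_deficit_frac = d$snr_deficit_frac,
          cnr_deficit_frac = d$cnr_deficit_frac,
          dropout_frac = d$dropout_frac,
          male_frac_hv = d$male_frac_hv, male_frac_pd = d$male_frac_pd)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "), call. = FALSE)
  if (d$n_hv < 2 || d$n_pd < 2) stop("need >= 2 subjects per group",
                                     call. = FALSE)
  sds <- c(d$vol_hv_mean_sd["sd"], d$snr_hv_mean_sd["sd"],
           d$cnr_hv_mean_sd["sd"], d$tiv_mean_sd["sd"], d$visit_delay["sd"],
           d$vol_sd_pd, d$snr_sd_pd, d$cnr_sd_pd, d$rate_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (abs(d$clinical_corr_rho) >= 1)
    stop("|clinical_corr_rho| must be < 1 (correlation not attainable)",
         call. = FALSE)
  invisible(d)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %s PD cohort: %d PD / %d HV, scanner %s\n",
    x$cohort_label, x$n_pd, x$n_hv, x$scanner))
  cat(sprintf("  baseline Vol HV %.1f mm3, PD deficit %.1f%%; annual Vol rate PD %.1f %%/yr\n",
              x$vol_hv_mean_sd["mean"], 100 * x$pd_vol_deficit_frac,
              x$annual_decline_pd["vol"]))
  invisible(x)
}

trunc0 <- function(x) pmax(x, 0)

#' Generate a synthetic subject cohort with longitudinal SN truth values
#'
#' Draws one row per subject per visit. Baseline ("V1") SN truth values come
#' from the design's group distributions with sex and scanner offsets;
#' follow-up ("V2") values are the V1 values progressed by a per-subject
#' annual rate times the realized inter-visit delay (SNR on its excess
#' scale). Motor severity (MDS-UPDRS-III OFF) is built by a bivariate-normal
#' construction against the standardized baseline TIV-corrected volume so the
#' PD population correlation equals `clinical_corr_rho`; LEDD is drawn
#' independently of all imaging measures. Dropout removes a random subset of
#' follow-up rows only.
#'
#' @param design a [cohort_design].
#' @param seed integer seed (defaults to the design's own).
#' @return A list with class `nm_cohort`:
#'   `subjects` — demographic/clinical table, one row per subject-visit, with
#'   columns `subject_id, visit, group, sex, age, scanner, delay_years,
#'   tiv_cm3, updrs3_off, disease_duration_yr, hy_stage, ledd_mg`;
#'   `truth` — per-subject-visit SN ground truth and per-scan phantom
#'   parameters (`vol_true_mm3`, `snr_true`, `cnr_true`, `bnd_mean`,
#'   `bnd_sd`, `sn_target_volume_mm3`).
#' @export
generate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  d <- design
  n <- d$n_hv + d$n_pd
  group <- rep(c("HV", "PD"), c(d$n_hv, d$n_pd))
  id <- sprintf("S%03d", seq_len(n))
  n_male_hv <- round(d$male_frac_hv * d$n_hv)
  n_male_pd <- round(d$male_frac_pd * d$n_pd)
  sex <- c(rep(c("M", "F"), c(n_male_hv, d$n_hv - n_male_hv)),
           rep(c("M", "F"), c(n_male_pd, d$n_pd - n_male_pd)))
  age <- stats::rnorm(n, d$age_mean_sd["mean"], d$age_mean_sd["sd"])
  male <- sex == "M"
  tiv <- stats::rnorm(n, d$tiv_mean_sd["mean"], d$tiv_mean_sd["sd"]) +
    ifelse(male, d$tiv_male_offset, 0)
  is_pd <- group == "PD"

  mean_of <- function(hv_mean, deficit) hv_mean * (1 - ifelse(is_pd, deficit, 0))
  sd_of <- function(hv_sd, pd_sd) ifelse(is_pd, pd_sd, hv_sd)

  vol1 <- stats::rnorm(n,
    mean_of(d$vol_hv_mean_sd["mean"], d$pd_vol_deficit_frac) +
      ifelse(male, d$sex_effect["vol"], 0) + d$scanner_offset["vol"],
    sd_of(d$vol_hv_mean_sd["sd"], d$vol_sd_pd))
  vol1 <- trunc0(vol1)
  snr_exc1 <- stats::rnorm(n,
    mean_of(d$snr_hv_mean_sd["mean"] - 100, d$snr_deficit_frac) +
      ifelse(male, d$sex_effect["snr"], 0) + d$scanner_offset["snr"],
    sd_of(d$snr_hv_mean_sd["sd"], d$snr_sd_pd))
  snr_exc1 <- pmax(snr_exc1, 0.5)
  cnr1 <- stats::rnorm(n,
    mean_of(d$cnr_hv_mean_sd["mean"], d$cnr_deficit_frac) +
      ifelse(male, d$sex_effect["cnr"], 0) + d$scanner_offset["cnr"],
    sd_of(d$cnr_hv_mean_sd["sd"], d$cnr_sd_pd))
  cnr1 <- pmax(cnr1, 0.05)

  # follow-up: per-subject annual rates (%/yr) around the group means
  delay <- pmax(stats::rnorm(n, d$visit_delay["mean"], d$visit_delay["sd"]), 0.5)
  rate <- sapply(c("vol", "snr", "cnr"), function(m)
    stats::rnorm(n, ifelse(is_pd, d$annual_decline_pd[m],
                           d$annual_decline_hv[m]), d$rate_sd[m]))
  vol2 <- trunc0(vol1 * (1 + rate[, "vol"] * delay / 100))
  snr_exc2 <- pmax(snr_exc1 * (1 + rate[, "snr"] * delay / 100), 0.5)
  cnr2 <- pmax(cnr1 * (1 + rate[, "cnr"] * delay / 100), 0.05)

  has_v2 <- stats::runif(n) < (1 - d$dropout_frac)
  if (!d$hv_followup) has_v2[!is_pd] <- FALSE

  # clinical scores; UPDRS-III tied to baseline corrected volume in PD
  cvol1 <- vol1 / tiv
  z_cvol_pd <- as.numeric(scale(cvol1[is_pd]))
  rho <- d$clinical_corr_rho
  eps <- stats::rnorm(sum(is_pd))
  updrs1 <- numeric(n)
  updrs1[is_pd] <- trunc0(d$updrs_pd_mean_sd["mean"] + d$updrs_pd_mean_sd["sd"] *
                            (rho * z_cvol_pd + sqrt(1 - rho^2) * eps))
  updrs1[!is_pd] <- trunc0(stats::rnorm(sum(!is_pd), d$updrs_hv_mean_sd["mean"],
                                        d$updrs_hv_mean_sd["sd"]))
  updrs_slope <- stats::rnorm(n, d$updrs_slope_mean_sd["mean"],
                              d$updrs_slope_mean_sd["sd"])
  updrs2 <- trunc0(updrs1 + ifelse(is_pd, updrs_slope * delay, 0))
  dur1 <- ifelse(is_pd,
                 trunc0(stats::rnorm(n, d$duration_mean_sd["mean"],
                                     d$duration_mean_sd["sd"])), NA_real_)
  hy1 <- ifelse(is_pd,
                pmin(pmax(stats::rnorm(n, d$hy_mean_sd["mean"],
                                       d$hy_mean_sd["sd"]), 0), 5), NA_real_)
  ledd1 <- ifelse(is_pd, trunc0(stats::rnorm(n, d$ledd_mean_sd["mean"],
                                             d$ledd_mean_sd["sd"])), NA_real_)
  ledd2 <- ifelse(is_pd, trunc0(ledd1 + stats::rnorm(n, 85, 60) * delay),
                  NA_real_)

  row_for <- function(visit) {
    v2 <- visit == "V2"
    data.frame(
      subject_id = id, visit = visit, group = group, sex = sex,
      age = age + if (v2) delay else 0,
      scanner = d$scanner,
      delay_years = if (v2) delay else 0,
      tiv_cm3 = tiv,
      updrs3_off = if (v2) updrs2 else updrs1,
      disease_duration_yr = if (v2) dur1 + delay else dur1,
      hy_stage = hy1,
      ledd_mg = if (v2) ledd2 else ledd1,
      stringsAsFactors = FALSE
    )
  }
  truth_for <- function(visit) {
    v2 <- visit == "V2"
    snr <- 100 + if (v2) snr_exc2 else snr_exc1
    cnr <- if (v2) cnr2 else cnr1
    data.frame(
      subject_id = id, visit = visit, group = group,
      vol_true_mm3 = if (v2) vol2 else vol1,
      snr_true = snr, cnr_true = cnr,
      bnd_mean = 100, bnd_sd = (snr - 100) / cnr,
      sn_target_volume_mm3 = (if (v2) vol2 else vol1) / 2,
      stringsAsFactors = FALSE
    )
  }
  subjects <- rbind(row_for("V1"), row_for("V2")[has_v2, ])
  truth <- rbind(truth_for("V1"), truth_for("V2")[has_v2, ])
  rownames(subjects) <- rownames(truth) <- NULL
  structure(list(design = d, subjects = subjects, truth = truth,
                 seed = as.integer(seed)),
            class = "nm_cohort")
}

#' Simulate the measurement step over a generated cohort
#'
#' Adds measurement error to the cohort's ground-truth SN values, emulating
#' what ROI quantification of the rendered phantoms recovers (tracing and
#' estimator noise), and returns a measurement table joined to the subject
#' covariates. For a pixel-level end-to-end check use [phantom_spec_for()]
#' with [generate_phantom()] and [quantify_scan()] instead.
#'
#' @param cohort an `nm_cohort` from [generate_cohort()].
#' @param noise named numeric: `vol_frac` (fractional SD on volume),
#'   `snr_abs` (absolute SD on SNR), `cnr_abs` (absolute SD on CNR).
#' @param seed integer seed.
#' @return Data frame with one row per subject-visit: subject covariates plus
#'   `vol_mm3`, `cvol`, `snr`, `cnr`.
#' @export
measure_cohort <- function(cohort,
                           noise = c(vol_frac = 0.02, snr_abs = 0.4,
                                     cnr_abs = 0.08),
                           seed = cohort$seed + 1L) {
  stopifnot(inherits(cohort, "nm_cohort"))
  set.seed(as.integer(seed))
  tr <- cohort$truth
  n <- nrow(tr)
  vol <- trunc0(tr$vol_true_mm3 * (1 + stats::rnorm(n, 0, noise["vol_frac"])))
  snr <- tr$snr_true + stats::rnorm(n, 0, noise["snr_abs"])
  cnr <- pmax(tr$cnr_true + stats::rnorm(n, 0, noise["cnr_abs"]), 0.01)
  meas <- data.frame(subject_id = tr$subject_id, visit = tr$visit,
                     vol_mm3 = vol, snr = snr, cnr = cnr,
                     stringsAsFactors = FALSE)
  out <- merge(cohort$subjects, meas, by = c("subject_id", "visit"),
               sort = FALSE)
  out$cvol <- out$vol_mm3 / out$tiv_cm3
  out[order(out$visit, out$subject_id), ]
}

#' Phantom specification for one cohort scan
#'
#' Maps a row of the cohort truth table to a [phantom_spec] whose noiseless
#' measurements equal the row's ground truth (volume per side, SNR, and —
#' through the background noise SD — CNR).
#'
#' @param truth_row one row of `cohort$truth`.
#' @param grid_shape,voxel_size passed to [phantom_spec].
#' @return A [phantom_spec].
#' @export
phantom_spec_for <- function(truth_row, grid_shape = c(96, 96, 12),
                             voxel_size = c(0.4, 0.4, 3)) {
  stopifnot(nrow(truth_row) == 1L)
  phantom_spec(
    grid_shape = grid_shape, voxel_size = voxel_size,
    bnd_mean = truth_row$bnd_mean, bnd_sd = truth_row$bnd_sd,
    sn_target_volume = truth_row$sn_target_volume_mm3,
    sn_target_snr = truth_row$snr_true
  )
}
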