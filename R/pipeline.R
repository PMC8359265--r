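subject_table_columns <- c(
  "subject_id", "visit", "group", "sex", "age", "scanner", "delay_years",
  "tiv_cm3", "updrs3_off", "disease_duration_yr", "hy_stage", "ledd_mg")

#' Read and validate a subject-visit table
#'
#' CSV dialect is fixed: UTF-8, comma separator, `.` decimal. One row per
#' subject per visit; clinical columns may be `NA` for healthy volunteers.
#' Units are checked where the value makes them checkable: TIV in cm^3
#' (plausible head sizes), delay in years, Hoehn-Yahr in \[0, 5\].
#'
#' @param path CSV path with header columns `subject_id, visit, group, sex,
#'   age, scanner, delay_years, tiv_cm3, updrs3_off, disease_duration_yr,
#'   hy_stage, ledd_mg`.
#' @return The validated data frame.
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(subject_table_columns, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  problems <- character()
  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      problems <<- c(problems, paste0(what, " in row(s) ",
                                      paste(rows, collapse = ", ")))
  }
  bad_rows(!tab$visit %in% c("V1", "V2"), "visit label outside {V1, V2}")
  bad_rows(!tab$group %in% c("HV", "PD"), "group label outside {HV, PD}")
  bad_rows(!tab$sex %in% c("M", "F"), "sex label outside {M, F}")
  bad_rows(!is.na(tab$age) & tab$age <= 0, "age <= 0")
  bad_rows(!is.na(tab$tiv_cm3) & (tab$tiv_cm3 < 800 | tab$tiv_cm3 > 2500),
           "implausible TIV (expected cm^3, ~800-2500)")
  bad_rows(!is.na(tab$delay_years) & (tab$delay_years < 0 |
                                        tab$delay_years > 20),
           "implausible inter-visit delay (expected years)")
  bad_rows(!is.na(tab$hy_stage) & (tab$hy_stage < 0 | tab$hy_stage > 5),
           "Hoehn-Yahr stage outside [0, 5]")
  bad_rows(!is.na(tab$ledd_mg) & tab$ledd_mg < 0, "negative LEDD")
  dup <- duplicated(tab[, c("subject_id", "visit")])
  bad_rows(dup, "duplicated (subject_id, visit) pair")
  if (length(problems))
    stop("subject table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  tab
}

default_run_config <- function() {
  list(
    stages = c("simulate", "quantify", "reliability", "stats", "power"),
    out_dir = "results",
    seed = 1L,
    cohort = "cohort1",
    design = list(),                  # cohort_design overrides
    n_render = 2L,                    # scans rendered as voxel phantoms
    rater_shift_prob = 0.15,
    n_perm = 2000L,
    effects = c(0.3, 0.5, 0.7),
    powers = c(0.8, 0.9),
    alpha = 0.05,
    write_images = FALSE
  )
}

validate_run_config <- function(config) {
  base <- default_run_config()
  bad <- setdiff(names(config), names(base))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(base, config)
  known <- c("simulate", "quantify", "reliability", "stats", "power")
  if (!all(cfg$stages %in% known))
    stop("unknown stage(s): ",
         paste(setdiff(cfg$stages, known), collapse = ", "), call. = FALSE)
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Read a CSV written by [run_pipeline()] (skipping the provenance stamp)
#' @param path CSV path.
#' @return Data frame.
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> quantify -> reliability -> stats -> power on a
#' synthetic cohort, writing one CSV per product into `out_dir` (each
#' stamped with the config hash and seed) plus a JSON run report with stage
#' status, output hashes, and exclusion accounting. Identical configs and
#' seeds give byte-identical outputs.
#'
#' The quantify stage renders `n_render` scans as voxel phantoms and runs
#' full ROI quantification on them as an end-to-end check; the measurement
#' table for the statistical stages comes from [measure_cohort()].
#'
#' @param config named list overriding the default configuration (unknown
#'   keys are an error), or a path to a JSON file with the same structure.
#'   Keys: `stages`, `out_dir`, `seed`, `cohort`, `design`, `n_render`,
#'   `rater_shift_prob`, `n_perm`, `effects`, `powers`, `alpha`,
#'   `write_images`.
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  seed <- as.integer(cfg$seed)
  report <- list(config_hash = hash, seed = seed, stages = list(),
                 exclusions = list())
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_stamped_csv(df, p, hash, seed)
    outputs[[name]] <<- p
  }
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return()
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- "ok"
  }

  design <- do.call(cohort_design, c(list(cohort = cfg$cohort), cfg$design))
  cohort <- NULL; meas <- NULL

  run_stage("simulate", function() {
    cohort <<- generate_cohort(design, seed = seed)
    emit(cohort$subjects, "subjects.csv")
    emit(cohort$truth, "truth.csv")
    if (cfg$write_images) {
      img_dir <- file.path(cfg$out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (i in seq_len(min(cfg$n_render, nrow(cohort$truth)))) {
        row <- cohort$truth[i, ]
        ph <- generate_phantom(phantom_spec_for(row), seed = seed + i)
        write_nm_scan(ph$image, ph$masks,
                      file.path(img_dir, sprintf("%s_%s.nii.gz",
                                                 row$subject_id, row$visit)),
                      file.path(img_dir, sprintf("%s_%s_labels.nii.gz",
                                                 row$subject_id, row$visit)))
      }
    }
  })
  run_stage("quantify", function() {
    if (is.null(cohort)) cohort <<- generate_cohort(design, seed = seed)
    meas <<- measure_cohort(cohort, seed = seed + 1L)
    emit(meas, "measurements.csv")
    n_r <- min(cfg$n_render, nrow(cohort$truth))
    rendered <- lapply(seq_len(n_r), function(i) {
      row <- cohort$truth[i, ]
      ph <- generate_phantom(phantom_spec_for(row), seed = seed + i)
      sub <- cohort$subjects[cohort$subjects$subject_id == row$subject_id &
                               cohort$subjects$visit == row$visit, ]
      cbind(subject_id = row$subject_id, visit = row$visit,
            quantify_scan(ph$image, ph$masks, sub$tiv_cm3),
            vol_true_mm3 = row$vol_true_mm3, snr_true = row$snr_true)
    })
    emit(do.call(rbind, rendered), "rendered_check.csv")
  })
  run_stage("reliability", function() {
    if (is.null(cohort)) cohort <<- generate_cohort(design, seed = seed)
    if (is.null(meas)) meas <<- measure_cohort(cohort, seed = seed + 1L)
    n_r <- min(cfg$n_render, nrow(cohort$truth))
    dices <- vapply(seq_len(n_r), function(i) {
      ph <- generate_phantom(phantom_spec_for(cohort$truth[i, ]),
                             seed = seed + i)
      m2 <- perturb_mask(ph$masks$sn_mask, cfg$rater_shift_prob,
                         seed = seed + 100L + i)
      dice(ph$masks$sn_mask, m2)
    }, numeric(1))
    meas2 <- measure_cohort(cohort, seed = seed + 2L)  # second rater
    ord <- order(meas$subject_id, meas$visit)
    ord2 <- order(meas2$subject_id, meas2$visit)
    rel <- data.frame(
      metric = c("dice_mean", "icc_vol", "icc_snr"),
      value = c(mean(dices),
                icc(cbind(meas$vol_mm3[ord], meas2$vol_mm3[ord2])),
                icc(cbind(meas$snr[ord], meas2$snr[ord2]))))
    emit(rel, "reliability.csv")
  })
  run_stage("stats", function() {
    if (is.null(cohort)) cohort <<- generate_cohort(design, seed = seed)
    if (is.null(meas)) meas <<- measure_cohort(cohort, seed = seed + 1L)
    base <- meas[meas$visit == "V1", ]
    measures <- c("vol_mm3", "cvol", "snr", "cnr")
    cs <- do.call(rbind, lapply(measures, function(m)
      cbind(measure = m, cross_sectional_model(base, m))))
    emit(cs, "cross_sectional.csv")
    des <- if (design$hv_followup) "cohort1" else "cohort2"
    long_tab <- if (des == "cohort2") meas[meas$group == "PD", ] else meas
    lg <- do.call(rbind, lapply(measures, function(m) {
      r <- longitudinal_model(long_tab, m, design = des)
      report$exclusions[[paste0("longitudinal_", m)]] <<-
        attr(r, "n_excluded")
      cbind(measure = m, r)
    }))
    emit(lg, "longitudinal.csv")
    rates <- do.call(rbind, lapply(measures, function(m) {
      rc <- suppressMessages(annual_rate_cohort(meas, m))
      cbind(measure = m, rc)
    }))
    emit(rates, "annual_rates.csv")
    aucs <- do.call(rbind, lapply(measures, function(m) {
      r <- roc_auc(base[[m]], base$group, "PD")
      data.frame(measure = m, auc = r$auc, flipped = r$flipped)
    }))
    emit(aucs, "roc.csv")
    pd_base <- base[base$group == "PD", ]
    corr <- correlation_with_permutation(
      pd_base, measures,
      c("updrs3_off", "disease_duration_yr", "age", "ledd_mg"),
      n_perm = cfg$n_perm, seed = seed + 3L)
    emit(corr, "correlations.csv")
  })
  run_stage("power", function() {
    if (is.null(cohort)) cohort <<- generate_cohort(design, seed = seed)
    if (is.null(meas)) meas <<- measure_cohort(cohort, seed = seed + 1L)
    changes <- calibrate_power_inputs(meas)
    pt <- power_table(changes, cfg$effects, cfg$powers, cfg$alpha)
    emit(pt, "power.csv")
  })

  report$outputs <- lapply(outputs, function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
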