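#' Query for a disease-modification trial sample-size estimate
#'
#' Frames a two-arm, 1-year parallel trial whose endpoint is the annualized
#' change of one SN measurement. The detectable treatment effect is a
#' fraction of the predicted disease-specific change: by default the PD
#' minus HV difference in mean annual rates (`delta_ref = "difference"`), or
#' the PD rate alone (`delta_ref = "pd_only"`).
#'
#' @param measure label (`"vol"`, `"cvol"`, `"snr"`, `"cnr"`, or any).
#' @param effect_fraction fraction of the predicted change the drug removes,
#'   in (0, 1].
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @param decline_pd,decline_hv mean annualized change, percent per year.
#' @param sd_change SD of the 1-year change, percent (> 0).
#' @param delta_ref `"difference"` or `"pd_only"`.
#' @return An object of class `power_query`.
#' @export
power_query <- function(measure, effect_fraction, power = 0.8, alpha = 0.05,
                        decline_pd, decline_hv = 0, sd_change,
                        delta_ref = c("difference", "pd_only")) {
  delta_ref <- match.arg(delta_ref)
  if (effect_fraction <= 0 || effect_fraction > 1)
    stop("`effect_fraction` must be in (0, 1]", call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must be in (0, 1)",
                                     call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (sd_change <= 0) stop("`sd_change` must be positive", call. = FALSE)
  structure(list(measure = measure, effect_fraction = effect_fraction,
                 power = power, alpha = alpha, decline_pd = decline_pd,
                 decline_hv = decline_hv, sd_change = sd_change,
                 delta_ref = delta_ref),
            class = "power_query")
}

query_delta <- function(query) {
  base <- if (query$delta_ref == "difference")
    abs(query$decline_pd - query$decline_hv) else abs(query$decline_pd)
  query$effect_fraction * base
}

#' Analytic per-arm sample size
#'
#' Standard two-arm normal-approximation formula for a difference in mean
#' 1-year change: `n = ceil(2 sigma^2 (z_{1-alpha/2} + z_power)^2 / delta^2)`
#' with `delta = effect_fraction x` the predicted change (see
#' [power_query()]), floored at 2 per arm.
#'
#' @param query a [power_query].
#' @return `list(n_per_arm, method = "analytic", delta, inputs_echo)`.
#' @export
sample_size_analytic <- function(query) {
  stopifnot(inherits(query, "power_query"))
  delta <- query_delta(query)
  if (delta == 0)
    stop("zero detectable effect (delta = 0): sample size undefined",
         call. = FALSE)
  z <- stats::qnorm(1 - query$alpha / 2) + stats::qnorm(query$power)
  n <- ceiling(2 * query$sd_change^2 * z^2 / delta^2)
  list(n_per_arm = max(n, 2), method = "analytic", delta = delta,
       inputs_echo = query)
}

# Monte-Carlo rejection rate of the pooled t test at per-arm size n
simulated_power_at <- function(n, delta, sd, alpha, n_reps) {
  a <- matrix(stats::rnorm(n * n_reps, 0, sd), n)
  b <- matrix(stats::rnorm(n * n_reps, delta, sd), n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = n))^2)
  vb <- colSums((b - rep(mb, each = n))^2)
  sp2 <- (va + vb) / (2 * n - 2)
  tt <- (mb - ma) / sqrt(sp2 * 2 / n)
  crit <- stats::qt(1 - alpha / 2, 2 * n - 2)
  mean(abs(tt) >= crit)
}

#' Simulated per-arm sample size
#'
#' Monte-Carlo oracle for [sample_size_analytic()]: finds, by bisection, the
#' smallest per-arm n whose two-sample pooled t test rejects at the target
#' rate when 1-year changes are simulated under the query's effect and
#' variability.
#'
#' @param query a [power_query].
#' @param n_reps Monte-Carlo replicates per evaluated n (>= 500).
#' @param seed integer seed.
#' @param n_max largest n considered before erroring out.
#' @return `list(n_per_arm, method = "simulation", delta, achieved_power,
#'   inputs_echo)`.
#' @export
sample_size_simulated <- function(query, n_reps = 1000, seed = 1L,
                                  n_max = 5000L) {
  stopifnot(inherits(query, "power_query"))
  if (n_reps < 500) stop("use n_reps >= 500", call. = FALSE)
  delta <- query_delta(query)
  if (delta == 0)
    stop("zero detectable effect (delta = 0): sample size undefined",
         call. = FALSE)
  set.seed(as.integer(seed))
  pw <- function(n) simulated_power_at(n, delta, query$sd_change,
                                       query$alpha, n_reps)
  lo <- 2L
  hi <- lo
  while (pw(hi) < query$power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max)
      stop("target power not achievable below n_max = ", n_max,
           call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= query$power) hi <- mid else lo <- mid
  }
  list(n_per_arm = hi, method = "simulation", delta = delta,
       achieved_power = pw(hi), inputs_echo = query)
}

#' Calibrate power inputs from a cohort's annualized changes
#'
#' Estimates, per measurement, the mean annual rate in PD and HV and the SD
#' of the per-subject PD rates — the three numbers a [power_query] needs —
#' from a longitudinal measurement table.
#'
#' @param measurements long table as produced by [measure_cohort()].
#' @param measures measurement column names.
#' @return Data frame: `measure`, `decline_pd`, `decline_hv`, `sd_change`.
#' @export
calibrate_power_inputs <- function(measurements,
                                   measures = c("vol_mm3", "cvol", "snr",
                                                "cnr")) {
  rows <- lapply(measures, function(m) {
    rc <- suppressMessages(annual_rate_cohort(measurements, m))
    pd <- rc[rc$group == "PD", ]
    hv <- rc[rc$group == "HV", ]
    data.frame(measure = m,
               decline_pd = pd$mean_rate,
               decline_hv = if (nrow(hv)) hv$mean_rate else 0,
               sd_change = pd$sd_rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample-size table over a measures x effect x power grid
#'
#' @param changes data frame from [calibrate_power_inputs()] (or hand-built
#'   with the same columns).
#' @param effects detectable effect fractions.
#' @param powers target powers.
#' @param alpha two-sided level.
#' @param method `"analytic"` or `"simulation"`.
#' @param delta_ref passed to [power_query()].
#' @param seed,n_reps,n_max used when `method = "simulation"`.
#' @return Long data frame `measure, effect_fraction, power, n_per_arm,
#'   delta, sd_change`; render with [format_power_table()].
#' @export
power_table <- function(changes, effects = c(0.3, 0.5, 0.7),
                        powers = c(0.8, 0.9), alpha = 0.05,
                        method = c("analytic", "simulation"),
                        delta_ref = "difference", seed = 1L, n_reps = 1000,
                        n_max = 20000L) {
  method <- match.arg(method)
  stopifnot(nrow(changes) > 0)
  grid <- expand.grid(i = seq_len(nrow(changes)), effect_fraction = effects,
                      power = powers, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ch <- changes[grid$i[g], ]
    q <- power_query(ch$measure, grid$effect_fraction[g], grid$power[g],
                     alpha, ch$decline_pd, ch$decline_hv, ch$sd_change,
                     delta_ref)
    est <- if (method == "analytic") sample_size_analytic(q)
           else sample_size_simulated(q, n_reps, seed + g, n_max)
    data.frame(measure = ch$measure, effect_fraction = grid$effect_fraction[g],
               power = grid$power[g], n_per_arm = est$n_per_arm,
               delta = est$delta, sd_change = ch$sd_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a power table in the conventional wide layout
#'
#' Rows are effect-size / power combinations, columns the measurements.
#'
#' @param tab output of [power_table()].
#' @return A data frame ready for printing or CSV export.
#' @export
format_power_table <- function(tab) {
  wide <- stats::reshape(
    tab[, c("measure", "effect_fraction", "power", "n_per_arm")],
    direction = "wide", idvar = c("effect_fraction", "power"),
    timevar = "measure")
  names(wide) <- sub("^n_per_arm\\.", "", names(wide))
  wide <- wide[order(wide$effect_fraction, -wide$power), ]
  rownames(wide) <- NULL
  wide
}
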