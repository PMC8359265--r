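#' Chi-square test for a 2x2 proportion table
#'
#' Pearson chi-square on one degree of freedom, without continuity
#' correction, as used for sex-ratio comparisons between groups.
#'
#' @param counts 2x2 matrix (or table) of nonnegative counts with positive
#'   margins.
#' @return `list(chi2, df, p)`.
#' @export
chi_square_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L))
    stop("`counts` must be a 2x2 table", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: chi-square undefined", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Two-sample Student t test (pooled variance)
#'
#' @param values_a,values_b numeric samples, n >= 2 each.
#' @return `list(t, df, p)` with a two-sided p value.
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(values_a) + stats::var(values_b) == 0)
    stop("zero pooled variance: t undefined", call. = FALSE)
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Shapiro-Wilk normality gate for parametric testing
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha_gate significance level of the gate (default 0.05).
#' @return `list(W, p, parametric_ok)`; `parametric_ok` is `TRUE` when the
#'   test does not reject normality at `alpha_gate`.
#' @export
normality_gate <- function(values, alpha_gate = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant sample (zero variance): normality test undefined",
         call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = unname(sw$p.value),
       parametric_ok = sw$p.value > alpha_gate)
}

# sum-to-zero coded factor (drops unused levels first)
sum_coded <- function(x) {
  f <- factor(x)
  stats::C(f, stats::contr.sum)
}

model_result_row <- function(term, f, df1, df2, p, direction = NA_real_) {
  data.frame(term = term, f_stat = unname(f), df1 = unname(df1),
             df2 = unname(df2), p_value = unname(p),
             effect_direction = direction, stringsAsFactors = FALSE)
}

# Type-III ANOVA table of an lm fit -> tidy ModelResult rows.
# `rename` maps model terms to reported names; unmapped rows are dropped.
type3_rows <- function(fit, rename) {
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model: aliased term(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  a3 <- car::Anova(fit, type = 3)
  df2 <- a3[["Df"]][rownames(a3) == "Residuals"]
  rows <- lapply(names(rename), function(trm) {
    i <- match(trm, rownames(a3))
    if (is.na(i)) return(NULL)
    model_result_row(rename[[trm]], a3[["F value"]][i], a3[["Df"]][i], df2,
                     a3[["Pr(>F)"]][i])
  })
  do.call(rbind, rows)
}

# adjusted first-level-minus-second-level sign for a 2-level sum-coded factor
factor_direction <- function(fit, fname, positive_level) {
  cf <- stats::coef(fit)
  i <- match(paste0(fname, "1"), names(cf))
  if (is.na(i)) return(NA_real_)
  lev <- levels(fit$model[[fname]])
  d <- 2 * cf[[i]]                       # level1 - level2, adjusted
  if (lev[1] != positive_level) d <- -d  # report positive_level - other
  sign(d)
}

#' Cross-sectional factorial model for one SN measurement
#'
#' Baseline group comparison: a linear model of the measurement on group
#' (PD, HV) and sex as crossed between-subject factors plus age as a
#' (centered) covariate, reported as Type-III F tests with sum-to-zero
#' factor coding. `effect_direction` on the group row is the sign of the
#' adjusted PD - HV difference.
#'
#' @param table data frame with columns `group`, `sex`, `age` and the
#'   measurement.
#' @param measure measurement column name.
#' @param covariates covariate column names (centered before fitting);
#'   `NULL` for none.
#' @return Data frame of `ModelResult` rows (term, f_stat, df1, df2,
#'   p_value, effect_direction).
#' @export
cross_sectional_model <- function(table, measure, covariates = "age") {
  need <- c("group", "sex", covariates, measure)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- data.frame(y = table[[measure]],
                  group = sum_coded(table$group), sex = sum_coded(table$sex))
  if (nlevels(d$group) < 2 || nlevels(d$sex) < 2)
    stop("group and sex must each have >= 2 levels", call. = FALSE)
  rhs <- "group * sex"
  for (cv in covariates) {
    d[[paste0(cv, "_c")]] <- table[[cv]] - mean(table[[cv]])
    rhs <- paste(rhs, "+", paste0(cv, "_c"))
  }
  fit <- stats::lm(stats::reformulate(rhs, "y"), data = d)
  rename <- c(group = "group", sex = "sex", `group:sex` = "group:sex")
  if (!is.null(covariates))
    rename <- c(rename, stats::setNames(covariates, paste0(covariates, "_c")))
  res <- type3_rows(fit, rename)
  res$effect_direction[res$term == "group"] <-
    factor_direction(fit, "group", "PD")
  res
}

#' Mixed-design longitudinal ANOVA for one SN measurement
#'
#' Two-visit mixed factorial: visit (V1, V2) is the within-subject factor;
#' in the `"cohort1"` design group (PD, HV) and sex are between-subject
#' factors with age as covariate, in the `"cohort2"` design (PD-only
#' follow-up) sex is the only between factor. With two visits the mixed
#' ANOVA decomposes exactly into two strata: between-subject terms are
#' tested on the subject means across visits (against the between-subject
#' error), visit and its interactions on the V2 - V1 differences (against
#' the subject-by-visit error). Both strata use Type-III sums of squares
#' with sum-to-zero coding; the visit main effect is the intercept test of
#' the difference stratum.
#'
#' Subjects lacking either visit are excluded (count attached as attribute
#' `n_excluded`).
#'
#' @param table long data frame: `subject_id`, `visit` (V1/V2), `group`,
#'   `sex`, covariates, and the measurement column.
#' @param measure measurement column name.
#' @param design `"cohort1"` (visit x group x sex + age) or `"cohort2"`
#'   (visit x sex + age).
#' @param covariates baseline covariates (centered); `NULL` for none.
#' @return Data frame of `ModelResult` rows with a `stratum` column
#'   (`between` or `within`); visit terms are named `visit`, `visit:group`,
#'   etc.
#' @export
longitudinal_model <- function(table, measure,
                               design = c("cohort1", "cohort2"),
                               covariates = "age") {
  design <- match.arg(design)
  v1 <- table[table$visit == "V1", ]
  v2 <- table[table$visit == "V2", ]
  common <- intersect(v1$subject_id, v2$subject_id)
  n_excluded <- length(unique(table$subject_id)) - length(common)
  v1 <- v1[match(common, v1$subject_id), ]
  v2 <- v2[match(common, v2$subject_id), ]
  d <- data.frame(m = (v1[[measure]] + v2[[measure]]) / 2,
                  dv = v2[[measure]] - v1[[measure]],
                  sex = sum_coded(v1$sex))
  between_f <- if (design == "cohort1") {
    d$group <- sum_coded(v1$group)
    cells <- table(d$group, d$sex)
    "group * sex"
  } else {
    cells <- table(d$sex)
    "sex"
  }
  if (any(cells < 2))
    stop("fewer than 2 complete subjects in some design cell", call. = FALSE)
  rhs <- between_f
  for (cv in covariates) {
    d[[paste0(cv, "_c")]] <- v1[[cv]] - mean(v1[[cv]])
    rhs <- paste(rhs, "+", paste0(cv, "_c"))
  }
  fit_b <- stats::lm(stats::reformulate(rhs, "m"), data = d)
  fit_w <- stats::lm(stats::reformulate(rhs, "dv"), data = d)

  ren_b <- c(sex = "sex")
  if (design == "cohort1")
    ren_b <- c(group = "group", ren_b, `group:sex` = "group:sex")
  if (!is.null(covariates))
    ren_b <- c(ren_b, stats::setNames(covariates, paste0(covariates, "_c")))
  ren_w <- stats::setNames(
    ifelse(names(ren_b) == "(Intercept)", "visit",
           paste0("visit:", unname(ren_b))), names(ren_b))
  ren_w <- c(`(Intercept)` = "visit", ren_w)

  res_b <- type3_rows(fit_b, as.list(ren_b))
  res_w <- type3_rows(fit_w, as.list(ren_w))
  if (design == "cohort1") {
    res_b$effect_direction[res_b$term == "group"] <-
      factor_direction(fit_b, "group", "PD")
    res_w$effect_direction[res_w$term == "visit:group"] <-
      factor_direction(fit_w, "group", "PD")
  }
  res_w$effect_direction[res_w$term == "visit"] <-
    sign(stats::coef(fit_w)[["(Intercept)"]])
  res_b$stratum <- "between"
  res_w$stratum <- "within"
  out <- rbind(res_b, res_w)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' One-way scanner-effect ANOVA on baseline healthy volunteers
#'
#' @param table_hv_baseline baseline HV rows with a `scanner` column.
#' @param measure measurement column name.
#' @return A one-row `ModelResult` data frame for the scanner term.
#' @export
scanner_effect <- function(table_hv_baseline, measure) {
  sc <- factor(table_hv_baseline$scanner)
  if (nlevels(sc) < 2)
    stop("scanner effect needs >= 2 scanners", call. = FALSE)
  fit <- stats::lm(table_hv_baseline[[measure]] ~ sc)
  a <- stats::anova(fit)
  model_result_row("scanner", a[["F value"]][1], a[["Df"]][1], a[["Df"]][2],
                   a[["Pr(>F)"]][1])
}

#' Empirical ROC area under the curve
#'
#' Mann-Whitney AUC with ties counted one-half. Because the diseased group
#' has *lower* SN measurements, the raw AUC of an unoriented score can fall
#' below 0.5; with `direction = "auto"` the score sign is flipped so the
#' reported AUC is >= 0.5, and the flip is disclosed in the output.
#'
#' @param scores numeric scores.
#' @param labels class labels.
#' @param positive_group label of the positive (diseased) class.
#' @param direction `"auto"` (flip to >= 0.5 if needed), `"higher"` (higher
#'   score = positive) or `"lower"`.
#' @return `list(auc, flipped, n_pos, n_neg)`.
#' @export
roc_auc <- function(scores, labels, positive_group,
                    direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  pos <- labels == positive_group
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)   # midranks: ties contribute 1/2
  auc_higher <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  auc <- switch(direction, higher = auc_higher, lower = 1 - auc_higher,
                auto = max(auc_higher, 1 - auc_higher))
  flipped <- direction == "lower" ||
    (direction == "auto" && auc_higher < 0.5)
  list(auc = auc, flipped = flipped, n_pos = n_pos, n_neg = n_neg)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Pearson correlations with max-statistic permutation correction
#'
#' Computes the Pearson correlation of each SN measurement with each
#' clinical variable, and corrects each family of tests (the measurement
#' columns against one clinical variable) for multiplicity by an approximate
#' multivariate permutation test: clinical values are permuted jointly
#' across the measurement family, the maximum |r| over the family is
#' recorded per permutation, and the corrected p value is the (add-one)
#' proportion of permutations whose max |r| reaches the observed |r|. The
#' raw p value uses the same permutations pairwise, so corrected >= raw by
#' construction.
#'
#' @param table data frame holding both measurement and clinical columns.
#' @param measures measurement column names (the family).
#' @param clinical_vars clinical column names; each is corrected within its
#'   own family.
#' @param n_perm number of random permutations (>= 1000 unless exhaustive).
#' @param seed integer seed.
#' @param exhaustive if `TRUE` (complete cases n <= 8), enumerate all n!
#'   permutations and report exact proportions instead of add-one estimates.
#' @return Data frame: `measure`, `clinical_var`, `r`, `p_raw`,
#'   `p_corrected`, `n`. Constant columns are skipped with a warning.
#' @export
correlation_with_permutation <- function(table, measures, clinical_vars,
                                         n_perm = 5000, seed = 1L,
                                         exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1000)
    stop("use n_perm >= 1000 (or exhaustive = TRUE)", call. = FALSE)
  set.seed(as.integer(seed))
  out <- list()
  for (cv in clinical_vars) {
    cc <- stats::complete.cases(table[, c(measures, cv)])
    y <- table[[cv]][cc]
    n <- length(y)
    if (n < 3 || stats::sd(y) == 0) {
      warning("clinical variable `", cv, "` constant or too short: skipped",
              call. = FALSE)
      next
    }
    fam <- measures[vapply(measures,
                           function(m) stats::sd(table[[m]][cc]) > 0,
                           logical(1))]
    if (length(fam) < length(measures))
      warning("constant measurement column(s) skipped: ",
              paste(setdiff(measures, fam), collapse = ", "), call. = FALSE)
    if (!length(fam)) next
    X <- scale(as.matrix(table[cc, fam, drop = FALSE]))
    ys <- as.numeric(scale(y))
    r_obs <- as.numeric(crossprod(X, ys)) / (n - 1)

    perm_idx <- if (exhaustive) {
      if (n > 8) stop("exhaustive enumeration limited to n <= 8",
                      call. = FALSE)
      all_permutations(n)
    } else {
      t(replicate(n_perm, sample.int(n)))
    }
    r_perm <- abs(t(apply(perm_idx, 1, function(ix)
      as.numeric(crossprod(X, ys[ix])) / (n - 1))))
    if (length(fam) == 1L) r_perm <- matrix(r_perm, ncol = 1L)
    max_stat <- apply(r_perm, 1, max)
    n_p <- nrow(perm_idx)
    for (j in seq_along(fam)) {
      if (exhaustive) {
        p_raw <- mean(r_perm[, j] >= abs(r_obs[j]))
        p_cor <- mean(max_stat >= abs(r_obs[j]))
      } else {
        p_raw <- (1 + sum(r_perm[, j] >= abs(r_obs[j]))) / (1 + n_p)
        p_cor <- (1 + sum(max_stat >= abs(r_obs[j]))) / (1 + n_p)
      }
      out[[length(out) + 1L]] <- data.frame(
        measure = fam[j], clinical_var = cv, r = r_obs[j],
        p_raw = p_raw, p_corrected = p_cor, n = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
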