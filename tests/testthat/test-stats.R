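test_that("2x2 chi-square matches the cell-by-cell formula, no continuity correction", {
  r <- chi_square_proportions(matrix(c(66, 17, 33, 24), 2))
  expect_equal(round(r$chi2, 3), 7.630)
  expect_equal(r$df, 1)
  # proportional rows: exactly zero
  expect_equal(chi_square_proportions(matrix(c(20, 10, 40, 20), 2))$chi2, 0)
  # oracle: sum (O - E)^2 / E
  set.seed(3)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_proportions(tab)$chi2, sum((tab - E)^2 / E))
  }
  expect_error(chi_square_proportions(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("pooled t test matches the hand formula and is antisymmetric", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$t, 3), -3.674)   # (2-5)/sqrt(1 * (1/3 + 1/3))
  r_sw <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r_sw$t, -r$t)
  expect_equal(r_sw$p, r$p)
  expect_error(two_sample_t(c(2, 2), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("normality gate passes Gaussian samples and fails bimodal ones", {
  expect_error(normality_gate(rep(4, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
  set.seed(11)
  frac_ok <- mean(sapply(1:100, function(i)
    normality_gate(rnorm(500))$parametric_ok))
  expect_gte(frac_ok, 0.9)
  set.seed(12)
  bimodal <- c(rnorm(100, -5), rnorm(100, 5))
  g <- normality_gate(bimodal)
  expect_lt(g$p, 0.05)
  expect_false(g$parametric_ok)
})

test_that("cross-sectional model is location invariant and flags the programmed deficit", {
  set.seed(21)
  n <- 100
  tab <- data.frame(group = rep(c("HV", "PD"), each = n / 2),
                    sex = sample(c("M", "F"), n, TRUE),
                    age = rnorm(n, 60, 8))
  tab$y <- rnorm(n) - (tab$group == "PD")   # 1-sd deficit
  res <- cross_sectional_model(tab, "y")
  expect_setequal(res$term, c("group", "sex", "group:sex", "age"))
  tab2 <- tab; tab2$y <- tab$y + 100
  res2 <- cross_sectional_model(tab2, "y")
  expect_equal(res2$f_stat, res$f_stat)
  expect_equal(res$effect_direction[res$term == "group"], -1)

  # 1-sd group deficit at n = 100 is detected essentially always
  hits <- sapply(1:20, function(i) {
    tab$y <- rnorm(n) - (tab$group == "PD")
    cross_sectional_model(tab, "y")$p_value[1] < 0.001
  })
  expect_gte(mean(hits), 0.9)

  # rank deficiency is reported, not silently dropped
  tab3 <- tab; tab3$sex <- ifelse(tab3$group == "PD", "M", "F")
  expect_error(cross_sectional_model(tab3, "y"), "aliased")
})

test_that("mixed-design ANOVA equals the classical within/between decomposition on a balanced toy", {
  # 2 (group) x 2 (sex) x 2 (visit), 4 subjects per between-cell, integers
  set.seed(9)
  cells <- expand.grid(group = c("HV", "PD"), sex = c("M", "F"))
  subj <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(subject_id = paste0(cells$group[i], cells$sex[i], 1:4),
               group = cells$group[i], sex = cells$sex[i])))
  y1 <- sample(50:80, 16, TRUE)
  y2 <- y1 + sample(-8:2, 16, TRUE) - 4 * (subj$group == "PD")
  long <- rbind(cbind(subj, visit = "V1", y = y1),
                cbind(subj, visit = "V2", y = y2))
  res <- longitudinal_model(long, "y", design = "cohort1", covariates = NULL)

  oracle <- summary(aov(y ~ group * sex * visit + Error(subject_id),
                        data = long))
  ob <- oracle[["Error: subject_id"]][[1]]
  ow <- oracle[["Error: Within"]][[1]]
  get_f <- function(stratum, term) stratum[trimws(rownames(stratum)) == term,
                                           "F value"]
  expect_equal(res$f_stat[res$term == "group"], get_f(ob, "group"))
  expect_equal(res$f_stat[res$term == "sex"], get_f(ob, "sex"))
  expect_equal(res$f_stat[res$term == "group:sex"], get_f(ob, "group:sex"))
  expect_equal(res$f_stat[res$term == "visit"], get_f(ow, "visit"))
  expect_equal(res$f_stat[res$term == "visit:group"],
               get_f(ow, "group:visit"))
  expect_equal(res$f_stat[res$term == "visit:sex"], get_f(ow, "sex:visit"))
  expect_equal(res$f_stat[res$term == "visit:group:sex"],
               get_f(ow, "group:sex:visit"))
  expect_equal(unique(res$df2), 12)   # 16 subjects - 4 between-cell means
})

test_that("flat longitudinal data yield a null visit effect; incomplete subjects are excluded", {
  set.seed(30)
  n <- 40
  subj <- data.frame(subject_id = paste0("s", 1:n),
                     group = rep(c("HV", "PD"), each = n / 2),
                     sex = rep(c("M", "F"), n / 2), age = rnorm(n, 60, 8))
  base <- rnorm(n, 100, 10)
  long <- rbind(cbind(subj, visit = "V1", y = base + rnorm(n, 0, 1)),
                cbind(subj, visit = "V2", y = base + rnorm(n, 0, 1)))
  res <- longitudinal_model(long, "y", "cohort1")
  expect_gt(res$p_value[res$term == "visit"], 0.05)
  # drop V2 of three subjects
  long2 <- long[!(long$visit == "V2" & long$subject_id %in%
                    c("s1", "s2", "s3")), ]
  res2 <- longitudinal_model(long2, "y", "cohort1")
  expect_equal(attr(res2, "n_excluded"), 3L)
  expect_error(longitudinal_model(long[long$subject_id %in%
                                         c("s1", "s2", "s21"), ], "y",
                                  "cohort1"),
               "fewer than 2")
})

test_that("scanner one-way ANOVA reduces to the squared t test on two groups", {
  set.seed(14)
  tab <- data.frame(scanner = rep(c("PRISMA", "TRIO"), c(41, 23)),
                    vol = c(rnorm(41, 273, 48), rnorm(23, 248, 37)))
  r <- scanner_effect(tab, "vol")
  tt <- two_sample_t(tab$vol[tab$scanner == "PRISMA"],
                     tab$vol[tab$scanner == "TRIO"])
  expect_equal(r$f_stat, tt$t^2)
  expect_equal(r$p_value, tt$p)
  expect_error(scanner_effect(data.frame(scanner = "A", vol = 1:5), "vol"),
               ">= 2 scanners")

  # a programmed offset on Table-2-scale noise is usually detected
  hits <- sapply(1:100, function(i) {
    tab$vol <- c(rnorm(41, 273.2, 48.4), rnorm(23, 273.2 * (1 - 0.094), 37))
    scanner_effect(tab, "vol")$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("ROC AUC equals exhaustive pair enumeration and flips disclosed", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("HV", "PD"), each = 3),
                     "PD", direction = "higher")
  expect_equal(perfect$auc, 1)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(1:8, n, TRUE)          # heavy ties on purpose
    labels <- sample(c("HV", "PD"), n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels, "PD", direction = "higher")$auc,
                 oracle_auc_pairs(scores, labels, "PD"))
  }
  # lower scores in the diseased group: auto-flip reports AUC > 0.5
  r <- roc_auc(c(10, 11, 12, 1, 2, 3), rep(c("HV", "PD"), each = 3), "PD")
  expect_equal(r$auc, 1)
  expect_true(r$flipped)
  expect_error(roc_auc(1:4, rep("PD", 4), "PD"), "both classes")
  # independent reference implementation on one instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(9)
    sc <- rnorm(40); lb <- sample(c("HV", "PD"), 40, TRUE)
    expect_equal(roc_auc(sc, lb, "PD", direction = "higher")$auc,
                 as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("HV", "PD"),
                                                direction = "<", quiet = TRUE))))
  }
})

test_that("max-statistic permutation correction dominates raw p and matches exhaustive enumeration", {
  set.seed(44)
  tab <- data.frame(a = rnorm(20))
  tab$b <- tab$a                     # perfect correlation
  tab$c <- rnorm(20)
  res <- correlation_with_permutation(tab, c("a", "c"), "b", n_perm = 2000,
                                      seed = 1)
  ra <- res[res$measure == "a", ]
  expect_equal(ra$r, 1)
  expect_lte(ra$p_corrected, 2 / 2001)

  expect_true(all(res$p_corrected >= res$p_raw))

  # exhaustive n = 6 against an independent full-enumeration oracle
  set.seed(45)
  toy <- data.frame(m1 = rnorm(6), m2 = rnorm(6), clin = rnorm(6))
  res6 <- correlation_with_permutation(toy, c("m1", "m2"), "clin",
                                       exhaustive = TRUE)
  perms <- oracle_perms(6)
  r_obs <- c(cor(toy$m1, toy$clin), cor(toy$m2, toy$clin))
  maxs <- sapply(perms, function(p)
    max(abs(cor(toy$m1, toy$clin[p])), abs(cor(toy$m2, toy$clin[p]))))
  for (j in 1:2) {
    expect_equal(res6$p_corrected[j], mean(maxs >= abs(r_obs[j])))
  }
  # constant columns are skipped with a warning
  toy$flat <- 1
  expect_warning(correlation_with_permutation(toy, c("m1", "flat"), "clin",
                                              exhaustive = TRUE),
                 "constant")
})
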