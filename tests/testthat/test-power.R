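test_that("analytic sample size follows the two-arm z formula", {
  # delta = sigma, alpha = .05, power = .80: (1.95996 + 0.84162)^2 = 7.849
  q <- power_query("vol", 1, power = 0.8, alpha = 0.05,
                   decline_pd = -5, decline_hv = 0, sd_change = 5)
  expect_equal(sample_size_analytic(q)$n_per_arm, ceiling(2 * 7.849))
  expect_equal(sample_size_analytic(q)$n_per_arm, 16)

  # halving delta quadruples n (up to ceiling)
  q_half <- power_query("vol", 0.5, power = 0.8, decline_pd = -5,
                        decline_hv = 0, sd_change = 5)
  n1 <- sample_size_analytic(q)$n_per_arm
  n4 <- sample_size_analytic(q_half)$n_per_arm
  expect_gte(n4, 4 * n1 - 4)
  expect_lte(n4, 4 * n1)

  q90 <- power_query("vol", 1, power = 0.9, decline_pd = -5,
                     decline_hv = 0, sd_change = 5)
  expect_gt(sample_size_analytic(q90)$n_per_arm, n1)

  # delta referencing options
  q_pd <- power_query("vol", 0.5, decline_pd = -6, decline_hv = -1,
                      sd_change = 4, delta_ref = "pd_only")
  expect_equal(sample_size_analytic(q_pd)$delta, 3)
  q_diff <- power_query("vol", 0.5, decline_pd = -6, decline_hv = -1,
                        sd_change = 4)
  expect_equal(sample_size_analytic(q_diff)$delta, 2.5)

  expect_error(sample_size_analytic(
    power_query("vol", 0.3, decline_pd = 2, decline_hv = 2, sd_change = 1)),
    "delta = 0")
  expect_error(power_query("vol", 0, decline_pd = -5, sd_change = 1),
               "effect_fraction")
})

test_that("simulated sample size agrees with the analytic formula and is calibrated", {
  # overwhelming effect: floor behaviour
  q_huge <- power_query("vol", 1, decline_pd = -50, decline_hv = 0,
                        sd_change = 1)
  expect_lte(sample_size_simulated(q_huge, n_reps = 500, seed = 1)$n_per_arm, 3)

  qs <- list(
    power_query("vol", 0.5, power = 0.8, decline_pd = -6.2, decline_hv = 0,
                sd_change = 3.3),
    power_query("snr", 0.5, power = 0.9, decline_pd = 1.5, decline_hv = 0.8,
                sd_change = 4),
    power_query("cnr", 0.7, power = 0.8, decline_pd = -4, decline_hv = 0,
                sd_change = 6))
  for (i in seq_along(qs)) {
    na <- sample_size_analytic(qs[[i]])$n_per_arm
    ns <- sample_size_simulated(qs[[i]], n_reps = 1500, seed = 10 + i)$n_per_arm
    expect_lte(abs(ns - na) / na, 0.15)
  }

  # rejection rate at the returned n, fresh seed, reaches the target power
  q <- qs[[1]]
  n <- sample_size_simulated(q, n_reps = 1500, seed = 2)$n_per_arm
  delta <- q$effect_fraction * abs(q$decline_pd - q$decline_hv)
  set.seed(99)
  rej <- mean(replicate(1500, {
    t.test(rnorm(n, 0, q$sd_change), rnorm(n, delta, q$sd_change),
           var.equal = TRUE)$p.value < q$alpha
  }))
  expect_gte(rej, q$power - 3 * sqrt(q$power * (1 - q$power) / 1500))

  expect_error(sample_size_simulated(q, n_reps = 100), "n_reps")
  q_hopeless <- power_query("vol", 0.1, decline_pd = -0.5, decline_hv = 0,
                            sd_change = 50)
  expect_error(sample_size_simulated(q_hopeless, n_reps = 500, seed = 1,
                                     n_max = 100), "n_max")
})

test_that("power table covers the grid and shrinks with larger effects", {
  changes <- data.frame(measure = c("vol", "cvol", "snr", "cnr"),
                        decline_pd = c(-5.8, -5.6, 1.5, 1.9),
                        decline_hv = c(0.4, 0.3, 0.8, 3.9),
                        sd_change = c(3.3, 3.3, 4.2, 8.1))
  tab <- power_table(changes)
  expect_equal(nrow(tab), 24)
  for (m in changes$measure) for (pw in c(0.8, 0.9)) {
    sl <- tab[tab$measure == m & tab$power == pw, ]
    sl <- sl[order(sl$effect_fraction), ]
    expect_true(all(diff(sl$n_per_arm) < 0))
  }
  wide <- format_power_table(tab)
  expect_equal(nrow(wide), 6)
  expect_true(all(c("vol", "cvol", "snr", "cnr") %in% names(wide)))
})
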