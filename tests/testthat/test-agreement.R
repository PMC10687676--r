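test_that("Bland-Altman matches closed forms", {
  # identical methods: bias 0, LoA (0, 0)
  x <- c(10, 200, 3000)
  ba <- bland_altman(a = x, b = x)
  expect_equal(ba$mean_bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)

  # diffs (-1, +1): bias 0, sd sqrt(2), LoA +/- 1.96*sqrt(2)
  ba2 <- bland_altman(a = c(99, 101), b = c(100, 100))
  expect_equal(ba2$mean_bias, 0)
  expect_equal(ba2$sd_diff, sqrt(2))
  expect_equal(ba2$loa_high, 1.96 * sqrt(2))
  expect_equal(ba2$loa_low, -1.96 * sqrt(2))

  # constant difference: zero variance, LoA collapse to the bias
  ba3 <- bland_altman(a = c(12, 22, 32), b = c(10, 20, 30))
  expect_equal(ba3$mean_bias, 2)
  expect_equal(ba3$loa_low, 2)
  expect_equal(ba3$loa_high, 2)

  expect_error(bland_altman(a = 1, b = 2),
               class = "stepwave_insufficient_data")
})

test_that("Bland-Altman agrees with a direct-formula oracle on random data", {
  for (k in 1:50) {
    withr::local_seed(1000 + k)
    n <- sample(3:40, 1)
    a <- runif(n, 0, 2000)
    b <- a + rnorm(n, sd = runif(1, 1, 200))
    ba <- bland_altman(a = a, b = b)
    or <- ba_oracle(a, b)
    expect_equal(ba$mean_bias, or$bias, tolerance = 1e-10)
    expect_equal(ba$loa_low, or$loa_low, tolerance = 1e-10)
    expect_equal(ba$loa_high, or$loa_high, tolerance = 1e-10)
  }
})

test_that("Bland-Altman is antisymmetric and shift invariant", {
  withr::local_seed(7)
  a <- runif(30, 100, 2000)
  b <- a + rnorm(30, 5, 50)
  f <- bland_altman(a = a, b = b)
  r <- bland_altman(a = b, b = a)
  expect_equal(f$mean_bias, -r$mean_bias)
  expect_equal(f$loa_low, -r$loa_high)
  expect_equal(f$loa_high, -r$loa_low)

  s <- bland_altman(a = a + 500, b = b + 500)
  expect_equal(s$mean_bias, f$mean_bias)
  expect_equal(s$loa_low, f$loa_low)
  expect_equal(s$loa_high, f$loa_high)
  # the relative bias denominator does shift
  expect_lt(abs(s$relative_bias), abs(f$relative_bias))
})

test_that("tidy and glance summarise a Bland-Altman result", {
  ba <- bland_altman(a = c(10, 20, 30), b = c(12, 19, 33))
  td <- tidy(ba)
  expect_setequal(td$term, c("mean_bias", "loa_low", "loa_high", "sd_diff",
                             "relative_bias"))
  gl <- glance(ba)
  expect_equal(gl$n, 3)
  expect_equal(gl$mean_bias, ba$mean_bias)
})

test_that("location pairing enumerates unordered pairs in canonical order", {
  counts <- tibble::tibble(
    bout = 1, location = c("arm", "thigh", "waist"), steps = c(3, 1, 2)
  )
  p <- pair_locations(counts)
  expect_equal(nrow(p), 3)
  expect_equal(p$location_a, c("thigh", "thigh", "waist"))
  expect_equal(p$location_b, c("waist", "arm", "arm"))
  expect_equal(p$steps_a, c(1, 1, 2))

  four <- tibble::tibble(bout = 1,
                         location = c("thigh", "waist", "chest", "arm"),
                         steps = 1:4)
  expect_equal(nrow(pair_locations(four)), 6)
  one <- tibble::tibble(bout = 1, location = "waist", steps = 5)
  expect_equal(nrow(pair_locations(one)), 0)
})

test_that("linear fairness model recovers exact and noisy coefficients", {
  withr::local_seed(21)
  df <- tibble::tibble(age = runif(200, 25, 80), bmi = runif(200, 18, 40))

  exact <- dplyr::mutate(df, d = 5 + 0 * age + 0 * bmi)
  fit <- fit_fairness_linear(exact, d, age, bmi)
  td <- tidy(fit)
  expect_equal(td$estimate, c(5, 0, 0), tolerance = 1e-8)
  expect_equal(td$conf_low, td$estimate, tolerance = 1e-6)

  noisy <- dplyr::mutate(df, d = 5 + 2 * age + rnorm(200))
  fit2 <- fit_fairness_linear(noisy, d, age, bmi)
  td2 <- tidy(fit2)
  age_row <- td2[td2$term == "age", ]
  bmi_row <- td2[td2$term == "bmi", ]
  expect_true(age_row$conf_low <= 2 && 2 <= age_row$conf_high)
  expect_true(bmi_row$conf_low <= 0 && 0 <= bmi_row$conf_high)

  zero <- dplyr::mutate(df, d = 0)
  expect_equal(tidy(fit_fairness_linear(zero, d, age, bmi))$estimate,
               c(0, 0, 0))
})

test_that("mixed fairness model recovers the random-intercept SD and is calibrated", {
  # 20 replicates: n = 100 participants x 2 observations, b_i ~ N(0, 50^2),
  # residual sd 10, all fixed effects 0. Count, per coefficient, how many
  # replicate 95% CIs cover the truth.
  covered <- c(`(Intercept)` = 0, age = 0, bmi = 0)
  first_fit <- NULL
  for (k in 1:20) {
    withr::local_seed(5000 + k)
    n <- 100
    people <- tibble::tibble(
      id = seq_len(n), age = runif(n, 25, 80), bmi = runif(n, 18, 40),
      b = rnorm(n, 0, 50)
    )
    obs <- dplyr::bind_rows(people, people)
    obs$d <- obs$b + rnorm(nrow(obs), 0, 10)
    fit <- fit_fairness_mixed(obs, d, age, bmi, id)
    if (k == 1) first_fit <- fit
    td <- tidy(fit)
    covered <- covered + (td$conf_low <= 0 & 0 <= td$conf_high)
  }
  expect_true(all(covered >= 17))
  expect_gte(first_fit$random_intercept_sd, 35)
  expect_lte(first_fit$random_intercept_sd, 65)
  expect_false(first_fit$singular)
  expect_equal(glance(first_fit)$model_kind, "mixed_random_intercept")
})

test_that("degenerate mixed fits collapse toward pooled OLS", {
  withr::local_seed(9)
  n <- 80
  df <- tibble::tibble(
    id = seq_len(n), age = runif(n, 25, 80), bmi = runif(n, 18, 40)
  )
  df$d <- 3 + 0.5 * df$age + rnorm(n, 0, 5)  # one observation each
  mixed <- fit_fairness_mixed(df, d, age, bmi, id)
  ols <- fit_fairness_linear(df, d, age, bmi)
  expect_true(mixed$singular || mixed$random_intercept_sd < 5)
  expect_equal(tidy(mixed)$estimate, tidy(ols)$estimate, tolerance = 0.05)

  # zero between-participant variance with repeats: SD near 0, flagged
  rep2 <- dplyr::bind_rows(df, df)
  rep2$d <- 1 + 0 * rep2$age
  rep2$d <- rep2$d + rnorm(nrow(rep2), 0, 1)
  fit0 <- fit_fairness_mixed(rep2, d, age, bmi, id)
  expect_lt(fit0$random_intercept_sd, 1)
})
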