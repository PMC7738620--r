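test_that("OLS recovers exact coefficients on noise-free data", {
  d <- data.frame(x = seq_len(20))
  d$y <- 3 + 2 * d$x
  fit <- fit_ols(y ~ x, d)
  expect_equal(unname(coef(fit)), c(3, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # identity regression: slope 1, intercept 0
  set.seed(1)
  z <- rnorm(30)
  idf <- data.frame(z = z, y = z)
  fit_id <- fit_ols(y ~ z, idf)
  expect_equal(unname(coef(fit_id)), c(0, 1), tolerance = 1e-10)
})

test_that("OLS standard errors and p-values match summary.lm", {
  set.seed(2)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + rnorm(40)
  ours <- fit_ols(y ~ x1 + x2, d)
  ref <- summary(lm(y ~ x1 + x2, d))
  expect_equal(unname(ours$coefficients), unname(ref$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(ours$standard_errors),
               unname(ref$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(unname(ours$p_values), unname(ref$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(ours$r2, ref$r.squared, tolerance = 1e-12)
  expect_equal(ours$adj_r2, ref$adj.r.squared, tolerance = 1e-12)
})

test_that("a pure-noise predictor gets a near-zero coefficient", {
  set.seed(3)
  n <- 10000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 + rnorm(n)
  fit <- fit_ols(y ~ x1 + x2, d)
  expect_lt(abs(coef(fit)[["x2"]]),
            3 * fit$standard_errors[["x2"]])
})

test_that("OLS error contracts: rank deficiency and tiny n", {
  d <- data.frame(a = 1:10, b = 2 * (1:10))
  d$y <- rnorm(10)
  expect_error(fit_ols(y ~ a + b, d), "collinear.*b")
  expect_error(fit_ols(rnorm(3), data.frame(a = 1:3, b = c(2, 1, 7))),
               "cannot identify")
})

test_that("the Gaussian AIC convention matches its closed form and stats::AIC", {
  # rss/n = 1, n = 100, two mean parameters -> 100 log(2 pi) + 106
  expect_equal(aic_gaussian(100, 100, 2), 100 * log(2 * pi) + 106,
               tolerance = 1e-12)
  # halving rss at fixed n and p lowers AIC by n log 2
  expect_equal(aic_gaussian(50, 100, 2) - aic_gaussian(100, 100, 2),
               -100 * log(2), tolerance = 1e-12)
  # equal rss: the model with fewer mean parameters wins
  expect_lt(aic_gaussian(80, 100, 3), aic_gaussian(80, 100, 5))
  expect_error(aic_gaussian(0, 100, 2), "rss")

  # same convention as stats::AIC on an lm fit
  set.seed(4)
  d <- data.frame(x = rnorm(30))
  d$y <- 2 + d$x + rnorm(30)
  m <- lm(y ~ x, d)
  expect_equal(aic_gaussian(sum(resid(m)^2), 30, 2), AIC(m),
               tolerance = 1e-10)
  ours <- fit_ols(y ~ x, d)
  expect_equal(ours$aic, AIC(m), tolerance = 1e-10)
})

test_that("subset enumeration covers every candidate combination", {
  set.seed(5)
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  d$y <- d$a + rnorm(50)
  s2 <- best_subset_search(y ~ a + b, d)
  expect_equal(nrow(s2$table), 4)
  expect_setequal(s2$table$predictors,
                  c("(intercept only)", "a", "b", "a+b"))

  d8 <- simulate_regression_cohort(n = 300, seed = 6)
  s8 <- best_subset_search(
    delta_rr_mean ~ vo2max + training_load + hr_max + rpe +
      perceived_fatigue + doms + sleep_quality + stress, d8)
  expect_equal(nrow(s8$table), 256)
  expect_equal(anyDuplicated(s8$table$predictors), 0)
  # ranked ascending by AIC
  expect_true(!is.unsorted(s8$table$aic))
  expect_s3_class(s8$best, "ortho_lm")
})

test_that("AIC ranking is invariant to additive shifts and ties break small", {
  d <- simulate_regression_cohort(n = 120, seed = 7)
  s <- best_subset_search(delta_rr_mean ~ vo2max + rpe +
                            perceived_fatigue, d)
  ord1 <- s$table$predictors
  # shifting every AIC by a constant cannot change the ordering
  shifted <- order(s$table$aic + 1234, s$table$k, s$table$predictors)
  expect_equal(ord1[order(s$table$rank)][shifted], ord1[shifted])
  # nesting: rss never increases in a superset fitted on the same rows
  rss_of <- function(pred) s$fits[[which(s$table$predictors == pred)]]$rss
  expect_lte(rss_of("vo2max+rpe"), rss_of("vo2max"))
  expect_lte(rss_of("vo2max+rpe+perceived_fatigue"), rss_of("vo2max+rpe"))
  # adj r2 never exceeds r2
  expect_true(all(s$table$adj_r2 <= s$table$r2 + 1e-12))
})

test_that("constant candidates are excluded with a warning", {
  d <- simulate_regression_cohort(n = 100, seed = 8)
  d$flat <- 5
  expect_warning(
    s <- best_subset_search(delta_rr_mean ~ vo2max + flat, d),
    "flat")
  expect_equal(nrow(s$table), 2)
})

test_that("noise-free generated data reproduce coefficients to 1e-8", {
  d <- simulate_regression_cohort(n = 500, noise_sd = 0, seed = 9)
  fit <- fit_ols(delta_rr_mean ~ vo2max + training_load + hr_max +
                   rpe + perceived_fatigue, d)
  truth <- r1_truth[names(coef(fit))]
  expect_equal(unname(coef(fit) / truth), rep(1, 6), tolerance = 1e-8)
})

test_that("subset-search methods: coef, predict, summary, plot", {
  d <- simulate_regression_cohort(n = 200, seed = 10)
  s <- best_subset_search(delta_rr_mean ~ vo2max + rpe +
                            perceived_fatigue, d)
  expect_named(coef(s), c("(Intercept)", s$fits[[1]]$predictor_names),
               ignore.order = TRUE)
  # passing the full cohort row warns about unused covariates
  expect_warning(pr <- predict(s, d[1:5, ]), "ignoring covariate")
  expect_length(pr, 5)
  sm <- summary(s, top = 2)
  expect_length(sm$details, 2)
  expect_output(print(s), "models over")
  pdf(NULL)
  expect_invisible(plot(s))
  dev.off()
})
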