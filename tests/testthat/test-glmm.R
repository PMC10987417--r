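test_that("spline basis has df columns and degenerates to linear at df = 1", {
  x <- seq(0, 20, length.out = 80)
  b1 <- spline_basis(x, 1L)
  expect_identical(ncol(b1$matrix), 1L)
  expect_equal(unname(b1$matrix[, 1]), x)
  b3 <- spline_basis(x, 3L)
  expect_identical(ncol(b3$matrix), 3L)
  # evaluating at the original x reproduces the basis
  expect_equal(unname(eval_basis(b3, x)), unname(b3$matrix))
  expect_error(spline_basis(x, 0L), "df")
  expect_error(spline_basis(rep(2, 10), 3L), "constant")
  expect_error(spline_basis(c(1, NA, 3), 2L), "finite")
})

test_that("a df=3 spline fits curvature a line cannot", {
  set.seed(4)
  x <- runif(200, -2, 2)
  y <- x^2 + rnorm(200, 0, 0.3)
  rss_lin <- sum(resid(lm(y ~ x))^2)
  rss_spl <- sum(resid(lm(y ~ spline_basis(x, 3L)$matrix))^2)
  expect_lt(rss_spl, rss_lin)
})

test_that("Bernoulli intercept-only fit recovers the closed-form logit", {
  d <- data.frame(y = rep(c(1L, 0L), c(30L, 70L)))
  fit <- fit_glmm(model_spec("y", "bernoulli"), d)
  expect_equal(unname(glmmTMB::fixef(fit$tmb)$cond[1]), log(30 / 70),
               tolerance = 1e-6)
  # predicted probability equals the sample proportion on any grid
  pr <- predict_conditional(fit, data.frame(.dummy = 1))
  expect_equal(pr$estimate, 0.3, tolerance = 1e-6)
  expect_true(pr$lower <= pr$estimate && pr$estimate <= pr$upper)
})

test_that("single-group data reduce to the GLM oracle to 4 decimals", {
  set.seed(21)
  n <- 400
  d <- data.frame(x = rnorm(n), g = "only_group")
  d$y <- rpois(n, exp(0.8 + 0.5 * d$x))
  expect_warning(
    fit <- fit_glmm(model_spec("y", "poisson", terms = "x", random = "g"), d),
    "dropping random")
  oracle <- glm(y ~ x, poisson(), d)
  expect_equal(unname(glmmTMB::fixef(fit$tmb)$cond), unname(coef(oracle)),
               tolerance = 1e-4)
  # negative binomial against the MASS oracle
  d$y2 <- MASS::rnegbin(n, exp(1 + 0.4 * d$x), theta = 3)
  fit_nb <- fit_glmm(model_spec("y2", "nb2", terms = "x"), d)
  oracle_nb <- MASS::glm.nb(y2 ~ x, d)
  expect_equal(unname(glmmTMB::fixef(fit_nb$tmb)$cond), unname(coef(oracle_nb)),
               tolerance = 1e-4)
  expect_equal(fit_nb$theta, oracle_nb$theta, tolerance = 1e-3)
  # Bernoulli with a covariate
  d$y3 <- rbinom(n, 1, plogis(-0.3 + 0.7 * d$x))
  fit_b <- fit_glmm(model_spec("y3", "bernoulli", terms = "x"), d)
  oracle_b <- glm(y3 ~ x, binomial(), d)
  expect_equal(unname(glmmTMB::fixef(fit_b$tmb)$cond), unname(coef(oracle_b)),
               tolerance = 1e-4)
})

test_that("zero group variance leaves coefficients at the GLM solution", {
  set.seed(33)
  n <- 600
  d <- data.frame(x = rnorm(n), g = sample(letters[1:10], n, TRUE))
  d$y <- rpois(n, exp(0.6 + 0.3 * d$x))  # no group effect in truth
  fit <- fit_glmm(model_spec("y", "poisson", terms = "x", random = "g"), d)
  oracle <- glm(y ~ x, poisson(), d)
  expect_equal(unname(glmmTMB::fixef(fit$tmb)$cond), unname(coef(oracle)),
               tolerance = 1e-3)
  expect_lt(fit$varcomp[["g"]], 0.01)
})

test_that("ZINB on zero-inflation-free data estimates a negligible pi", {
  set.seed(55)
  d <- data.frame(x = rnorm(500))
  d$y <- MASS::rnegbin(500, exp(1.5 + 0.5 * d$x), theta = 2)
  fit <- fit_glmm(model_spec("y", "zinb", terms = "x"), d)
  expect_lt(fit$zi_prob, 0.02)
  nb <- fit_glmm(model_spec("y", "nb2", terms = "x"), d)
  expect_equal(unname(glmmTMB::fixef(fit$tmb)$cond),
               unname(glmmTMB::fixef(nb$tmb)$cond), tolerance = 0.02)
})

test_that("confidence bands tighten with sample size and respect ordering", {
  width <- vapply(c(100L, 10000L), function(n) {
    set.seed(8)
    d <- data.frame(y = rbinom(n, 1, 0.4))
    fit <- fit_glmm(model_spec("y", "bernoulli"), d)
    pr <- predict_conditional(fit, data.frame(.dummy = 1))
    pr$upper - pr$lower
  }, numeric(1))
  expect_lt(width[2], width[1] / 5)
})

test_that("predicted means are monotone in the linear predictor", {
  set.seed(12)
  d <- data.frame(x = rnorm(300))
  d$y <- rpois(300, exp(0.5 + 0.6 * d$x))
  fit <- fit_glmm(model_spec("y", "poisson", terms = "x"), d)
  pr <- predict_conditional(fit, data.frame(x = seq(-2, 2, 0.5)))
  expect_true(all(diff(pr$estimate) > 0))
  expect_true(all(pr$lower <= pr$estimate & pr$estimate <= pr$upper))
})

test_that("variance explained behaves like a coefficient of determination", {
  set.seed(66)
  n <- 800
  d <- data.frame(x = rnorm(n), g = sample(letters[1:8], n, TRUE))
  d$y <- rpois(n, exp(0.5))
  null_fit <- fit_glmm(model_spec("y", "poisson"), d)
  expect_equal(variance_explained(null_fit)$marginal, 0)
  # pure fixed-effect data: conditional ~ marginal
  d$y2 <- rpois(n, exp(0.5 + 0.8 * d$x))
  f2 <- fit_glmm(model_spec("y2", "poisson", terms = "x", random = "g"), d)
  v2 <- variance_explained(f2)
  expect_lt(v2$conditional - v2$marginal, 0.02)
  expect_gte(v2$conditional, v2$marginal)
  # adding an informative covariate does not reduce marginal R2
  f0 <- fit_glmm(model_spec("y2", "poisson", random = "g"), d)
  expect_gte(v2$marginal, variance_explained(f0)$marginal)
  expect_true(v2$marginal >= 0 && v2$conditional <= 1)
})

test_that("effect sizes classify on the documented four-band scale", {
  expect_identical(cohens_d(0, 1)$magnitude, "nominal")
  expect_identical(cohens_d(0.16, 1)$magnitude, "nominal")
  expect_identical(cohens_d(0.2, 1)$magnitude, "small")
  expect_identical(cohens_d(0.5, 1)$magnitude, "medium")   # boundary inclusive
  expect_identical(cohens_d(0.8, 1)$magnitude, "large")
  expect_identical(cohens_d(-0.9, 1)$magnitude, "large")   # magnitude of |d|
  expect_error(cohens_d(1, 0), "dispersion")
  expect_identical(
    classify_magnitude(list(kind = "pearson_r", value = 0.69)), "nominal")
  expect_identical(
    classify_magnitude(list(kind = "pearson_r", value = 0.7)), "small")
  expect_identical(
    classify_magnitude(list(kind = "pearson_r", value = 0.95)), "large")
  expect_error(classify_magnitude(list(kind = "pearson_r", value = 1.2)), "1")
})

test_that("factor contrasts carry estimate, p-value and effect size", {
  set.seed(91)
  n <- 1200
  d <- data.frame(sex = sample(c("female", "male"), n, TRUE))
  d$y <- rbinom(n, 1, ifelse(d$sex == "female", 0.6, 0.4))
  fit <- fit_glmm(model_spec("y", "bernoulli", terms = "sex"), d)
  ct <- factor_contrast(fit, "sex")
  expect_equal(ct$diff, mean(d$y[d$sex == "male"]) - mean(d$y[d$sex == "female"]),
               tolerance = 1e-5)
  expect_lt(ct$p_value, 1e-6)
  expect_true(ct$lower <= ct$diff && ct$diff <= ct$upper)
  expect_identical(sign(ct$d), sign(ct$diff))
})
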