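#' Natural cubic spline basis with knots at quantiles
#'
#' Nonlinear covariate effects (time, severity, profile counts) enter the
#' mixed models through a natural cubic spline basis. `df = 1` degenerates
#' to a single linear column, which is how the linear-time comparison
#' models are specified. Interior knots sit at quantiles of `x`; duplicate
#' quantile knots (heavily tied covariates) are collapsed and the
#' effective df reduced with a warning.
#'
#' @param x Numeric vector, finite.
#' @param df Basis dimension (>= 1).
#' @return Object of class `spline_basis`: a list with the basis `matrix`
#'   (columns `sp1..spdf`) and enough state to evaluate the same basis at
#'   new covariate values via [eval_basis()].
#' @export
spline_basis <- function(x, df) {
  if (length(df) != 1L || is.na(df) || df < 1 || df != round(df)) {
    stop("df must be a single integer >= 1", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  if (df > 1 && length(unique(x)) < 2L) {
    stop("constant x cannot support a spline with df > 1", call. = FALSE)
  }
  if (df == 1) {
    m <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, "sp1"))
    out <- list(matrix = m, df = 1L, type = "linear")
  } else {
    probs <- seq_len(df - 1L) / df
    knots <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
    bknots <- range(x)
    knots <- knots[knots > bknots[1] & knots < bknots[2]]
    eff_df <- length(knots) + 1L
    if (eff_df < df) {
      warning("tied quantile knots: spline df reduced from ", df, " to ", eff_df,
              call. = FALSE)
    }
    m <- if (length(knots) > 0L) {
      splines::ns(x, knots = knots, Boundary.knots = bknots)
    } else {
      splines::ns(x, df = 1L, Boundary.knots = bknots)
    }
    cn <- paste0("sp", seq_len(ncol(m)))
    m2 <- matrix(as.numeric(m), nrow = length(x), dimnames = list(NULL, cn))
    out <- list(matrix = m2, df = ncol(m2), type = "ns",
                knots = knots, boundary = bknots)
  }
  class(out) <- "spline_basis"
  out
}

#' Evaluate a fitted spline basis at new covariate values
#' @param basis A [spline_basis()].
#' @param x New covariate values.
#' @return Matrix with the basis columns evaluated at `x`.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  if (basis$type == "linear") {
    return(matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, "sp1")))
  }
  m <- if (length(basis$knots) > 0L) {
    splines::ns(x, knots = basis$knots, Boundary.knots = basis$boundary)
  } else {
    splines::ns(x, df = 1L, Boundary.knots = basis$boundary)
  }
  matrix(as.numeric(m), nrow = length(x),
         dimnames = list(NULL, paste0("sp", seq_len(ncol(m)))))
}

#' Specify a generalized linear mixed model
#'
#' Declarative model specification consumed by [fit_glmm()]. Families:
#' `bernoulli` (0/1, logit), `binomial_k` (k trials, logit), `poisson`,
#' `nb2` (negative binomial, variance `mu + mu^2/theta`), and `zinb`
#' (NB2 conditional part with an intercept-only logit zero-inflation
#' component). Random intercepts are declared as grouping expressions,
#' e.g. `c("sport_group", "sport_group:athlete_id")` for athletes nested
#' in sport groups.
#'
#' @param response Response column name.
#' @param family One of `"bernoulli"`, `"binomial_k"`, `"poisson"`,
#'   `"nb2"`, `"zinb"`.
#' @param terms Character vector of plain fixed-effect terms (e.g. `"sex"`).
#' @param spline Optional `list(var = <column>, df = <int>)` for a natural
#'   spline effect of a continuous covariate.
#' @param spline_by Optional factor name to interact with the spline
#'   (e.g. `"sex"` gives basis-by-sex interaction plus main effect).
#' @param random Character vector of random-intercept grouping
#'   expressions; groups with < 2 levels are dropped at fit time.
#' @param size Number of trials for `binomial_k`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("bernoulli", "binomial_k", "poisson", "nb2", "zinb"),
                       terms = character(),
                       spline = NULL,
                       spline_by = NULL,
                       random = character(),
                       size = 6L) {
  family <- match.arg(family)
  if (family == "binomial_k" && (size < 1 || size != round(size))) {
    stop("binomial_k requires size >= 1", call. = FALSE)
  }
  if (!is.null(spline)) stopifnot(is.list(spline), !is.null(spline$var), !is.null(spline$df))
  structure(list(response = response, family = family, terms = terms,
                 spline = spline, spline_by = spline_by, random = random,
                 size = as.integer(size)),
            class = "model_spec")
}

#' Fit a mixed model from a [model_spec()]
#'
#' Estimation is maximum marginal likelihood with random intercepts
#' integrated out by Laplace approximation (via \pkg{glmmTMB}, the
#' standard engine for zero-inflated negative-binomial mixed models). The
#' ZINB density is `P(y) = pi * 1[y = 0] + (1 - pi) * NB2(y; mu, theta)`
#' with a log link on `mu` and logit on `pi`. Non-convergence is never
#' silent: the fit carries a `converged` flag and diagnostics, and a
#' warning is emitted.
#'
#' @param spec A [model_spec()].
#' @param data Data frame covering all columns in the spec.
#' @return Object of class `glmm_fit`: the engine fit plus extracted
#'   coefficients (`coef_table`), variance components (`varcomp`),
#'   `theta` (NB dispersion), `zi_prob`, `logLik`, `converged`, and the
#'   spline basis used (if any).
#' @export
fit_glmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  data <- as.data.frame(data)
  need <- c(spec$response, spec$terms, spec$spline_by,
            if (!is.null(spec$spline)) spec$spline$var,
            unique(unlist(strsplit(spec$random, ":", fixed = TRUE))))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) stop("data missing column(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)

  # character covariates get stable factor coding (alphabetical levels)
  for (v in unique(c(spec$terms, spec$spline_by))) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L) {
      stop("term '", v, "' has a single level: effect inestimable", call. = FALSE)
    }
  }

  basis <- NULL
  sp_cols <- character(0)
  if (!is.null(spec$spline)) {
    basis <- spline_basis(data[[spec$spline$var]], spec$spline$df)
    sp_cols <- colnames(basis$matrix)
    data[sp_cols] <- basis$matrix
  }

  rhs_parts <- character(0)
  if (length(sp_cols) > 0L) {
    sp_sum <- paste0("(", paste(sp_cols, collapse = " + "), ")")
    rhs_parts <- if (!is.null(spec$spline_by)) {
      paste0(sp_sum, " * ", spec$spline_by)
    } else sp_sum
  }
  rhs_parts <- c(rhs_parts, spec$terms)
  if (length(rhs_parts) == 0L) rhs_parts <- "1"

  random <- spec$random
  if (length(random) > 0L) {
    keep <- vapply(random, function(r) {
      vars <- strsplit(r, ":", fixed = TRUE)[[1]]
      g <- interaction(data[vars], drop = TRUE)
      nlevels(g) >= 2L
    }, logical(1))
    if (any(!keep)) {
      warning("dropping random term(s) with < 2 levels: ",
              paste(random[!keep], collapse = ", "), call. = FALSE)
      random <- random[keep]
    }
  }
  re_parts <- if (length(random) > 0L) paste0("(1 | ", random, ")") else character(0)

  lhs <- switch(spec$family,
    binomial_k = sprintf("cbind(%s, %d - %s)", spec$response, spec$size, spec$response),
    spec$response
  )
  if (spec$family == "binomial_k") {
    y <- data[[spec$response]]
    if (any(y < 0 | y > spec$size)) {
      stop("response outside [0, ", spec$size, "] for binomial_k", call. = FALSE)
    }
  }
  fml <- stats::as.formula(
    paste(lhs, "~", paste(c(rhs_parts, re_parts), collapse = " + "))
  )
  fam <- switch(spec$family,
    bernoulli = stats::binomial(),
    binomial_k = stats::binomial(),
    poisson = stats::poisson(),
    nb2 = glmmTMB::nbinom2(),
    zinb = glmmTMB::nbinom2()
  )
  zif <- if (spec$family == "zinb") ~1 else ~0

  fit <- suppressWarnings(
    glmmTMB::glmmTMB(fml, data = data, family = fam, ziformula = zif)
  )
  ok <- function(f) isTRUE(f$sdr$pdHess) && isTRUE(f$fit$convergence == 0)
  if (!ok(fit)) {
    # restart with a quasi-Newton optimizer; keep whichever fit converged
    fit2 <- try(suppressWarnings(glmmTMB::glmmTMB(
      fml, data = data, family = fam, ziformula = zif,
      control = glmmTMB::glmmTMBControl(
        optimizer = stats::optim, optArgs = list(method = "BFGS"))
    )), silent = TRUE)
    if (!inherits(fit2, "try-error") && ok(fit2)) fit <- fit2
  }
  pdh <- isTRUE(fit$sdr$pdHess)
  conv <- isTRUE(fit$fit$convergence == 0)
  if (!pdh || !conv) {
    warning("model did not converge cleanly (pdHess = ", pdh,
            ", optimizer code = ", fit$fit$convergence, ")", call. = FALSE)
  }

  sm <- summary(fit)$coefficients$cond
  vc <- glmmTMB::VarCorr(fit)$cond
  varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  theta <- if (spec$family %in% c("nb2", "zinb")) stats::sigma(fit) else NA_real_
  zi_prob <- if (spec$family == "zinb") {
    as.numeric(stats::plogis(glmmTMB::fixef(fit)$zi[1]))
  } else 0

  structure(
    list(tmb = fit, spec = spec, basis = basis, formula = fml,
         coef_table = sm, varcomp = varcomp, theta = theta, zi_prob = zi_prob,
         logLik = as.numeric(stats::logLik(fit)),
         converged = pdh && conv, n_obs = nrow(data)),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Mixed model fit (", x$spec$family, "), n = ", x$n_obs,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(round(x$coef_table, 4))
  if (length(x$varcomp) > 0L) {
    cat("Random-intercept variances:\n")
    print(round(x$varcomp, 4))
  }
  if (!is.na(x$theta)) cat("NB dispersion theta:", round(x$theta, 3), "\n")
  if (x$spec$family == "zinb") cat("Zero-inflation pi:", round(x$zi_prob, 4), "\n")
  cat("logLik:", round(x$logLik, 2), "\n")
  invisible(x)
}

# Fixed-effects design matrix for new covariate values, reusing the
# spline basis and factor coding from the fit.
fixef_design <- function(fit, newdata) {
  spec <- fit$spec
  newdata <- as.data.frame(newdata)
  if (!is.null(fit$basis)) {
    newdata[colnames(fit$basis$matrix)] <-
      eval_basis(fit$basis, newdata[[spec$spline$var]])
  }
  for (v in unique(c(spec$terms, spec$spline_by))) {
    old <- fit$tmb$frame[[v]]
    if (is.factor(old)) {
      newdata[[v]] <- factor(as.character(newdata[[v]]), levels = levels(old))
    }
  }
  rhs_parts <- character(0)
  if (!is.null(fit$basis)) {
    sp_sum <- paste0("(", paste(colnames(fit$basis$matrix), collapse = " + "), ")")
    rhs_parts <- if (!is.null(spec$spline_by)) paste0(sp_sum, " * ", spec$spline_by)
                 else sp_sum
  }
  rhs_parts <- c(rhs_parts, spec$terms)
  if (length(rhs_parts) == 0L) rhs_parts <- "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(rhs_parts, collapse = " + "))),
                           newdata)
  beta <- glmmTMB::fixef(fit$tmb)$cond
  X[, names(beta), drop = FALSE]
}

linkinv_of <- function(fit) {
  switch(fit$spec$family,
    bernoulli = stats::plogis,
    binomial_k = function(eta) fit$spec$size * stats::plogis(eta),
    function(eta) exp(eta))
}

#' Population-level conditional effects on a covariate grid
#'
#' Predicted mean response with 95% confidence bounds, with random
#' effects at zero (population level). Intervals are delta-method Wald
#' intervals on the linear-predictor scale, transformed through the
#' inverse link, so `lower <= estimate <= upper` holds everywhere. For
#' the ZINB family the conditional mean is scaled by the estimated
#' non-structural-zero probability `1 - pi` (intercept-only
#' zero-inflation; its estimation uncertainty is not propagated). Grid
#' values outside the spline support are flagged as extrapolation.
#'
#' @param fit A [fit_glmm()] result.
#' @param grid Data frame of covariate values (one column per fixed
#'   covariate in the spec).
#' @return Data frame of class `conditional_effect`: the grid plus
#'   `estimate`, `lower`, `upper`.
#' @export
predict_conditional <- function(fit, grid) {
  stopifnot(inherits(fit, "glmm_fit"))
  grid <- as.data.frame(grid)
  if (!is.null(fit$basis) && fit$basis$type == "ns") {
    x <- grid[[fit$spec$spline$var]]
    if (any(x < fit$basis$boundary[1] | x > fit$basis$boundary[2])) {
      warning("grid extends beyond the spline support: extrapolating",
              call. = FALSE)
    }
  }
  X <- fixef_design(fit, grid)
  beta <- glmmTMB::fixef(fit$tmb)$cond
  V <- stats::vcov(fit$tmb)$cond
  lp <- as.numeric(X %*% beta)
  se <- sqrt(pmax(0, rowSums((X %*% V) * X)))
  inv <- linkinv_of(fit)
  scale <- if (fit$spec$family == "zinb") 1 - fit$zi_prob else 1
  out <- grid
  out$estimate <- scale * inv(lp)
  out$lower <- scale * inv(lp - 1.96 * se)
  out$upper <- scale * inv(lp + 1.96 * se)
  class(out) <- c("conditional_effect", class(out))
  out
}

#' Sex (two-level factor) contrast at covariate grid points
#'
#' Difference in predicted mean response between the two levels of a
#' factor at each grid point, with a delta-method Wald test on the
#' linear-predictor contrast and a standardized effect size: the
#' response-scale difference divided by the pooled family standard
#' deviation at the average predicted mean (binomial:
#' `sqrt(k p (1 - p))`; NB2/ZINB: `sqrt(mu + mu^2 / theta)`; Poisson:
#' `sqrt(mu)`).
#'
#' @param fit A [fit_glmm()] result whose spec contains `factor_name`.
#' @param factor_name Two-level factor, e.g. `"sex"`.
#' @param grid Data frame of the remaining covariates (may be a single
#'   empty row for models with no other fixed covariates).
#' @return Data frame: grid, per-level estimates, `diff` (level2 -
#'   level1), `se`, `lower`, `upper`, `p_value`, `d`, `magnitude`.
#' @export
factor_contrast <- function(fit, factor_name, grid = data.frame(.row = 1)[, 0, drop = FALSE]) {
  stopifnot(inherits(fit, "glmm_fit"))
  lev <- levels(fit$tmb$frame[[factor_name]])
  if (length(lev) != 2L) stop("factor_contrast needs a two-level factor", call. = FALSE)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) grid <- data.frame(row.names = 1)
  g1 <- grid; g1[[factor_name]] <- lev[1]
  g2 <- grid; g2[[factor_name]] <- lev[2]
  X1 <- fixef_design(fit, g1); X2 <- fixef_design(fit, g2)
  beta <- glmmTMB::fixef(fit$tmb)$cond
  V <- stats::vcov(fit$tmb)$cond
  inv <- linkinv_of(fit)
  scale <- if (fit$spec$family == "zinb") 1 - fit$zi_prob else 1
  lp1 <- as.numeric(X1 %*% beta); lp2 <- as.numeric(X2 %*% beta)
  mu1 <- scale * inv(lp1); mu2 <- scale * inv(lp2)
  # derivative of the inverse link at each linear predictor
  dinv <- switch(fit$spec$family,
    bernoulli = function(eta) stats::dlogis(eta),
    binomial_k = function(eta) fit$spec$size * stats::dlogis(eta),
    function(eta) exp(eta))
  G <- scale * (dinv(lp2) * X2 - dinv(lp1) * X1)
  se <- sqrt(pmax(0, rowSums((G %*% V) * G)))
  diff <- mu2 - mu1
  # inference on the link scale (standard Wald contrast); estimate, CI
  # and effect size are reported on the response scale
  C <- X2 - X1
  se_link <- sqrt(pmax(0, rowSums((C %*% V) * C)))
  z <- ifelse(se_link > 0, (lp2 - lp1) / se_link, 0)
  pooled <- pooled_sd(fit, (mu1 + mu2) / 2)
  d <- cohens_d(diff, pooled)
  if (inherits(d, "effect_size")) d <- list(d)
  out <- grid
  out[[paste0(factor_name, "_", lev[1])]] <- mu1
  out[[paste0(factor_name, "_", lev[2])]] <- mu2
  out$diff <- diff
  out$se <- se
  out$lower <- diff - 1.96 * se
  out$upper <- diff + 1.96 * se
  out$p_value <- 2 * stats::pnorm(-abs(z))
  out$d <- vapply(d, function(e) e$value, numeric(1))
  out$magnitude <- vapply(d, function(e) e$magnitude, character(1))
  rownames(out) <- NULL
  out
}

pooled_sd <- function(fit, mu) {
  switch(fit$spec$family,
    bernoulli = sqrt(mu * (1 - mu)),
    binomial_k = { p <- mu / fit$spec$size; sqrt(fit$spec$size * p * (1 - p)) },
    poisson = sqrt(mu),
    sqrt(mu + mu^2 / fit$theta))
}

#' Joint Wald test of a coefficient subset
#'
#' Chi-square test that all coefficients whose names match `pattern` are
#' zero; used for the spline-by-sex interaction tests.
#'
#' @param fit A [fit_glmm()] result.
#' @param pattern Regular expression over coefficient names.
#' @return List: `chisq`, `df`, `p_value`, `coefficients`.
#' @export
wald_joint <- function(fit, pattern) {
  beta <- glmmTMB::fixef(fit$tmb)$cond
  idx <- grep(pattern, names(beta))
  if (length(idx) == 0L) stop("no coefficients match '", pattern, "'", call. = FALSE)
  V <- stats::vcov(fit$tmb)$cond[idx, idx, drop = FALSE]
  b <- beta[idx]
  stat <- as.numeric(t(b) %*% solve(V) %*% b)
  list(chisq = stat, df = length(idx),
       p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE),
       coefficients = b)
}

#' Marginal and conditional variance explained (Nakagawa-style R2)
#'
#' Decomposes latent-scale variance into fixed-effect variance (variance
#' of the fixed linear predictor over the data), random-intercept
#' variance, and a distribution-specific residual variance: `pi^2/3` for
#' logit models, the lognormal approximation `log(1 + 1/lambda)` for
#' Poisson and `log(1 + 1/lambda + 1/theta)` for NB2/ZINB, with `lambda`
#' the mean fitted value. Marginal R2 uses fixed effects only;
#' conditional R2 adds the random terms; `random_share` is the fraction
#' of explained variance attributable to the random terms.
#'
#' @param fit A converged [fit_glmm()] result.
#' @return List: `marginal`, `conditional`, `random_share`, and the
#'   variance components.
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) stop("variance_explained is undefined for non-converged fits",
                           call. = FALSE)
  X <- stats::model.matrix(fit$tmb)
  beta <- glmmTMB::fixef(fit$tmb)$cond
  lp_fixed <- as.numeric(X[, names(beta), drop = FALSE] %*% beta)
  var_f <- stats::var(lp_fixed)
  var_r <- sum(fit$varcomp)
  lambda <- mean(exp(lp_fixed + var_r / 2))
  var_d <- switch(fit$spec$family,
    bernoulli = pi^2 / 3,
    binomial_k = pi^2 / 3,
    poisson = log1p(1 / lambda),
    log1p(1 / lambda + 1 / fit$theta))
  tot <- var_f + var_r + var_d
  list(marginal = var_f / tot,
       conditional = (var_f + var_r) / tot,
       random_share = if (var_f + var_r > 0) var_r / (var_f + var_r) else 0,
       var_fixed = var_f, var_random = var_r, var_resid = var_d)
}

#' Standardized effect size for a contrast
#'
#' Cohen's d: contrast divided by pooled standard deviation.
#'
#' @param contrast Numeric contrast estimate(s) on the response scale.
#' @param pooled_sd Pooled standard deviation(s), > 0.
#' @return List of objects of class `effect_size` (or a single one for
#'   scalar input), each with `kind`, `value`, `magnitude`.
#' @export
cohens_d <- function(contrast, pooled_sd) {
  if (any(pooled_sd <= 0)) stop("pooled dispersion must be > 0: effect size undefined",
                                call. = FALSE)
  out <- mapply(function(ct, sd) {
    e <- structure(list(kind = "cohens_d", value = ct / sd), class = "effect_size")
    e$magnitude <- classify_magnitude(e)
    e
  }, contrast, pooled_sd, SIMPLIFY = FALSE)
  if (length(out) == 1L) out[[1L]] else out
}

#' Magnitude category of an effect size
#'
#' Four-band scale with lower-inclusive boundaries: for Cohen's d,
#' nominal < 0.2 <= small < 0.5 <= medium < 0.8 <= large; for Pearson's
#' r (absolute value), nominal < 0.7 <= small < 0.8 <= medium < 0.9 <=
#' large.
#'
#' @param effect An `effect_size` (from [cohens_d()]) or a list with
#'   `kind` (`"cohens_d"` / `"pearson_r"`) and `value`.
#' @return Character: `"nominal"`, `"small"`, `"medium"`, or `"large"`.
#' @export
classify_magnitude <- function(effect) {
  v <- abs(effect$value)
  cuts <- switch(effect$kind,
    cohens_d = c(0.2, 0.5, 0.8),
    pearson_r = { if (v > 1) stop("pearson_r must be in [-1, 1]", call. = FALSE)
                  c(0.7, 0.8, 0.9) },
    stop("unknown effect-size kind: ", effect$kind, call. = FALSE))
  c("nominal", "small", "medium", "large")[findInterval(v, cuts) + 1L]
}
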