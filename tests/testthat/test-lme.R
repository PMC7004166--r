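small_table <- function(seed = 1, n_ind = 5, n_days = 40, ...) {
  simulate_lme_data(n_ind = n_ind, n_days = n_days,
                    beta = c("(Intercept)" = -1.2, musth = 0.4, age = -0.01,
                             ndvi = 0.1),
                    G = diag(c(0.02, 0.005)), phi = 0.3, delta = 1.5,
                    sigma = 0.2, seed = seed, ...)
}

test_that("the fixed design has the documented 24-column structure", {
  tab <- small_table()
  d <- build_design(tab)
  expect_equal(ncol(d$X), 24)
  expect_equal(colnames(d$X)[1:2], c("(Intercept)", "musth"))
  expect_equal(sum(grepl("^musth:", colnames(d$X))), 11)
  # rows sorted by individual then date; group index blocks
  expect_true(!is.unsorted(d$group))
  expect_equal(length(unique(d$group)), 5)
  # with musth identically zero, every interaction column vanishes
  tab0 <- transform(tab, musth = 0)
  d0 <- build_design(tab0)
  expect_true(all(d0$X[, grepl("^musth", colnames(d0$X))] == 0))
  # response is the log of the speed column
  expect_equal(d$y, log(tab[order(tab$id, tab$date), "mean_speed_kmh"]))
})

test_that("profiled likelihood reduces to closed-form OLS in the degenerate case", {
  tab <- small_table(seed = 3)
  d <- build_design(tab)
  cols <- c("(Intercept)", "musth", "age", "ndvi")
  at <- lme_loglik_at(d, Lambda = matrix(0, 2, 2), phi = 0, delta = 1,
                      method = "ML", fixed_cols = cols)
  ols <- lm(d$y ~ d$X[, cols] - 1)
  n <- length(d$y)
  s2 <- sum(residuals(ols)^2) / n
  ll_ols <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_equal(at$loglik, ll_ols, tolerance = 1e-8)
  expect_equal(unname(at$beta), unname(coef(ols)), tolerance = 1e-10)
})

test_that("likelihood agrees with lme4 for the random-intercept-and-slope submodel", {
  skip_if_not_installed("lme4")
  tab <- small_table(seed = 4, n_ind = 8)
  d <- build_design(tab)
  cols <- c("(Intercept)", "musth", "age", "ndvi")
  df <- data.frame(y = d$y, musth = d$X[, "musth"], age = d$X[, "age"],
                   ndvi = d$X[, "ndvi"], g = d$group)
  lf <- lme4::lmer(y ~ musth + age + ndvi + (1 + ndvi | g), data = df,
                   REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(lf)$g
  s2 <- lme4::getME(lf, "sigma")^2
  at <- lme_loglik_at(d, Lambda = vc[1:2, 1:2] / s2, phi = 0, delta = 1,
                      method = "ML", fixed_cols = cols)
  expect_equal(at$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(at$beta), unname(lme4::fixef(lf)), tolerance = 1e-6)

  # our optimiser, with phi and delta pinned to the submodel, reaches the
  # same maximum
  fit <- fit_lme(d, "ML", cols, fix_phi = 0, fix_delta = 1)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
})

test_that("likelihood is invariant to fixed-column reordering", {
  tab <- small_table(seed = 5)
  d <- build_design(tab)
  cols <- c("(Intercept)", "musth", "age", "ndvi", "slope")
  f1 <- fit_lme(d, "ML", cols)
  f2 <- fit_lme(d, "ML", rev(cols))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$beta[cols], f2$beta[cols], tolerance = 1e-4)
})

test_that("profiled GLS solution satisfies the normal equations at the optimum", {
  tab <- small_table(seed = 6)
  d <- build_design(tab)
  cols <- c("(Intercept)", "musth", "age", "ndvi")
  fit <- fit_lme(d, "ML", cols)
  # gradient of the profiled deviance w.r.t. beta must vanish: check via
  # X' V^-1 (y - X beta) = 0 assembled group by group
  groups <- musthmove:::lme_group_data(d, cols)
  pars <- musthmove:::theta_to_pars(fit$theta)
  grad <- numeric(length(cols))
  for (g in groups) {
    C <- exp(log(abs(pars$phi)) * g$gap); if (pars$phi < 0) C <- C * (-1)^g$gap
    dv <- ifelse(g$musth == 1, pars$delta, 1)
    W <- g$Z %*% pars$Lambda %*% t(g$Z) + C * tcrossprod(dv)
    grad <- grad + drop(crossprod(g$X, solve(W, g$y - g$X %*% fit$beta)))
  }
  expect_lt(max(abs(grad)), 1e-6 * length(d$y))
})

test_that("duplicating every individual preserves beta and shrinks SEs by sqrt(2)", {
  tab <- small_table(seed = 7)
  tab2 <- tab
  tab2$id <- paste0(tab2$id, "_copy")
  both <- rbind(tab, tab2)
  cols <- c("(Intercept)", "musth", "age", "ndvi")
  f1 <- fit_lme(build_design(tab), "ML", cols)
  f2 <- fit_lme(build_design(both), "ML", cols, start = f1$theta)
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 1e-3)
  expect_equal(unname(f2$se / f1$se), rep(1 / sqrt(2), 4), tolerance = 0.02)
})

test_that("the full model recovers its generating parameters (30 x 120)", {
  truth <- list(beta = c("(Intercept)" = -1.2, musth = 0.76, age = -0.008,
                         "musth:age" = 0.02, ndvi = 0.12),
                G = matrix(c(0.025, 0.004, 0.004, 0.006), 2), phi = 0.35,
                delta = 1.8, sigma = 0.2)
  tab <- simulate_lme_data(n_ind = 30, n_days = 120, beta = truth$beta,
                           G = truth$G, phi = truth$phi, delta = truth$delta,
                           sigma = truth$sigma, seed = 11)
  d <- build_design(tab)
  cols <- names(truth$beta)
  fit <- fit_lme(d, "ML", cols)
  for (nm in cols) {
    expect_lt(abs(fit$beta[nm] - truth$beta[nm]), 3 * fit$se[nm])
  }
  # variance parameters against asymptotic SEs on the optimiser scale
  th_true <- c(log(chol(truth$G / truth$sigma^2)[1, 1]),
               chol(truth$G / truth$sigma^2)[1, 2],
               log(chol(truth$G / truth$sigma^2)[2, 2]),
               atanh(truth$phi), log(truth$delta))
  # chol() is upper triangular; our theta uses the lower factor
  L <- t(chol(truth$G / truth$sigma^2))
  th_true <- c(log(L[1, 1]), L[2, 1], log(L[2, 2]), atanh(truth$phi),
               log(truth$delta))
  for (k in c(4, 5)) {  # phi and delta, the parameters the model is about
    expect_lt(abs(fit$theta[k] - th_true[k]), 3 * fit$theta_se[k])
  }
  expect_lt(abs(fit$sigma - truth$sigma) / truth$sigma, 0.1)
})

test_that("backward selection respects marginality and drops null terms", {
  tab <- small_table(seed = 8)
  d <- build_design(tab)
  cols <- c("(Intercept)", "musth", "age", "age2", "ndvi")
  # age2 retained => age is not droppable
  expect_false("age" %in% musthmove:::droppable_terms(cols))
  expect_true("age2" %in% musthmove:::droppable_terms(cols))
  # musth:age retained => musth and age protected
  cols2 <- c("(Intercept)", "musth", "age", "ndvi", "musth:age")
  dr <- musthmove:::droppable_terms(cols2)
  expect_false(any(c("musth", "age") %in% dr))
  expect_setequal(dr, c("musth:age", "ndvi"))

  sel <- select_model(d, fixed_cols = cols)
  expect_equal(sel$fit$method, "REML")
  expect_true(all(c("(Intercept)", "musth") %in% sel$fit$fixed_cols))
})

test_that("a null term is dropped in at least 90% of replicates", {
  drops <- vapply(1:150, function(r) {
    tab <- simulate_lme_data(n_ind = 5, n_days = 30,
                             beta = c("(Intercept)" = -1.2, musth = 0.5),
                             G = diag(c(0.02, 0.004)), phi = 0.2, delta = 1.3,
                             sigma = 0.2, seed = 400 + r)
    d <- build_design(tab)
    # "ndvi" has true coefficient 0
    sel <- select_model(d, fixed_cols = c("(Intercept)", "musth", "ndvi"))
    !("ndvi" %in% sel$fit$fixed_cols)
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("the NDVI random-slope diagnostic detects a strong slope", {
  tab <- simulate_lme_data(n_ind = 10, n_days = 60,
                           beta = c("(Intercept)" = -1.2, musth = 0.5),
                           G = matrix(c(0.02, 0, 0, 0.08), 2), phi = 0,
                           delta = 1, sigma = 0.15, seed = 12)
  d <- build_design(tab)
  rl <- random_slope_lrt(d, c("(Intercept)", "musth", "ndvi"))
  expect_lt(rl$p, 0.001)
  expect_gte(rl$chisq, 0)
})

test_that("likelihood-ratio tests between nested fits use df = 1 per term", {
  tab <- small_table(seed = 9)
  d <- build_design(tab)
  full <- fit_lme(d, "ML", c("(Intercept)", "musth", "age", "ndvi"))
  red <- fit_lme(d, "ML", c("(Intercept)", "age", "ndvi"))
  t1 <- lrt(full, red)
  expect_equal(t1$df, 1)
  expect_gte(t1$chisq, 0)
  expect_equal(t1$p, pchisq(t1$chisq, 1, lower.tail = FALSE))
})

test_that("effect ratios evaluate the musth contrast exactly", {
  tab <- small_table(seed = 10)
  d <- build_design(tab)
  fit <- fit_lme(d, "REML", c("(Intercept)", "musth", "age", "musth:age"))
  # hand-evaluated exp contrast at age 50 (centred age 15); the small
  # cohort need not span these ages, so range warnings are irrelevant here
  hand <- exp(fit$beta["musth"] + 15 * fit$beta["musth:age"])
  er <- suppressWarnings(effect_ratio(fit, age = 50, n_boot = 0))
  expect_equal(er$ratio, unname(hand), tolerance = 1e-12)
  # at the centring age only the main musth term contributes
  er35 <- suppressWarnings(effect_ratio(fit, age = 35, n_boot = 0))
  expect_equal(er35$ratio, unname(exp(fit$beta["musth"])), tolerance = 1e-12)

  # a fit with beta_musth = ln 1.49 and no interactions gives 1.49 at any age
  fit2 <- fit
  fit2$beta <- c("(Intercept)" = -1, musth = log(1.49))
  fit2$fixed_cols <- names(fit2$beta)
  expect_equal(suppressWarnings(effect_ratio(fit2, 35, n_boot = 0))$ratio, 1.49)
  expect_equal(suppressWarnings(effect_ratio(fit2, 50, n_boot = 0))$ratio, 1.49)
  # all musth coefficients zero -> ratio 1 everywhere
  fit2$beta["musth"] <- 0
  expect_equal(suppressWarnings(effect_ratio(fit2, 44, n_boot = 0))$ratio, 1)
  expect_warning(effect_ratio(fit, 99, n_boot = 0), "outside")

  # bootstrap CI brackets the point estimate
  er_ci <- suppressWarnings(effect_ratio(fit, 35, n_boot = 30, seed = 2))
  expect_true(er_ci$lo <= er_ci$ratio && er_ci$ratio <= er_ci$hi)
})
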