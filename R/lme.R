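# Linear mixed-effects analysis of log daily movement: musth state
# interacting with age and environmental covariates, per-individual random
# intercept and NDVI slope, continuous-AR1 residual correlation across
# calendar-day gaps, and a state-specific residual variance (the musth
# variance ratio delta). The marginal Gaussian likelihood is maximised
# numerically over the variance parameters with the fixed effects profiled
# out by generalised least squares.

LME_MAIN_TERMS <- c("age", "age2", "ndvi", "ndvi2", "slope", "slope2",
                    "vrm", "vrm2", "dist_water", "dist_water2", "protected")

lme_term_columns <- function() {
  c("(Intercept)", "musth", LME_MAIN_TERMS, paste0("musth:", LME_MAIN_TERMS))
}

#' Build design matrices for the movement mixed model
#'
#' The fixed design has 24 columns in documented order: intercept, musth,
#' the 11 main covariate terms (age, age^2, NDVI, NDVI^2, slope, slope^2,
#' VRM, VRM^2, distance to water and its square, protected) and the 11
#' musth interactions. The random design is per-individual intercept and
#' NDVI slope. Rows are sorted by (individual, date) so AR1 lags are
#' well-defined; gaps between non-consecutive days decay the residual
#' correlation as phi^(day gap). Rows with missing values are dropped with
#' a message, as are rows labelled `excluded`.
#'
#' @param daily Analysis table with columns id, date, musth label (column
#'   `label` or logical `musth`), age (centred, column `age`), the
#'   standardized covariates ndvi, slope, vrm, dist_water, protected, and
#'   the response column.
#' @param response "speed" (log mean_speed_kmh) or "mcp" (log mcp95_km2).
#' @return List of class `lme_design`: y, X (n x 24), Z (n x 2), group
#'   (integer), day (integer day numbers), musth (0/1), ids.
#' @export
build_design <- function(daily, response = c("speed", "mcp")) {
  response <- match.arg(response)
  col <- if (response == "speed") "mean_speed_kmh" else "mcp95_km2"
  if ("label" %in% names(daily)) {
    daily <- daily[daily$label != "excluded", , drop = FALSE]
    daily$musth <- as.numeric(daily$label == "musth")
  }
  need <- c("id", "date", "musth", "age", "ndvi", "slope", "vrm",
            "dist_water", "protected", col)
  miss <- setdiff(need, names(daily))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ok <- stats::complete.cases(daily[, need]) & daily[[col]] > 0
  if (any(!ok)) message(sum(!ok), " row(s) dropped (missing values)")
  daily <- daily[ok, , drop = FALSE]
  daily <- daily[order(daily$id, daily$date), , drop = FALSE]
  mains <- cbind(age = daily$age, age2 = daily$age^2,
                 ndvi = daily$ndvi, ndvi2 = daily$ndvi^2,
                 slope = daily$slope, slope2 = daily$slope^2,
                 vrm = daily$vrm, vrm2 = daily$vrm^2,
                 dist_water = daily$dist_water, dist_water2 = daily$dist_water^2,
                 protected = daily$protected)
  X <- cbind(1, daily$musth, mains, daily$musth * mains)
  colnames(X) <- lme_term_columns()
  Z <- cbind(intercept = 1, ndvi = daily$ndvi)
  structure(list(y = log(daily[[col]]), X = X, Z = Z,
                 group = as.integer(factor(daily$id)),
                 ids = levels(factor(daily$id)),
                 day = as.integer(daily$date), musth = daily$musth),
            class = "lme_design")
}

# Per-group cached pieces reused across likelihood evaluations.
lme_group_data <- function(design, fixed_cols) {
  X <- design$X[, fixed_cols, drop = FALSE]
  lapply(split(seq_along(design$y), design$group), function(ix) {
    list(y = design$y[ix], X = X[ix, , drop = FALSE],
         Z = design$Z[ix, , drop = FALSE],
         gap = abs(outer(design$day[ix], design$day[ix], "-")),
         musth = design$musth[ix])
  })
}

# Profiled marginal log-likelihood at given variance parameters.
# Lambda = G / sigma^2 (2x2 psd), phi in (-1,1), delta > 0.
# Returns loglik, beta, sigma2, cov_unscaled (solve of X'W^-1X).
lme_profile <- function(groups, Lambda, phi, delta, method = c("ML", "REML")) {
  method <- match.arg(method)
  p <- ncol(groups[[1]]$X)
  A <- matrix(0, p, p); b <- numeric(p)
  logdet <- 0; n <- 0
  sol <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    ni <- length(g$y)
    if (abs(phi) < 1e-12) {
      C <- diag(ni)
    } else {
      C <- exp(log(abs(phi)) * g$gap)
      if (phi < 0) C <- C * (-1)^g$gap
    }
    dvec <- ifelse(g$musth == 1, delta, 1)
    W <- g$Z %*% Lambda %*% t(g$Z) + C * tcrossprod(dvec)
    L <- chol(W)  # upper triangular
    logdet <- logdet + 2 * sum(log(diag(L)))
    s <- backsolve(L, cbind(g$y, g$X), transpose = TRUE)
    sol[[i]] <- s
    A <- A + crossprod(s[, -1, drop = FALSE])
    b <- b + drop(crossprod(s[, -1, drop = FALSE], s[, 1]))
    n <- n + ni
  }
  Achol <- chol(A)
  beta <- backsolve(Achol, backsolve(Achol, b, transpose = TRUE))
  rss <- 0
  for (i in seq_along(sol)) {
    e <- sol[[i]][, 1] - sol[[i]][, -1, drop = FALSE] %*% beta
    rss <- rss + sum(e^2)
  }
  if (method == "ML") {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  } else {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet +
                    2 * sum(log(diag(Achol))) + (n - p))
  }
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2,
       cov_unscaled = chol2inv(Achol), n = n)
}

theta_to_pars <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  list(Lambda = L %*% t(L), phi = tanh(theta[4]), delta = exp(theta[5]))
}

#' Evaluate the profiled marginal log-likelihood at given parameters
#'
#' The fixed effects and the residual scale are profiled out analytically;
#' useful for verifying the likelihood against closed forms (with
#' `Lambda = 0`, `phi = 0`, `delta = 1` it reduces to the OLS Gaussian
#' log-likelihood).
#'
#' @param design An `lme_design`.
#' @param Lambda Random-effects covariance divided by the residual
#'   variance (2x2).
#' @param phi AR1 parameter in (-1, 1).
#' @param delta Musth residual-SD ratio (> 0).
#' @param method "ML" or "REML".
#' @param fixed_cols Fixed-effect columns used.
#' @return List: loglik, beta, sigma2.
#' @export
lme_loglik_at <- function(design, Lambda = matrix(0, 2, 2), phi = 0, delta = 1,
                          method = "ML", fixed_cols = colnames(design$X)) {
  groups <- lme_group_data(design, fixed_cols)
  lme_profile(groups, Lambda, phi, delta, method)[c("loglik", "beta", "sigma2")]
}

#' Fit the movement mixed-effects model
#'
#' Numerically maximises the profiled marginal likelihood over the
#' random-effects covariance (log-Cholesky parameterised), the AR1
#' parameter and the musth variance ratio.
#'
#' @param design An `lme_design`.
#' @param method "ML" (for likelihood-ratio testing) or "REML" (for final
#'   estimates).
#' @param fixed_cols Fixed-effect columns to include (default all 24).
#' @param start Optional start for the 5 variance parameters
#'   (log l11, l21, log l22, atanh phi, log delta).
#' @param fix_phi,fix_delta Optionally hold the AR1 parameter or the musth
#'   variance ratio fixed (e.g. `fix_phi = 0, fix_delta = 1` reduces the
#'   model to a standard random-intercept-and-slope fit).
#' @param random "both" (intercept + NDVI slope, the analysis model) or
#'   "intercept" only -- used by [random_slope_lrt()].
#' @return Object of class `lme_fit` with elements beta, se, vcov_beta, G,
#'   phi, delta, sigma, loglik, method, theta, singular, converged.
#' @export
fit_lme <- function(design, method = c("ML", "REML"),
                    fixed_cols = colnames(design$X), start = NULL,
                    fix_phi = NULL, fix_delta = NULL,
                    random = c("both", "intercept")) {
  method <- match.arg(method)
  random <- match.arg(random)
  if (length(unique(design$group)) < 2) stop("need >= 2 individuals", call. = FALSE)
  groups <- lme_group_data(design, fixed_cols)
  if (is.null(start)) start <- c(log(0.3), 0, log(0.1), atanh(0.2), 0)
  apply_fix <- function(theta) {
    if (!is.null(fix_phi)) theta[4] <- atanh(fix_phi)
    if (!is.null(fix_delta)) theta[5] <- log(fix_delta)
    if (random == "intercept") { theta[2] <- 0; theta[3] <- log(1e-8) }
    theta
  }
  obj <- function(theta) {
    p <- theta_to_pars(apply_fix(theta))
    if (abs(p$phi) > 0.999) return(1e10)
    ll <- tryCatch(lme_profile(groups, p$Lambda, p$phi, p$delta, method)$loglik,
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  o1 <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
  o2 <- stats::optim(o1$par, obj, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-12), hessian = TRUE)
  opt <- if (o2$value <= o1$value) o2 else o1
  opt$par <- apply_fix(opt$par)
  pars <- theta_to_pars(opt$par)
  fin <- lme_profile(groups, pars$Lambda, pars$phi, pars$delta, method)
  vcov_beta <- fin$sigma2 * fin$cov_unscaled
  se <- sqrt(diag(vcov_beta))
  names(fin$beta) <- names(se) <- fixed_cols
  singular <- any(opt$par[c(1, 3)] < log(1e-5))
  theta_se <- tryCatch({
    dg <- diag(solve(o2$hessian))
    ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
  }, error = function(e) rep(NA_real_, 5))
  structure(list(beta = fin$beta, se = se, vcov_beta = vcov_beta,
                 G = fin$sigma2 * pars$Lambda, phi = pars$phi,
                 delta = pars$delta, sigma = sqrt(fin$sigma2),
                 loglik = fin$loglik, method = method, theta = opt$par,
                 theta_se = theta_se, n = fin$n, fixed_cols = fixed_cols,
                 singular = singular, converged = opt$convergence == 0,
                 design = design),
            class = "lme_fit")
}

# terms that must stay while `term` is retained (marginality)
lme_term_deps <- function(term) {
  if (term == "(Intercept)") return(character(0))
  if (grepl("^musth:", term)) {
    base <- sub("^musth:", "", term)
    deps <- c("musth", base)
    if (grepl("2$", base)) deps <- c(deps, paste0("musth:", sub("2$", "", base)))
    return(deps)
  }
  if (grepl("2$", term)) return(sub("2$", "", term))
  character(0)
}

droppable_terms <- function(active) {
  cand <- setdiff(active, "(Intercept)")
  keep_needed <- unique(unlist(lapply(cand, function(tm) {
    intersect(lme_term_deps(tm), active)
  })))
  setdiff(cand, keep_needed)
}

#' Backward model selection by likelihood-ratio tests
#'
#' Starting from the full ML fit, repeatedly refits without each currently
#' droppable term (marginality respected: a quadratic protects its linear
#' term, an interaction its main effects), removes the term with the
#' largest LRT p-value while that p-value is at least `alpha`, then refits
#' the selected model by REML.
#'
#' @param design An `lme_design`.
#' @param alpha Retention threshold.
#' @param fixed_cols Starting fixed-effect columns.
#' @param quiet Suppress progress messages.
#' @return List: `fit` (REML `lme_fit` of the selected model), `ml_fit`,
#'   `dropped` (data frame term, chisq, df, p in drop order), `lrt`
#'   (per-term LRTs of the retained droppable terms).
#' @export
select_model <- function(design, alpha = 0.05, fixed_cols = colnames(design$X),
                         quiet = TRUE) {
  active <- fixed_cols
  fit <- fit_lme(design, "ML", active)
  dropped <- data.frame(term = character(0), chisq = numeric(0),
                        df = integer(0), p = numeric(0), stringsAsFactors = FALSE)
  lrt_tab <- data.frame(term = character(0), chisq = numeric(0),
                        df = integer(0), p = numeric(0), stringsAsFactors = FALSE)
  repeat {
    cand <- droppable_terms(active)
    if (!length(cand)) break
    tests <- lapply(cand, function(tm) {
      red <- fit_lme(design, "ML", setdiff(active, tm), start = fit$theta)
      chisq <- max(0, 2 * (fit$loglik - red$loglik))
      list(term = tm, fit = red, chisq = chisq,
           p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
    })
    ps <- vapply(tests, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    if (ps[worst] < alpha) {
      lrt_tab <- data.frame(term = cand,
                            chisq = vapply(tests, `[[`, numeric(1), "chisq"),
                            df = 1L, p = ps, stringsAsFactors = FALSE)
      break
    }
    if (!quiet) message("dropping ", cand[worst], " (p = ",
                        signif(ps[worst], 3), ")")
    dropped <- rbind(dropped, data.frame(term = cand[worst],
                                         chisq = tests[[worst]]$chisq, df = 1L,
                                         p = ps[worst], stringsAsFactors = FALSE))
    active <- setdiff(active, cand[worst])
    fit <- tests[[worst]]$fit
  }
  reml <- fit_lme(design, "REML", active, start = fit$theta)
  list(fit = reml, ml_fit = fit, dropped = dropped, lrt = lrt_tab)
}

#' Diagnostic LRT for the per-individual NDVI random slope
#'
#' Compares the analysis model's random structure (intercept + NDVI
#' slope) against a random intercept only, by ML. The random structure of
#' the analysis model is fixed a priori; this test is reported as a
#' diagnostic, not used for selection. The null pins two parameters at a
#' boundary, so the nominal chi-square p-value (df = 2) is conservative.
#'
#' @param design An `lme_design`.
#' @param fixed_cols Fixed-effect columns.
#' @return List: chisq, df, p, and the two fits.
#' @export
random_slope_lrt <- function(design, fixed_cols = colnames(design$X)) {
  full <- fit_lme(design, "ML", fixed_cols)
  red <- fit_lme(design, "ML", fixed_cols, random = "intercept",
                 start = full$theta)
  chisq <- max(0, 2 * (full$loglik - red$loglik))
  list(chisq = chisq, df = 2,
       p = stats::pchisq(chisq, 2, lower.tail = FALSE),
       full = full, reduced = red)
}

#' Likelihood-ratio test between two nested ML fits
#'
#' @param full,reduced `lme_fit` objects fitted by ML.
#' @return List: chisq, df (difference in fixed-effect counts), p.
#' @export
lrt <- function(full, reduced) {
  stopifnot(full$method == "ML", reduced$method == "ML")
  df <- length(full$beta) - length(reduced$beta)
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

ratio_contrast <- function(fixed_cols, age, age_center = 35) {
  a <- age - age_center
  vals <- c("musth" = 1, "musth:age" = a, "musth:age2" = a^2)
  v <- stats::setNames(numeric(length(fixed_cols)), fixed_cols)
  for (nm in names(vals)) if (nm %in% fixed_cols) v[nm] <- vals[nm]
  v
}

#' Musth/non-musth response ratio at a given age
#'
#' The modelled multiplicative effect of musth on the response (speed or
#' MCP) for a bull of the given age under average environmental conditions
#' (standardized covariates at 0, outside protected areas):
#' exp(beta_musth + beta_musth:age (age - 35) + beta_musth:age2
#' (age - 35)^2). The confidence interval comes from a nonparametric
#' bootstrap resampling individuals with replacement and refitting.
#'
#' @param fit An `lme_fit` (REML) containing its design.
#' @param age Age(s) in years.
#' @param n_boot Bootstrap resamples (0 skips the CI).
#' @param level CI level.
#' @param seed Seed for resampling.
#' @return Data frame: age, ratio, lo, hi (CI columns NA when n_boot = 0).
#' @export
effect_ratio <- function(fit, age, n_boot = 1000, level = 0.95, seed = 1) {
  design <- fit$design
  obs_range <- range(design$X[, "age"]) + 35  # centred ages back to years
  if (any(age < obs_range[1] | age > obs_range[2])) {
    warning("age outside the observed range", call. = FALSE)
  }
  point <- vapply(age, function(a) {
    exp(sum(ratio_contrast(fit$fixed_cols, a) * fit$beta))
  }, numeric(1))
  out <- data.frame(age = age, ratio = point, lo = NA_real_, hi = NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    ng <- length(unique(design$group))
    ix_by_g <- split(seq_along(design$y), design$group)
    boot <- matrix(NA_real_, n_boot, length(age))
    for (b in seq_len(n_boot)) {
      gs <- sample.int(ng, ng, replace = TRUE)
      ix <- unlist(ix_by_g[gs], use.names = FALSE)
      newg <- rep(seq_along(gs), lengths(ix_by_g[gs]))
      bd <- structure(list(y = design$y[ix], X = design$X[ix, , drop = FALSE],
                           Z = design$Z[ix, , drop = FALSE], group = newg,
                           ids = as.character(seq_along(gs)),
                           day = design$day[ix], musth = design$musth[ix]),
                      class = "lme_design")
      bf <- tryCatch(fit_lme(bd, "REML", fit$fixed_cols, start = fit$theta),
                     error = function(e) NULL)
      if (!is.null(bf)) {
        boot[b, ] <- vapply(age, function(a) {
          exp(sum(ratio_contrast(bf$fixed_cols, a) * bf$beta))
        }, numeric(1))
      }
    }
    qs <- apply(boot, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    out$lo <- qs[1, ]; out$hi <- qs[2, ]
  }
  out
}

#' Simulate a daily analysis table from the mixed model
#'
#' Generates standardized covariates, contiguous musth bouts, random
#' intercept and NDVI slope per individual, and AR1 residuals with the
#' musth variance ratio, then returns a table ready for [build_design()].
#' Used for parameter-recovery checks.
#'
#' @param n_ind,n_days Individuals and days per individual.
#' @param beta Named fixed-effect vector (names from the 24-column order;
#'   absent terms are 0).
#' @param G 2x2 random-effects covariance.
#' @param phi,delta,sigma Residual parameters.
#' @param gap_rate Fraction of days removed to create AR1 gaps.
#' @param seed Seed.
#' @return Daily table (id, date, musth, age, covariates, mean_speed_kmh).
#' @export
simulate_lme_data <- function(n_ind = 30, n_days = 120, beta, G, phi = 0.3,
                              delta = 2, sigma = 0.2, gap_rate = 0.05,
                              seed = 1) {
  set.seed(seed)
  full_beta <- stats::setNames(numeric(24), lme_term_columns())
  full_beta[names(beta)] <- beta
  rows <- list()
  for (i in seq_len(n_ind)) {
    age_c <- sample(-15:15, 1)
    b <- drop(crossprod(chol(G + diag(1e-12, 2)), stats::rnorm(2)))
    ndvi <- as.numeric(stats::arima.sim(list(ar = 0.8), n_days, sd = 0.4))
    covs <- cbind(ndvi = ndvi, slope = stats::rnorm(n_days),
                  vrm = stats::rnorm(n_days), dist_water = stats::rnorm(n_days),
                  protected = stats::rbinom(n_days, 1, 0.7))
    musth <- rep(0, n_days)
    blen <- min(30L, max(5L, n_days %/% 3))
    s <- sample.int(n_days - blen, 1)
    musth[s:(s + blen - 1)] <- 1
    if (abs(phi) > 0) {
      z <- as.numeric(stats::arima.sim(list(ar = phi), n_days))
      z <- z * sqrt(1 - phi^2)  # unit marginal SD
    } else {
      z <- stats::rnorm(n_days)
    }
    eps <- sigma * ifelse(musth == 1, delta, 1) * z
    mains <- cbind(age = rep(age_c, n_days), age2 = age_c^2,
                   ndvi = covs[, "ndvi"], ndvi2 = covs[, "ndvi"]^2,
                   slope = covs[, "slope"], slope2 = covs[, "slope"]^2,
                   vrm = covs[, "vrm"], vrm2 = covs[, "vrm"]^2,
                   dist_water = covs[, "dist_water"],
                   dist_water2 = covs[, "dist_water"]^2,
                   protected = covs[, "protected"])
    X <- cbind(1, musth, mains, musth * mains)
    Zb <- b[1] + b[2] * covs[, "ndvi"]
    y <- drop(X %*% full_beta) + Zb + eps
    keep <- stats::runif(n_days) >= gap_rate
    rows[[i]] <- data.frame(id = sprintf("S%02d", i),
                            date = as.Date("2022-01-01") + seq_len(n_days) - 1,
                            musth = musth, age = age_c, ndvi = covs[, "ndvi"],
                            slope = covs[, "slope"], vrm = covs[, "vrm"],
                            dist_water = covs[, "dist_water"],
                            protected = covs[, "protected"],
                            mean_speed_kmh = exp(y),
                            stringsAsFactors = FALSE)[keep, ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
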