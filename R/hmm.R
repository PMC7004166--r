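# Ordered three-state Bayesian hidden Markov model for musth detection.
# The chain starts in state 1 (pre-musth), may advance once into state 2
# (musth: elevated log daily speed) and once more into state 3
# (post-musth); no other moves are possible, encoding a single bout per
# analysis window. Emissions are Gaussian on log daily mean speed (or log
# MCP), states are marginalised with the forward algorithm, and inference
# is by adaptive random-walk Metropolis MCMC.

#' Build an HMM analysis window for one individual
#'
#' Eligibility mirrors the study protocol: at least `min_obs` usable
#' (non-excluded) observations including one musth observation, then a
#' window of up to `half_width` days either side of the midpoint of the
#' musth-observation dates, truncated to data availability, with at least
#' `min_days` days and under `max_missing` missing daily values.
#'
#' @param metrics Daily metrics table for one individual (needs columns
#'   date and the response column).
#' @param observations Labelled observation table for the same individual.
#' @param response "speed" (log mean daily speed) or "mcp" (log 95% MCP).
#' @param min_obs,min_days,half_width,max_missing Eligibility parameters.
#' @return Object of class `hmm_window`: id, dates (daily sequence), y
#'   (log response, NA where the day is missing), midpoint.
#' @export
select_window <- function(metrics, observations, response = c("speed", "mcp"),
                          min_obs = 6, min_days = 120, half_width = 120,
                          max_missing = 0.1) {
  response <- match.arg(response)
  id <- metrics$id[1]
  obs <- observations[observations$id == id & observations$label != "excluded", ]
  if (nrow(obs) < min_obs) {
    stop(sprintf("%s ineligible: %d usable observations (< %d)", id, nrow(obs),
                 min_obs), call. = FALSE)
  }
  mdates <- obs$date[obs$label == "musth"]
  if (length(mdates) == 0L) {
    stop(sprintf("%s ineligible: no musth observation", id), call. = FALSE)
  }
  mid <- min(mdates) + floor(as.numeric(max(mdates) - min(mdates)) / 2)
  lo <- max(mid - half_width, min(metrics$date))
  hi <- min(mid + half_width, max(metrics$date))
  dates <- seq(lo, hi, by = "day")
  if (length(dates) < min_days) {
    stop(sprintf("%s ineligible: window of %d days (< %d)", id, length(dates),
                 min_days), call. = FALSE)
  }
  col <- if (response == "speed") "mean_speed_kmh" else "mcp95_km2"
  y <- log(metrics[[col]])[match(dates, metrics$date)]
  miss <- mean(is.na(y))
  if (miss >= max_missing) {
    stop(sprintf("%s ineligible: %.0f%% missing data (>= %.0f%%)", id,
                 100 * miss, 100 * max_missing), call. = FALSE)
  }
  structure(list(id = id, dates = dates, y = y, midpoint = mid,
                 response = response),
            class = "hmm_window")
}

#' Forward-algorithm log-likelihood of an HMM window
#'
#' Left-to-right transition structure, computed in log space; missing days
#' contribute transition-only steps.
#'
#' @param params List with `beta` (length 3 state means), `sigma` (length 3
#'   state SDs), `q1` = P(1 to 2) and `q2` = P(2 to 3) per day.
#' @param window An `hmm_window` (or any list with element `y`).
#' @return Log-likelihood.
#' @export
hmm_loglik <- function(params, window) {
  stopifnot(length(params$beta) == 3, length(params$sigma) == 3,
            all(params$sigma > 0), params$q1 > 0, params$q1 < 1,
            params$q2 > 0, params$q2 < 1)
  hmm_forward_cpp(as.numeric(window$y), params$beta, params$sigma,
                  params$q1, params$q2)
}

#' Default priors for the musth HMM
#'
#' Weakly informative, anchored on the window itself the way the original
#' analysis anchored its priors on the mixed-model estimates: state means
#' normal around the window median of y (SD 0.5), with the musth mean
#' offset upwards by 0.7 (about a doubling of speed) and softly ordered
#' above the flanking states; half-normal(0.5) state SDs; beta(1, 30)
#' daily transition probabilities (bouts are rare per day, lasting weeks).
#'
#' @param window An `hmm_window`.
#' @return List of prior hyperparameters.
#' @export
hmm_priors <- function(window) {
  list(m0 = stats::median(window$y, na.rm = TRUE),
       beta_sd = 0.5, beta2_offset = 0.7, sigma_scale = 0.5,
       q_shape1 = 1, q_shape2 = 30)
}

# theta (unconstrained emission block, length 6):
#   b1, b3, u (beta2 = max(b1, b3) + exp(u)), log sigma1..3
hmm_constrain <- function(theta) {
  b1 <- theta[1]; b3 <- theta[2]
  b2 <- max(b1, b3) + exp(theta[3])
  list(beta = c(b1, b2, b3), sigma = exp(theta[4:6]))
}

# log prior + marginal log-likelihood of the emission block, q held fixed
hmm_log_post <- function(theta, q1, q2, y, pr) {
  p <- hmm_constrain(theta)
  lp <- stats::dnorm(p$beta[1], pr$m0, pr$beta_sd, log = TRUE) +
    stats::dnorm(p$beta[3], pr$m0, pr$beta_sd, log = TRUE) +
    stats::dnorm(p$beta[2], pr$m0 + pr$beta2_offset, pr$beta_sd, log = TRUE) +
    theta[3] +                                    # Jacobian d beta2 / d u
    sum(log(2) + stats::dnorm(p$sigma, 0, pr$sigma_scale, log = TRUE) +
          theta[4:6])                             # half-normal + Jacobian
  if (!is.finite(lp)) return(-Inf)
  lp + hmm_forward_cpp(y, p$beta, p$sigma, q1, q2)
}

#' Split-chain Gelman-Rubin potential scale reduction
#'
#' @param draws Numeric matrix, iterations by chains.
#' @return R-hat scalar.
#' @export
rhat_split <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  x <- cbind(draws[seq_len(half), , drop = FALSE],
             draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x); nn <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Sample the HMM posterior by MCMC
#'
#' Metropolis-within-Gibbs: the six emission parameters (state means and
#' SDs, with states marginalised by the forward algorithm) move by
#' adaptive random-walk Metropolis, while the transition probabilities q1
#' and q2 are redrawn exactly from their Beta full conditionals given a
#' state path sampled by forward-filtering backward-sampling. Proposal
#' adaptation (targeting acceptance near 0.23) runs during warmup only,
#' so the retained draws form a valid Markov chain. The default
#' configuration (8 chains, 5,000 warmup and 5,000 sampling iterations)
#' retains 40,000 posterior samples; tests and desk-scale runs pass a
#' smaller configuration. Fully reproducible given `seed`.
#'
#' @param window An `hmm_window`.
#' @param priors Prior list from [hmm_priors()]; computed if NULL.
#' @param chains,warmup,iters MCMC configuration.
#' @param seed Integer seed.
#' @return Object of class `hmm_posterior`: `draws` (retained samples of
#'   beta1..3, sigma1..3, q1, q2, chains stacked), `rhat` per parameter,
#'   `converged` (all R-hat <= 1.1), `config`, `window`, `accept_rate`.
#' @export
sample_posterior <- function(window, priors = NULL, chains = 8, warmup = 5000,
                             iters = 5000, seed = 1) {
  if (is.null(priors)) priors <- hmm_priors(window)
  y <- as.numeric(window$y)
  set.seed(seed)
  npar <- 6L
  Tn <- length(y)
  sdy <- stats::sd(y, na.rm = TRUE)
  all_draws <- vector("list", chains)
  acc_rates <- numeric(chains)
  for (ch in seq_len(chains)) {
    theta <- c(priors$m0 + stats::rnorm(1, 0, 0.1),
               priors$m0 + stats::rnorm(1, 0, 0.1),
               log(priors$beta2_offset) + stats::rnorm(1, 0, 0.3),
               log(pmax(sdy, 0.05)) + stats::rnorm(3, 0, 0.2))
    q1 <- stats::rbeta(1, priors$q_shape1, priors$q_shape2)
    q2 <- stats::rbeta(1, priors$q_shape1, priors$q_shape2)
    lp <- hmm_log_post(theta, q1, q2, y, priors)
    scale <- 2.38 / sqrt(npar)
    L <- diag(0.1, npar)        # proposal Cholesky factor
    cw_scale <- rep(0.1, npar)  # componentwise proposal SDs
    hist_mat <- matrix(NA_real_, warmup, npar)
    draws <- matrix(NA_real_, iters, 8)
    n_acc <- 0L
    total <- warmup + iters
    for (it in seq_len(total)) {
      prop <- theta + scale * drop(L %*% stats::rnorm(npar))
      lp_prop <- hmm_log_post(prop, q1, q2, y, priors)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop
        if (it > warmup) n_acc <- n_acc + 1L
        acc <- 1
      } else acc <- 0
      # componentwise sweep sharpens mixing of weakly identified states
      for (j in seq_len(npar)) {
        prop <- theta
        prop[j] <- prop[j] + cw_scale[j] * stats::rnorm(1)
        lp_prop <- hmm_log_post(prop, q1, q2, y, priors)
        acc_j <- log(stats::runif(1)) < lp_prop - lp
        if (acc_j) { theta <- prop; lp <- lp_prop }
        if (it <= warmup) {
          cw_scale[j] <- exp(log(cw_scale[j]) + (as.numeric(acc_j) - 0.44) / sqrt(it))
        }
      }
      # conjugate refresh of the transition probabilities from an FFBS path
      p <- hmm_constrain(theta)
      path <- hmm_ffbs_cpp(y, p$beta, p$sigma, q1, q2, stats::runif(Tn))
      from1 <- path[-Tn] == 1L; from2 <- path[-Tn] == 2L
      n12 <- sum(from1 & path[-1] == 2L); n11 <- sum(from1) - n12
      n23 <- sum(from2 & path[-1] == 3L); n22 <- sum(from2) - n23
      q1 <- stats::rbeta(1, priors$q_shape1 + n12, priors$q_shape2 + n11)
      q2 <- stats::rbeta(1, priors$q_shape1 + n23, priors$q_shape2 + n22)
      q1 <- min(max(q1, 1e-12), 1 - 1e-12)
      q2 <- min(max(q2, 1e-12), 1 - 1e-12)
      lp <- hmm_log_post(theta, q1, q2, y, priors)
      if (it <= warmup) {
        hist_mat[it, ] <- theta
        scale <- exp(log(scale) + (acc - 0.234) / sqrt(it))
        if (it %% 250 == 0 && it >= 250) {
          cv <- stats::cov(hist_mat[max(1, it - 999):it, , drop = FALSE])
          L <- tryCatch(t(chol(cv + diag(1e-8, npar))), error = function(e) L)
        }
      } else {
        draws[it - warmup, ] <- c(p$beta, p$sigma, q1, q2)
      }
    }
    acc_rates[ch] <- n_acc / iters
    colnames(draws) <- c("beta1", "beta2", "beta3", "sigma1", "sigma2", "sigma3",
                         "q1", "q2")
    all_draws[[ch]] <- draws
  }
  pars <- colnames(all_draws[[1]])
  rhat <- vapply(pars, function(pn) {
    rhat_split(do.call(cbind, lapply(all_draws, function(d) d[, pn])))
  }, numeric(1))
  draws <- do.call(rbind, all_draws)
  structure(list(draws = draws, rhat = rhat, converged = all(rhat <= 1.1),
                 config = list(chains = chains, warmup = warmup, iters = iters,
                               seed = seed, retained = chains * iters),
                 accept_rate = acc_rates, window = window, priors = priors),
            class = "hmm_posterior")
}

#' Decode musth days from an HMM posterior
#'
#' Per-day P(state = 2) is the smoothed (forward-backward) state-2
#' marginal averaged over posterior draws; a day is assigned musth when
#' that probability exceeds `threshold`. Bout change-days are sampled per
#' draw by forward-filtering backward-sampling: tau1 = first state-2 day,
#' tau2 = last; the duration SD is the SD of (tau2 - tau1 + 1) over draws
#' (0 days for paths without a bout).
#'
#' @param posterior An `hmm_posterior`.
#' @param n_draws Number of posterior draws used (subsampled evenly).
#' @param threshold Assignment threshold on P(state = 2).
#' @param seed Seed for the path sampling.
#' @return List: `decode` (data frame date, p_state2, assigned), `tau1`,
#'   `tau2` (posterior draws, NA when no bout), `interval` (first/last
#'   assigned date or NA), `duration_sd`, `duration_mean`.
#' @export
decode_states <- function(posterior, n_draws = 1000, threshold = 0.5, seed = 1) {
  w <- posterior$window
  y <- as.numeric(w$y)
  Tn <- length(y)
  d <- posterior$draws
  n_draws <- min(n_draws, nrow(d))
  ix <- unique(round(seq(1, nrow(d), length.out = n_draws)))
  set.seed(seed)
  p2 <- numeric(Tn)
  tau1 <- tau2 <- rep(NA_real_, length(ix))
  dur <- numeric(length(ix))
  for (k in seq_along(ix)) {
    th <- d[ix[k], ]
    beta <- th[1:3]; sigma <- th[4:6]; q1 <- th[7]; q2 <- th[8]
    p2 <- p2 + hmm_smooth_cpp(y, beta, sigma, q1, q2)[, 2]
    path <- hmm_ffbs_cpp(y, beta, sigma, q1, q2, stats::runif(Tn))
    in2 <- which(path == 2L)
    if (length(in2)) {
      tau1[k] <- in2[1]; tau2[k] <- in2[length(in2)]
      dur[k] <- in2[length(in2)] - in2[1] + 1
    } else dur[k] <- 0
  }
  p2 <- p2 / length(ix)
  assigned <- p2 > threshold
  interval <- if (any(assigned)) {
    c(w$dates[which(assigned)[1]], w$dates[max(which(assigned))])
  } else as.Date(c(NA, NA))
  list(decode = data.frame(date = w$dates, p_state2 = p2, assigned = assigned),
       tau1 = tau1, tau2 = tau2, interval = interval,
       duration_sd = stats::sd(dur), duration_mean = mean(dur))
}

#' Posterior predictive checks of an HMM fit
#'
#' For each posterior draw, a state path is sampled and a replicated
#' series simulated from the emission model; the report gives the quantile
#' of the observed statistic (mean, max, lag-1 autocorrelation of y)
#' within the replicated distribution. Quantiles near 0 or 1 flag misfit.
#'
#' @param posterior An `hmm_posterior`.
#' @param n_draws Number of draws used.
#' @param seed Seed.
#' @return List with per-statistic observed value, replicate quantile, and
#'   the replicate draws.
#' @export
posterior_predictive_check <- function(posterior, n_draws = 500, seed = 1) {
  w <- posterior$window
  y <- as.numeric(w$y)
  obs_ix <- which(!is.na(y))
  yo <- y[obs_ix]
  lag1 <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(v[-length(v)], v[-1])
  }
  obs <- c(mean = mean(yo), max = max(yo), lag1_acf = lag1(yo))
  d <- posterior$draws
  ix <- unique(round(seq(1, nrow(d), length.out = min(n_draws, nrow(d)))))
  set.seed(seed)
  reps <- matrix(NA_real_, length(ix), 3,
                 dimnames = list(NULL, names(obs)))
  Tn <- length(y)
  for (k in seq_along(ix)) {
    th <- d[ix[k], ]
    path <- hmm_ffbs_cpp(y, th[1:3], th[4:6], th[7], th[8], stats::runif(Tn))
    yr <- stats::rnorm(length(obs_ix), th[1:3][path[obs_ix]],
                       th[4:6][path[obs_ix]])
    reps[k, ] <- c(mean(yr), max(yr), lag1(yr))
  }
  quant <- vapply(names(obs), function(s) {
    r <- reps[, s]; r <- r[!is.na(r)]
    (sum(r < obs[[s]]) + 0.5 * sum(r == obs[[s]])) / length(r)
  }, numeric(1))
  list(observed = obs, quantile = quant, replicates = reps)
}
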