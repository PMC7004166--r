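# Track regularisation: snap fixes to the top of the hour, fit a
# continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
# velocity model) per individual, interpolate short gaps with the Kalman
# smoother, and flag which days are analysable.

#' Down-sample a track to hourly fixes on the hour
#'
#' For every top-of-hour instant, the nearest fix within the snap tolerance
#' is kept (ties broken towards the earlier fix) and its timestamp snapped
#' to the exact hour; all other fixes are dropped. Hours with no fix inside
#' the tolerance become gaps -- nothing is fabricated. Tracks already
#' sampled hourly on the hour pass through unchanged.
#'
#' @param track Track data frame (id, timestamp, lat, lon, interpolated).
#' @param snap_tolerance_min Half-width of the snap window in minutes.
#' @return Track data frame with on-the-hour timestamps.
#' @export
downsample_hourly <- function(track, snap_tolerance_min = 5) {
  secs <- as.numeric(track$timestamp)
  hour <- round(secs / 3600) * 3600
  off <- abs(secs - hour)
  keep <- off <= snap_tolerance_min * 60
  tr <- track[keep, , drop = FALSE]
  if (nrow(tr) == 0L) return(tr)
  hour <- hour[keep]; off <- off[keep]
  o <- order(hour, off, tr$timestamp)  # tie on offset -> earlier fix wins
  best <- rep(FALSE, nrow(tr))
  best[o[!duplicated(hour[o])]] <- TRUE
  tr <- tr[best, , drop = FALSE]
  tr$timestamp <- as.POSIXct(hour[best], origin = "1970-01-01", tz = "UTC")
  rownames(tr) <- NULL
  tr
}

# Discrete-time transition of the integrated-OU model over dt hours.
# beta = velocity mean-reversion rate (1/h), sigv = stationary velocity SD
# (km/h). State is (position, velocity).
iou_discretize <- function(beta, sigv, dt) {
  e <- exp(-beta * dt)
  F <- matrix(c(1, 0, (1 - e) / beta, e), 2, 2)
  s2 <- sigv^2
  Q <- matrix(c(
    s2 * (2 * dt / beta - (3 - 4 * e + e^2) / beta^2),
    s2 * (1 - e)^2 / beta,
    s2 * (1 - e)^2 / beta,
    s2 * (1 - e^2)), 2, 2)
  list(F = F, Q = Q)
}

# Kalman filter for one axis of the integrated-OU model with exact (zero
# measurement error) position observations. times in hours, strictly
# increasing; obs_mask marks which grid points carry an observation.
# Conditions on the first observation (position known, velocity
# stationary). Returns the log-likelihood of the remaining observations
# and, if smooth = TRUE, RTS-smoothed position means at every grid point.
iou_kalman <- function(y, times, obs_mask, beta, sigv, smooth = FALSE) {
  n <- length(times)
  first <- which(obs_mask)[1]
  m <- c(y[first], 0)
  P <- matrix(c(0, 0, 0, sigv^2), 2, 2)
  ll <- 0
  if (smooth) {
    mp_s <- matrix(NA_real_, n, 2); Pp_s <- vector("list", n)
    mf_s <- matrix(NA_real_, n, 2); Pf_s <- vector("list", n)
    Fs <- vector("list", n)
    mf_s[first, ] <- m; Pf_s[[first]] <- P
  }
  if (n > first) {
    for (t in (first + 1L):n) {
      d <- iou_discretize(beta, sigv, times[t] - times[t - 1])
      m <- drop(d$F %*% m)
      P <- d$F %*% P %*% t(d$F) + d$Q
      if (smooth) { mp_s[t, ] <- m; Pp_s[[t]] <- P; Fs[[t]] <- d$F }
      if (obs_mask[t]) {
        S <- P[1, 1]
        resid <- y[t] - m[1]
        ll <- ll + stats::dnorm(resid, 0, sqrt(S), log = TRUE)
        K <- P[, 1] / S
        m <- m + K * resid
        P <- P - outer(K, P[1, ])
        P <- (P + t(P)) / 2
      }
      if (smooth) { mf_s[t, ] <- m; Pf_s[[t]] <- P }
    }
  }
  out <- list(loglik = ll)
  if (smooth && n > first) {
    ms <- mf_s
    for (t in (n - 1L):first) {
      Ppred <- Pp_s[[t + 1]]
      G <- Pf_s[[t]] %*% t(Fs[[t + 1]]) %*% solve(Ppred)
      ms[t, ] <- mf_s[t, ] + drop(G %*% (ms[t + 1, ] - mp_s[t + 1, ]))
    }
    out$smoothed_pos <- ms[, 1]
  }
  out
}

#' Fit the continuous-time correlated random walk to a track
#'
#' Maximum-likelihood fit of the integrated Ornstein-Uhlenbeck velocity
#' model, applied independently to the two coordinates of a local
#' azimuthal-equidistant projection centred on the track centroid, with
#' parameters (mean-reversion rate, stationary velocity SD) shared between
#' axes and GPS measurement error fixed at zero.
#'
#' @param track Track data frame.
#' @param center Optional projection centre c(lat, lon); defaults to the
#'   track centroid.
#' @return List of class `ctcrw_fit`: `beta` (1/h), `sigma_v` (km/h),
#'   `loglik`, `center`, `converged`, `boundary` (TRUE when the optimum sat
#'   on a parameter bound, e.g. a constant-position track driving the
#'   velocity SD to zero), and asymptotic `se` on the log parameters.
#' @export
fit_ctcrw <- function(track, center = NULL) {
  if (nrow(track) < 48) stop("fit_ctcrw needs >= 48 fixes", call. = FALSE)
  if (is.null(center)) center <- c(mean(track$lat), mean(track$lon))
  xy <- aeqd_project(track$lat, track$lon, center)
  times <- as.numeric(track$timestamp - track$timestamp[1], units = "hours")
  mask <- rep(TRUE, length(times))
  lims <- c(-10, 6)
  nll <- function(p) {
    beta <- exp(p[1]); sigv <- exp(p[2])
    -(iou_kalman(xy$x, times, mask, beta, sigv)$loglik +
      iou_kalman(xy$y, times, mask, beta, sigv)$loglik)
  }
  opt <- stats::optim(c(log(0.5), log(0.3)), nll, method = "L-BFGS-B",
                      lower = lims[1], upper = lims[2], hessian = TRUE)
  boundary <- any(abs(opt$par - lims[1]) < 1e-6 | abs(opt$par - lims[2]) < 1e-6)
  se <- tryCatch({
    dg <- diag(solve(opt$hessian))
    ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
  }, error = function(e) rep(NA_real_, 2))
  structure(list(beta = exp(opt$par[1]), sigma_v = exp(opt$par[2]),
                 loglik = -opt$value, center = center,
                 converged = opt$convergence == 0, boundary = boundary,
                 se_log = se),
            class = "ctcrw_fit")
}

#' Log-likelihood of one projected axis under the fitted CTCRW
#'
#' Exposed for verification against direct dense-covariance computation of
#' the integrated-OU Gaussian process.
#'
#' @param y Positions (km) at `times`.
#' @param times Hours, strictly increasing.
#' @param beta,sigma_v Model parameters.
#' @return Log-likelihood of y[-1] given y[1].
#' @export
ctcrw_axis_loglik <- function(y, times, beta, sigma_v) {
  iou_kalman(y, times, rep(TRUE, length(y)), beta, sigma_v)$loglik
}

#' Interpolate short gaps in an hourly track
#'
#' Missing top-of-hour instants inside gaps of at most `max_gap_hours` are
#' filled with Kalman-smoothed CTCRW positions (flagged `interpolated`);
#' longer gaps are left open. Observed fixes are never altered. When no
#' usable fit is supplied (or `fallback_linear` forces it), positions are
#' interpolated linearly in the projected plane instead.
#'
#' @param track Hourly on-the-hour track data frame.
#' @param fit A `ctcrw_fit`, or NULL for the linear fallback.
#' @param max_gap_hours Longest gap (h) that will be filled.
#' @param fallback_linear Use straight-line interpolation regardless of fit.
#' @return Track data frame with inserted fixes, sorted by time.
#' @export
interpolate_gaps <- function(track, fit = NULL, max_gap_hours = 4,
                             fallback_linear = FALSE) {
  n <- nrow(track)
  if (n < 2L) return(track)
  secs <- as.numeric(track$timestamp)
  stopifnot(all(secs %% 3600 == 0))
  gaps_h <- diff(secs) / 3600
  fill_after <- which(gaps_h > 1 & gaps_h <= max_gap_hours)
  if (!length(fill_after)) return(track)
  miss_secs <- unlist(lapply(fill_after, function(i) {
    seq(secs[i] + 3600, secs[i + 1] - 3600, by = 3600)
  }))
  center <- if (!is.null(fit)) fit$center else c(mean(track$lat), mean(track$lon))
  xy <- aeqd_project(track$lat, track$lon, center)
  use_linear <- fallback_linear || is.null(fit) || !fit$converged || fit$boundary
  if (use_linear) {
    px <- stats::approx(secs, xy$x, xout = miss_secs)$y
    py <- stats::approx(secs, xy$y, xout = miss_secs)$y
  } else {
    all_secs <- sort(c(secs, miss_secs))
    times <- (all_secs - secs[1]) / 3600
    mask <- all_secs %in% secs
    yx <- rep(NA_real_, length(all_secs)); yx[mask] <- xy$x
    yy <- rep(NA_real_, length(all_secs)); yy[mask] <- xy$y
    px <- iou_kalman(yx, times, mask, fit$beta, fit$sigma_v, smooth = TRUE)$smoothed_pos
    py <- iou_kalman(yy, times, mask, fit$beta, fit$sigma_v, smooth = TRUE)$smoothed_pos
    px <- px[!mask]; py <- py[!mask]
  }
  ll <- aeqd_inverse(px, py, center)
  ins <- data.frame(id = track$id[1],
                    timestamp = as.POSIXct(miss_secs, origin = "1970-01-01", tz = "UTC"),
                    lat = ll$lat, lon = ll$lon, interpolated = TRUE,
                    stringsAsFactors = FALSE)
  out <- rbind(track, ins)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Day-level quality control of a regularised track
#'
#' A calendar day (study-site time, UTC+3) is analysable when its largest
#' data gap is at most `max_gap_hours` and it carries at least
#' `min_fixes` hourly fixes; interpolated fixes count. The gap for a day
#' includes the lead-in from local midnight to its first fix and the
#' tail-out from its last fix to the following midnight, so missing edge
#' hours are counted against the day.
#'
#' @param track Hourly track data frame (observed + interpolated fixes).
#' @param max_gap_hours Gap threshold in hours.
#' @param min_fixes Minimum number of fixes per day.
#' @return Data frame: id, date, n_fixes, max_gap_h, included.
#' @export
qc_days <- function(track, max_gap_hours = 4, min_fixes = 20) {
  d <- fix_date(track$timestamp)
  secs <- as.numeric(track$timestamp)
  res <- lapply(split(seq_along(d), d), function(ix) {
    day_start <- as.numeric(as.POSIXct(paste(d[ix[1]], "00:00:00"), tz = STUDY_TZ))
    s <- secs[ix]
    gaps <- c(s[1] - day_start, diff(s), day_start + 86400 - s[length(s)]) / 3600
    data.frame(id = track$id[ix[1]], date = d[ix[1]], n_fixes = length(ix),
               max_gap_h = max(gaps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$included <- out$max_gap_h <= max_gap_hours & out$n_fixes >= min_fixes
  rownames(out) <- NULL
  out
}

#' Regularise one raw track end to end
#'
#' Down-sample to the hour, fit the CTCRW (falling back to linear
#' interpolation when too few fixes or a degenerate fit), fill gaps up to
#' `max_gap_hours`, and QC the days.
#'
#' @param track Raw track data frame.
#' @inheritParams downsample_hourly
#' @inheritParams interpolate_gaps
#' @inheritParams qc_days
#' @return List: `track` (regularised fixes), `qc` (day table), `fit`
#'   (the `ctcrw_fit` or NULL).
#' @export
regularize_track <- function(track, snap_tolerance_min = 5, max_gap_hours = 4,
                             min_fixes = 20) {
  tr <- downsample_hourly(track, snap_tolerance_min)
  fit <- if (nrow(tr) >= 48) tryCatch(fit_ctcrw(tr), error = function(e) NULL) else NULL
  tr <- interpolate_gaps(tr, fit, max_gap_hours = max_gap_hours)
  list(track = tr, qc = qc_days(tr, max_gap_hours, min_fixes), fit = fit)
}
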