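# Synthetic study system: covariate fields, elephant-like hourly GPS
# tracks with age-structured musth bouts, and a sighting process with
# ground truth. Emulates the statistical structure the downstream models
# assume -- state-shifted lognormal daily speed with AR1 day-to-day noise
# and per-individual random effects -- so every pipeline stage can be
# exercised against known truth.

#' Default simulation configuration
#'
#' Defaults encode the study conditions: musth multiplies mean daily speed
#' by 2.14 and its speed-scale SD by 2.11; bulls of 35+ years express one
#' long annual bout (~60 days) while younger bulls express several short
#' (~2 week) bouts; day-to-day log-speed noise is AR1 with a ~20%
#' coefficient of variation; baseline non-musth speed is 0.3 km/h at age
#' 35 with a mild decreasing age trend.
#'
#' @param n_individuals Number of bulls.
#' @param ages Integer ages (years) at simulation start; recycled.
#' @param n_days Days simulated per bull.
#' @param start_date First simulated day.
#' @param seed Integer seed driving every stochastic element.
#' @param ... Overrides for any default listed below.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 6, ages = c(25, 30, 32, 38, 42, 47),
                       n_days = 240, start_date = as.Date("2022-01-01"),
                       seed = 1, ...) {
  cfg <- list(
    n_individuals = n_individuals,
    ages = rep_len(ages, n_individuals),
    n_days = n_days,
    start_date = as.Date(start_date),
    seed = seed,
    base_speed_kmh = 0.3,       # non-musth mean daily speed at age 35
    age_slope_log = -0.005,     # per-year non-musth trend on log speed
    musth_speed_mult = 2.14,    # multiplier on mean daily speed in musth
    musth_sd_mult = 2.11,       # multiplier on speed-scale SD in musth
    sigma_log = 0.19,           # non-musth day-to-day log-speed SD
    phi = 0.3,                  # AR1 of daily residuals
    re_intercept_sd = 0.15,     # per-individual log-speed intercept SD
    re_ndvi_sd = 0.05,          # per-individual NDVI slope SD
    ndvi_coef = 0.1,            # population log-speed response to NDVI
    bout_long_days = 60, bout_long_sd = 8,    # 35+ bulls, once a year
    bout_short_days = 14, bout_short_sd = 3,  # under-35 bulls
    bouts_per_year_young = 3,
    sighting_rate = 0.08,       # per-day observation probability
    one_signal_frac = 0.05,     # sightings downgraded to 1 ambiguous signal
    missing_fix_rate = 0.02,    # hourly fixes dropped at random
    missing_day_rate = 0.02,    # whole days dropped
    center = c(0.55, 37.5),     # study-area centre (lat, lon)
    grid_n = 120,               # covariate grid cells per side
    grid_cell_deg = 0.005
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  cfg$ages <- rep_len(cfg$ages, cfg$n_individuals)
  structure(cfg, class = "sim_config")
}

# musth-state log-scale SD that yields the configured speed-scale SD
# multiplier given the mean multiplier, via lognormal CV algebra
musth_sigma_log <- function(cfg) {
  cv1 <- sqrt(exp(cfg$sigma_log^2) - 1)
  cv2 <- cv1 * cfg$musth_sd_mult / cfg$musth_speed_mult
  sqrt(log(1 + cv2^2))
}

# smooth random field: sum of Gaussian bumps over a unit grid
smooth_field <- function(n, k = 25, width = c(0.1, 0.3), amp = 1) {
  u <- (seq_len(n) - 0.5) / n
  f <- matrix(0, n, n)
  cx <- stats::runif(k); cy <- stats::runif(k)
  w <- stats::runif(k, width[1], width[2])
  a <- stats::rnorm(k, 0, amp)
  for (b in seq_len(k)) {
    f <- f + a[b] * outer(exp(-(u - cy[b])^2 / (2 * w[b]^2)),
                          exp(-(u - cx[b])^2 / (2 * w[b]^2)))
  }
  f
}

#' Generate a synthetic covariate stack
#'
#' A smooth random elevation field (so slope and ruggedness are
#' non-trivial), seasonal sinusoidal NDVI composites at 16-day cadence
#' spanning the simulated dates without gaps, one meandering river
#' polyline and one rectangular protected area. Deterministic per seed.
#'
#' @param cfg A `sim_config`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A `cov_stack`.
#' @export
make_environment <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$grid_n; cs <- cfg$grid_cell_deg
  xll <- cfg$center[2] - n * cs / 2
  yll <- cfg$center[1] - n * cs / 2
  elev <- cov_grid(600 + 120 * smooth_field(n) +
                     40 * outer(seq_len(n) / n, rep(1, n)), xll, yll, cs)
  ndvi_base <- 0.15 * smooth_field(n, k = 15)
  starts <- seq(cfg$start_date - 16, cfg$start_date + cfg$n_days + 16, by = 16)
  ndvi <- lapply(starts, function(s) {
    doy <- as.integer(format(s + 8, "%j"))
    season <- 0.25 + 0.2 * sin(2 * pi * doy / 365)
    g <- pmin(pmax(ndvi_base + season, -1), 1)
    list(start = s, grid = cov_grid(g, xll, yll, cs))
  })
  tlon <- seq(xll, xll + n * cs, length.out = 40)
  river <- cbind(tlon, cfg$center[1] + 0.15 * n * cs * sin(seq(0, 3 * pi, length.out = 40)) / 3)
  span <- n * cs
  pa <- cbind(c(xll + 0.15 * span, xll + 0.7 * span, xll + 0.7 * span,
                xll + 0.15 * span, xll + 0.15 * span),
              c(yll + 0.2 * span, yll + 0.2 * span, yll + 0.8 * span,
                yll + 0.8 * span, yll + 0.2 * span))
  cov_stack(elev, ndvi, water = list(river), protected = list(pa))
}

# schedule contiguous musth bouts for one bull over n_days
schedule_bouts <- function(age, n_days, cfg) {
  state <- rep(FALSE, n_days)
  years <- ceiling(n_days / 365)
  if (age >= 35) {
    n_bouts <- years
    durs <- pmax(14, round(stats::rnorm(n_bouts, cfg$bout_long_days, cfg$bout_long_sd)))
  } else {
    n_bouts <- cfg$bouts_per_year_young * years
    durs <- pmax(4, round(stats::rnorm(n_bouts, cfg$bout_short_days, cfg$bout_short_sd)))
  }
  for (b in seq_len(n_bouts)) {
    for (try in 1:50) {
      s <- sample.int(max(1, n_days - durs[b] - 20), 1) + 10
      e <- min(n_days, s + durs[b] - 1)
      buf <- max(1, s - 10):min(n_days, e + 10)
      if (!any(state[buf])) { state[s:e] <- TRUE; break }
    }
  }
  state
}

#' Simulate hourly GPS tracks with known musth ground truth
#'
#' Each bull gets a daily log-speed level built from baseline, age trend,
#' individual random intercept, NDVI response with an individual random
#' slope, the musth multiplier on musth days, and mean-one AR1 lognormal
#' noise. The 24 hourly steps of each day form a correlated random walk on
#' the projected plane whose step lengths are rescaled so the day's mean
#' speed equals the generated level exactly; positions are inverse-projected
#' to WGS84 so the haversine geometry downstream is honest. Steps are
#' assigned the scale of the day in which they end, matching the daily
#' speed convention.
#'
#' @param cfg A `sim_config`.
#' @param stack Optional `cov_stack` for the NDVI covariate signal; when
#'   NULL a pure seasonal sinusoid is used.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return List: `tracks` (a `track_set`), `truth` (data frame id, date,
#'   state, day_speed_kmh, age_years), `params` (generative parameter
#'   list, including the per-state log-scale SDs).
#' @export
simulate_tracks <- function(cfg = sim_config(), stack = NULL, seed = cfg$seed) {
  set.seed(seed)
  sig1 <- cfg$sigma_log
  sig2 <- musth_sigma_log(cfg)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  ndvi_season <- 0.25 + 0.2 * sin(2 * pi * doy / 365)
  ndvi_c <- ndvi_season - mean(ndvi_season)
  ids <- sprintf("B%03d", seq_len(cfg$n_individuals))
  tracks <- list()
  truth <- list()
  span_km <- cfg$grid_n * cfg$grid_cell_deg * 111 / 2  # half-extent, approx
  for (i in seq_len(cfg$n_individuals)) {
    age <- cfg$ages[i]
    b0 <- stats::rnorm(1, 0, cfg$re_intercept_sd)
    b1 <- stats::rnorm(1, 0, cfg$re_ndvi_sd)
    musth <- schedule_bouts(age, cfg$n_days, cfg)
    sig_d <- ifelse(musth, sig2, sig1)
    z <- numeric(cfg$n_days)
    z[1] <- stats::rnorm(1)
    for (d in 2:cfg$n_days) {
      z[d] <- cfg$phi * z[d - 1] + stats::rnorm(1, 0, sqrt(1 - cfg$phi^2))
    }
    eta <- sig_d * z
    mu <- log(cfg$base_speed_kmh) + cfg$age_slope_log * (age - 35) + b0 +
      (cfg$ndvi_coef + b1) * ndvi_c + log(cfg$musth_speed_mult) * musth
    speed <- exp(mu + eta - sig_d^2 / 2)
    # hourly correlated walk; step ending at local hour h of day d has day
    # d's scale; soft attraction keeps the bull inside the study extent
    n_steps <- cfg$n_days * 24
    day_of_step <- rep(seq_len(cfg$n_days), each = 24)
    raw <- stats::rgamma(n_steps, shape = 4, rate = 4)
    len <- raw
    for (d in seq_len(cfg$n_days)) {
      ix <- which(day_of_step == d)
      if (d == 1) ix <- ix[-1]  # first fix anchors the track, no step
      len[ix] <- raw[ix] * speed[d] / mean(raw[ix])
    }
    heading <- numeric(n_steps)
    heading[1] <- stats::runif(1, -pi, pi)
    turn <- stats::rnorm(n_steps, 0, 0.8)
    x <- numeric(n_steps); y <- numeric(n_steps)
    x[1] <- stats::runif(1, -0.3, 0.3) * span_km
    y[1] <- stats::runif(1, -0.3, 0.3) * span_km
    for (s in 2:n_steps) {
      heading[s] <- heading[s - 1] + turn[s]
      r <- sqrt(x[s - 1]^2 + y[s - 1]^2)
      if (r > 0.7 * span_km) {  # steer home
        heading[s] <- atan2(-y[s - 1], -x[s - 1]) + stats::rnorm(1, 0, 0.3)
      }
      x[s] <- x[s - 1] + len[s] * cos(heading[s])
      y[s] <- y[s - 1] + len[s] * sin(heading[s])
    }
    ll <- aeqd_inverse(x, y, cfg$center)
    # local hour h of day d; local midnight is 21:00 UTC of the prior day
    t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = STUDY_TZ)
    ts <- t0 + ((day_of_step - 1) * 24 + rep(0:23, cfg$n_days)) * 3600
    attr(ts, "tzone") <- "UTC"
    keep <- stats::runif(n_steps) >= cfg$missing_fix_rate
    drop_day <- stats::runif(cfg$n_days) < cfg$missing_day_rate
    keep <- keep & !drop_day[day_of_step]
    tr <- data.frame(id = ids[i], timestamp = ts[keep], lat = ll$lat[keep],
                     lon = ll$lon[keep], interpolated = FALSE,
                     stringsAsFactors = FALSE)
    tracks[[ids[i]]] <- tr
    truth[[i]] <- data.frame(id = ids[i], date = dates,
                             state = ifelse(musth, "musth", "non_musth"),
                             day_speed_kmh = speed, age_years = age,
                             stringsAsFactors = FALSE)
  }
  list(tracks = structure(tracks, class = "track_set"),
       truth = do.call(rbind, truth),
       params = list(sigma_log_nonmusth = sig1, sigma_log_musth = sig2,
                     musth_speed_mult = cfg$musth_speed_mult,
                     base_speed_kmh = cfg$base_speed_kmh))
}

#' Simulate field sightings from ground truth
#'
#' Each individual-day is sighted independently with probability `rate`;
#' sighted musth days display 2-3 musth signals and non-musth days 0,
#' except that a configurable fraction of sightings is downgraded to a
#' single ambiguous signal to exercise the exclusion rule.
#'
#' @param truth Ground-truth table from [simulate_tracks()].
#' @param rate Per-day sighting probability.
#' @param one_signal_frac Fraction of sightings reporting one signal only.
#' @param seed Seed.
#' @return Raw observation data frame (id, date, n_signals).
#' @export
simulate_observations <- function(truth, rate = 0.08, one_signal_frac = 0.05,
                                  seed = 1) {
  set.seed(seed)
  seen <- stats::runif(nrow(truth)) < rate
  obs <- truth[seen, c("id", "date", "state")]
  n <- nrow(obs)
  obs$n_signals <- ifelse(obs$state == "musth", sample(2:3, n, replace = TRUE), 0L)
  one <- stats::runif(n) < one_signal_frac
  obs$n_signals[one] <- 1L
  obs$state <- NULL
  rownames(obs) <- NULL
  obs
}
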