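# Shared fixture builders (everything generated in code).

# hourly track: n fixes on consecutive hours from a given start, moving
# east by step_km each hour
make_hourly_track <- function(n = 24, start = "2022-03-01 00:00:00",
                              step_km = 0.5, lat0 = 0.5, lon0 = 37.5,
                              id = "T1") {
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)
  dlon <- step_km / (EARTH_RADIUS_KM * pi / 180 * cos(lat0 * pi / 180))
  data.frame(id = id, timestamp = ts, lat = lat0,
             lon = lon0 + dlon * (seq_len(n) - 1), interpolated = FALSE,
             stringsAsFactors = FALSE)
}

# a synthetic HMM window with one bout of elevated log speed
make_hmm_window <- function(seed, T = 240, s1 = 0.19, sep = 4,
                            bout = c(100, 160), missing_frac = 0.05,
                            mu1 = -1.2) {
  set.seed(seed)
  st <- rep(1L, T)
  st[bout[1]:bout[2]] <- 2L
  if (bout[2] < T) st[(bout[2] + 1):T] <- 3L
  mu <- c(mu1, mu1 + sep * s1, mu1)
  y <- rnorm(T, mu[st], s1)
  if (missing_frac > 0) y[sample(T, round(missing_frac * T))] <- NA
  structure(list(id = "SYN", dates = as.Date("2022-01-01") + 0:(T - 1), y = y,
                 midpoint = as.Date("2022-01-01") + floor(mean(bout)),
                 response = "speed"),
            class = "hmm_window")
}

# quick scaled-down posterior for tests
quick_posterior <- function(window, seed = 1, chains = 4, warmup = 1000,
                            iters = 1000) {
  sample_posterior(window, chains = chains, warmup = warmup, iters = iters,
                   seed = seed)
}
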