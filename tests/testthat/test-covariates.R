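flat_grid <- function(n = 12, value = 500, cellsize = 0.001) {
  cov_grid(matrix(value, n, n), 37.0, 0.2, cellsize)
}

test_that("Horn slope reproduces analytic planes", {
  g <- flat_grid()
  expect_true(all(slope_deg(g)$values == 0))

  # plane rising east at tan(30 deg): interior slope 30 degrees
  n <- 15
  g2 <- flat_grid(n)
  dx <- musthmove:::grid_cell_metres(g2)["dx"]
  g2$values <- outer(rep(1, n), seq_len(n)) * dx * tan(30 * pi / 180)
  sl <- slope_deg(g2)$values[2:(n - 1), 2:(n - 1)]
  expect_equal(max(abs(sl - 30)), 0, tolerance = 1e-6)

  # plane z = x + y (metre units): interior slope atan(sqrt(2))
  g3 <- flat_grid(n)
  dy <- musthmove:::grid_cell_metres(g3)["dy"]
  g3$values <- outer(seq_len(n) * dy, seq_len(n) * dx, "+")
  sl3 <- slope_deg(g3)$values[2:(n - 1), 2:(n - 1)]
  expect_equal(max(abs(sl3 - atan(sqrt(2)) * 180 / pi)), 0, tolerance = 1e-4)
})

test_that("VRM is 0 on flat and uniformly inclined terrain, matches the vector-sum oracle", {
  g <- flat_grid()
  expect_true(all(vrm(g)$values == 0))

  n <- 15
  g2 <- flat_grid(n)
  dx <- musthmove:::grid_cell_metres(g2)["dx"]
  g2$values <- outer(rep(1, n), seq_len(n)) * dx * 0.5
  # strict interior: windows must not touch edge-padded gradient cells
  v <- vrm(g2)$values[3:(n - 2), 3:(n - 2)]
  expect_equal(max(abs(v)), 0, tolerance = 1e-10)

  # egg-carton surface against the direct vector-sum oracle
  set.seed(10)
  g3 <- flat_grid(n)
  u <- seq_len(n)
  g3$values <- 50 * outer(sin(u / 1.5), cos(u / 1.7))
  gr <- musthmove:::horn_gradient(g3)
  slope <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2)); aspect <- atan2(gr$dzdy, gr$dzdx)
  xn <- sin(slope) * cos(aspect); yn <- sin(slope) * sin(aspect); zn <- cos(slope)
  v3 <- vrm(g3)
  for (k in 1:20) {
    i <- sample(2:(n - 1), 1); j <- sample(2:(n - 1), 1)
    expect_equal(v3$values[i, j], brute_vrm_cell(xn, yn, zn, i, j, 1),
                 tolerance = 1e-10)
  }
  expect_true(all(v3$values >= 0 & v3$values <= 1))
})

test_that("ASCII grid and GeoJSON round-trip", {
  set.seed(12)
  g <- cov_grid(matrix(rnorm(30), 5, 6), 37.1, 0.25, 0.01)
  f <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, f)
  g2 <- read_asc(f)
  expect_equal(g2$values, g$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(g2$xll, g$xll)
  expect_equal(g2$cellsize, g$cellsize)

  feats <- list(cbind(c(37.1, 37.2, 37.3), c(0.3, 0.35, 0.3)))
  fj <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(feats, "LineString", fj)
  expect_equal(read_geojson(fj)[[1]], feats[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("covariate sampling: NDVI windows, water distance, protection", {
  cfg <- sim_config(seed = 3, n_days = 40)
  stack <- make_environment(cfg)
  # NDVI slices tile the simulation span without gaps
  for (d in seq(cfg$start_date, cfg$start_date + cfg$n_days, by = "day")) {
    expect_false(is.null(ndvi_slice_for_date(stack, as.Date(d, origin = "1970-01-01"))))
  }
  # a slice is valid for exactly 16 days from its start
  s1 <- stack$ndvi[[2]]
  expect_identical(ndvi_slice_for_date(stack, s1$start), s1$grid)
  expect_identical(ndvi_slice_for_date(stack, s1$start + 15), s1$grid)
  expect_false(identical(ndvi_slice_for_date(stack, s1$start + 16), s1$grid))

  # fix on a water-feature vertex has distance 0
  v <- stack$water[[1]][3, ]
  tr <- data.frame(id = "A", timestamp = as.POSIXct("2022-01-05 06:00:00",
                                                    tz = "UTC"),
                   lat = v[2], lon = v[1], interpolated = FALSE)
  pf <- sample_covariates(tr, stack)
  expect_equal(pf$dist_water_km, 0, tolerance = 1e-6)

  # centre of the protected rectangle is protected
  pa <- stack$protected[[1]]
  tr$lat <- mean(pa[1:4, 2]); tr$lon <- mean(pa[1:4, 1])
  expect_equal(sample_covariates(tr, stack)$protected, 1)
  # far outside the rasters -> NA covariates
  tr$lat <- 5; tr$lon <- 40
  expect_true(is.na(sample_covariates(tr, stack)$elevation))
})

test_that("daily covariate means average per fix and round protection half-up", {
  perfix <- data.frame(id = "A", timestamp = Sys.time() + 1:24,
                       date = as.Date("2022-01-01"),
                       elevation = 500, slope = 2, vrm = 0.1,
                       ndvi = c(rep(0.2, 12), rep(0.6, 12)),
                       dist_water_km = 1, protected = rep(c(1, 0), each = 12))
  dm <- daily_covariate_means(perfix)
  expect_equal(dm$ndvi, 0.4)
  expect_equal(dm$protected, 1L)  # mean exactly 0.5 rounds in
  perfix$protected <- c(rep(1, 11), rep(0, 13))
  expect_equal(daily_covariate_means(perfix)$protected, 0L)
  perfix$protected <- 1
  expect_equal(daily_covariate_means(perfix)$protected, 1L)
})

test_that("standardization centres/scales pooled columns and inverts exactly", {
  df <- data.frame(ndvi = c(1, 2, 3), slope = c(2, 4, 9), age = c(20, 35, 50))
  st <- standardize(df, c("ndvi", "slope"), age_col = "age")
  expect_equal(st$data$ndvi, c(-1, 0, 1))
  expect_equal(mean(st$data$slope), 0)
  expect_equal(sd(st$data$slope), 1)
  expect_equal(st$data$age, c(-15, 0, 15))  # centred, not scaled
  back <- unstandardize(st$data, st$params)
  expect_equal(back$ndvi, df$ndvi, tolerance = 1e-12)
  expect_equal(back$age, df$age, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = rep(1, 5)), "a"), "zero-variance.*a")
})
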