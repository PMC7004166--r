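# Environmental covariates: terrain derivatives (Horn slope, vector
# ruggedness measure), NDVI composites with 16-day validity windows,
# distance to water and protected-area membership, sampled per fix and
# averaged per day. Rasters are handled as a lightweight lon/lat grid
# structure serialised to plain-text ESRI ASCII grids; vector features as
# GeoJSON.

#' Construct a lon/lat raster grid
#'
#' @param values Numeric matrix, rows = latitudes south to north, columns =
#'   longitudes west to east.
#' @param xll,yll Lon/lat of the lower-left cell *corner* (degrees).
#' @param cellsize Cell size in degrees (square cells).
#' @return Object of class `cov_grid`.
#' @export
cov_grid <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "cov_grid")
}

grid_lon <- function(g) g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
grid_lat <- function(g) g$yll + (seq_len(nrow(g$values)) - 0.5) * g$cellsize

# metre extents of one cell at the grid centre (for terrain derivatives)
grid_cell_metres <- function(g) {
  lat0 <- mean(grid_lat(g)); lon0 <- mean(grid_lon(g))
  dx <- haversine_km(lat0, lon0, lat0, lon0 + g$cellsize) * 1000
  dy <- haversine_km(lat0, lon0, lat0 + g$cellsize, lon0) * 1000
  c(dx = dx, dy = dy)
}

#' Nearest-cell lookup on a grid
#'
#' @param grid A `cov_grid`.
#' @param lat,lon Query coordinates (degrees), vectorised.
#' @return Values; NA for points outside the grid extent.
#' @export
grid_sample <- function(grid, lat, lon) {
  j <- floor((lon - grid$xll) / grid$cellsize) + 1
  i <- floor((lat - grid$yll) / grid$cellsize) + 1
  ok <- i >= 1 & i <= nrow(grid$values) & j >= 1 & j <= ncol(grid$values)
  out <- rep(NA_real_, length(lat))
  out[ok] <- grid$values[cbind(i[ok], j[ok])]
  out
}

#' Write a grid as an ESRI ASCII raster
#' @param grid A `cov_grid`.
#' @param path Output `.asc` path.
#' @export
write_asc <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    "NODATA_value -9999"), con)
  v <- grid$values
  v[is.na(v)] <- -9999
  for (i in rev(seq_len(nrow(v)))) {  # ASCII grids run north to south
    writeLines(paste(formatC(v[i, ], format = "g", digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#' @param path `.asc` file path.
#' @return A `cov_grid`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  v <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  nd <- hdr[["nodata_value"]]
  if (!is.null(nd)) v[v == nd] <- NA
  cov_grid(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

# Horn eight-neighbour gradient; returns list(dzdx, dzdy) in m/m with
# nearest-valid (edge-replicated) padding.
horn_gradient <- function(grid) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  pad <- v[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  cell <- grid_cell_metres(grid)
  sub <- function(di, dj) pad[seq_len(nr) + 1 + di, seq_len(nc) + 1 + dj]
  # neighbours: rows run south->north so di=+1 is the northern neighbour
  dzdx <- ((sub(1, 1) + 2 * sub(0, 1) + sub(-1, 1)) -
           (sub(1, -1) + 2 * sub(0, -1) + sub(-1, -1))) / (8 * cell["dx"])
  dzdy <- ((sub(1, 1) + 2 * sub(1, 0) + sub(1, -1)) -
           (sub(-1, 1) + 2 * sub(-1, 0) + sub(-1, -1))) / (8 * cell["dy"])
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Terrain slope in degrees (Horn's method)
#'
#' Eight-neighbour finite differences on the elevation grid; edge cells use
#' nearest-valid padding (flagged via attribute `edge_padded`).
#'
#' @param elevation A `cov_grid` of elevations in metres.
#' @return A `cov_grid` of slope in degrees, range 0-90.
#' @export
slope_deg <- function(elevation) {
  gr <- horn_gradient(elevation)
  sl <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2)) * 180 / pi
  out <- cov_grid(sl, elevation$xll, elevation$yll, elevation$cellsize)
  attr(out, "edge_padded") <- TRUE
  out
}

#' Vector ruggedness measure
#'
#' Per Sappington's formulation: each cell contributes a unit normal
#' decomposed from its slope and aspect; VRM = 1 - |resultant| / n over a
#' moving window. 0 on flat or uniformly inclined terrain, up to 1 on
#' maximally rugged terrain.
#'
#' @param elevation A `cov_grid` of elevations in metres.
#' @param window Odd window size (cells); the field-standard 3 by default.
#' @return A `cov_grid` with values in [0, 1].
#' @export
vrm <- function(elevation, window = 3) {
  stopifnot(window %% 2 == 1)
  gr <- horn_gradient(elevation)
  slope <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2))
  aspect <- atan2(gr$dzdy, gr$dzdx)  # any consistent convention works
  xn <- sin(slope) * cos(aspect)
  yn <- sin(slope) * sin(aspect)
  zn <- cos(slope)
  half <- (window - 1) / 2
  nr <- nrow(zn); nc <- ncol(zn)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1, i - half):min(nr, i + half)
    for (j in seq_len(nc)) {
      rj <- max(1, j - half):min(nc, j + half)
      n <- length(ri) * length(rj)
      res <- sqrt(sum(xn[ri, rj])^2 + sum(yn[ri, rj])^2 + sum(zn[ri, rj])^2)
      out[i, j] <- 1 - res / n
    }
  }
  out <- pmin(pmax(out, 0), 1)
  cov_grid(out, elevation$xll, elevation$yll, elevation$cellsize)
}

#' Assemble a covariate stack
#'
#' @param elevation `cov_grid` (m). Slope and VRM are derived on creation.
#' @param ndvi List of entries `list(start = Date, grid = cov_grid)`;
#'   each composite is valid for 16 days from its start date.
#' @param water List of polyline coordinate matrices (lon, lat columns).
#' @param protected List of polygon coordinate matrices (lon, lat).
#' @return Object of class `cov_stack`.
#' @export
cov_stack <- function(elevation, ndvi, water, protected) {
  structure(list(elevation = elevation, slope = slope_deg(elevation),
                 vrm = vrm(elevation), ndvi = ndvi, water = water,
                 protected = protected),
            class = "cov_stack")
}

#' NDVI composite covering a date
#'
#' @param stack A `cov_stack`.
#' @param date Date.
#' @return The `cov_grid` whose 16-day window contains `date`, or NULL.
#' @export
ndvi_slice_for_date <- function(stack, date) {
  date <- as.Date(date)
  for (s in stack$ndvi) {
    if (date >= s$start && date < s$start + 16) return(s$grid)
  }
  NULL
}

#' Sample the covariate stack at every fix
#'
#' Raster covariates use nearest-cell lookup; distance to water is the
#' great-circle distance (km) to the nearest water feature; protected-area
#' membership is a point-in-polygon test. Fixes outside the rasters get NA
#' covariates (their day is dropped later when means are NA).
#'
#' @param track Track data frame.
#' @param stack A `cov_stack`.
#' @return Per-fix data frame: id, timestamp, date, elevation, slope, vrm,
#'   ndvi, dist_water_km, protected.
#' @export
sample_covariates <- function(track, stack) {
  dts <- fix_date(track$timestamp)
  ndvi <- rep(NA_real_, nrow(track))
  for (d in unique(dts)) {
    g <- ndvi_slice_for_date(stack, as.Date(d, origin = "1970-01-01"))
    ix <- which(dts == d)
    if (!is.null(g)) ndvi[ix] <- grid_sample(g, track$lat[ix], track$lon[ix])
  }
  pts <- cbind(track$lon, track$lat)
  dw <- rep(NA_real_, nrow(track))
  for (line in stack$water) {
    d <- geosphere::dist2Line(pts, line)[, "distance"] / 1000
    dw <- if (all(is.na(dw))) d else pmin(dw, d)
  }
  prot <- rep(FALSE, nrow(track))
  for (poly in stack$protected) {
    prot <- prot | point_in_polygon(track$lon, track$lat, poly[, 1], poly[, 2])
  }
  data.frame(id = track$id, timestamp = track$timestamp, date = dts,
             elevation = grid_sample(stack$elevation, track$lat, track$lon),
             slope = grid_sample(stack$slope, track$lat, track$lon),
             vrm = grid_sample(stack$vrm, track$lat, track$lon),
             ndvi = ndvi, dist_water_km = dw, protected = as.numeric(prot),
             stringsAsFactors = FALSE)
}

#' Daily means of per-fix covariates
#'
#' Arithmetic means over each individual-day; the protected-area fraction
#' is rounded to the nearest binary value, with exactly 0.5 rounding up
#' (in).
#'
#' @param perfix Output of [sample_covariates()].
#' @return Data frame: id, date, elevation, slope, vrm, ndvi,
#'   dist_water_km, protected (0/1).
#' @export
daily_covariate_means <- function(perfix) {
  key <- interaction(perfix$id, perfix$date, drop = TRUE)
  rows <- lapply(split(perfix, key), function(g) {
    data.frame(id = g$id[1], date = g$date[1],
               elevation = mean(g$elevation), slope = mean(g$slope),
               vrm = mean(g$vrm), ndvi = mean(g$ndvi),
               dist_water_km = mean(g$dist_water_km),
               protected = as.integer(mean(g$protected) >= 0.5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize covariate columns over the pooled analysis set
#'
#' Continuous covariates become (x - mean)/sd (sample SD, n-1) computed
#' once over all rows -- never per individual. An age column, when named,
#' is centred on 35 years (the age from which clear annual musth periods
#' are expressed) but kept in years.
#'
#' @param df Daily analysis table.
#' @param columns Character vector of columns to standardize.
#' @param age_col Optional name of the age column to centre (scale 1).
#' @param age_center Centring age in years.
#' @return List: `data` (transformed df), `params` (data frame column,
#'   center, scale, usable for the inverse transform).
#' @export
standardize <- function(df, columns, age_col = NULL, age_center = 35) {
  params <- data.frame(column = character(0), center = numeric(0),
                       scale = numeric(0), stringsAsFactors = FALSE)
  for (cn in columns) {
    s <- stats::sd(df[[cn]])
    if (!is.finite(s) || s == 0) {
      stop("zero-variance column: ", cn, call. = FALSE)
    }
    m <- mean(df[[cn]])
    df[[cn]] <- (df[[cn]] - m) / s
    params <- rbind(params, data.frame(column = cn, center = m, scale = s))
  }
  if (!is.null(age_col)) {
    df[[age_col]] <- df[[age_col]] - age_center
    params <- rbind(params, data.frame(column = age_col, center = age_center,
                                       scale = 1))
  }
  list(data = df, params = params)
}

#' Invert a standardization
#'
#' @param df Transformed table.
#' @param params Params from [standardize()].
#' @return Table on the original scale.
#' @export
unstandardize <- function(df, params) {
  for (k in seq_len(nrow(params))) {
    cn <- params$column[k]
    df[[cn]] <- df[[cn]] * params$scale[k] + params$center[k]
  }
  df
}

#' Write line/polygon features as GeoJSON
#'
#' @param features List of coordinate matrices (lon, lat columns).
#' @param type "LineString" or "Polygon".
#' @param path Output path.
#' @export
write_geojson <- function(features, type = c("LineString", "Polygon"), path) {
  type <- match.arg(type)
  feats <- lapply(features, function(m) {
    coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    if (type == "Polygon") coords <- list(coords)
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read line/polygon features from GeoJSON
#'
#' Supports the (Multi)LineString and (Multi)Polygon geometries this
#' pipeline writes; polygons keep their outer ring only.
#'
#' @param path GeoJSON file.
#' @return List of coordinate matrices (lon, lat columns).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list()
  to_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  }
  for (f in gj$features) {
    g <- f$geometry
    out <- c(out, switch(g$type,
      LineString = list(to_mat(g$coordinates)),
      Polygon = list(to_mat(g$coordinates[[1]])),
      MultiLineString = lapply(g$coordinates, to_mat),
      MultiPolygon = lapply(g$coordinates, function(p) to_mat(p[[1]])),
      stop("unsupported geometry: ", g$type)))
  }
  out
}
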