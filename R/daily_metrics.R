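# Daily movement statistics: mean speed (km/h), 95% minimum convex polygon
# range (km^2) and the corrected sinuosity index.

#' Mean travel speed over a sequence of fixes
#'
#' Mean over consecutive-fix steps of great-circle distance divided by
#' elapsed time, so days with a few missing fixes remain usable.
#'
#' @param fixes Data frame of at least two fixes (timestamp, lat, lon),
#'   sorted by time.
#' @return Speed in km/h.
#' @export
daily_mean_speed <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2L) stop("daily_mean_speed needs >= 2 fixes", call. = FALSE)
  d <- haversine_km(fixes$lat[-n], fixes$lon[-n], fixes$lat[-1], fixes$lon[-1])
  dt <- diff(as.numeric(fixes$timestamp)) / 3600
  mean(d / dt)
}

# Shoelace area of the convex hull of planar points; 0 when fewer than
# three distinct points remain.
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Minimum convex polygon area of planar points
#'
#' Classic percent-MCP: the `ceiling((1 - percent/100) * n)` points
#' farthest from the arithmetic centroid are peeled off (distance ties
#' resolved by peeling the earlier point first) and the convex-hull area of
#' the remainder returned. Collinear or degenerate remainders have area 0.
#'
#' @param x,y Coordinates (km).
#' @param percent MCP percentage in (0, 100].
#' @return Area in km^2.
#' @export
mcp_area_xy <- function(x, y, percent = 95) {
  stopifnot(percent > 0, percent <= 100)
  n <- length(x)
  m <- ceiling((1 - percent / 100) * n)
  if (m > 0L) {
    d2 <- (x - mean(x))^2 + (y - mean(y))^2
    drop_ix <- order(-d2, seq_len(n))[seq_len(m)]
    x <- x[-drop_ix]; y <- y[-drop_ix]
  }
  hull_area(x, y)
}

#' Daily range size as a percent minimum convex polygon
#'
#' Fixes are projected onto a local azimuthal-equidistant plane centred on
#' their centroid before peeling and hulling.
#'
#' @param fixes Data frame of fixes (lat, lon), in time order.
#' @param percent MCP percentage; the analysis default is 95.
#' @return Area in km^2.
#' @export
mcp_km2 <- function(fixes, percent = 95) {
  center <- c(mean(fixes$lat), mean(fixes$lon))
  xy <- aeqd_project(fixes$lat, fixes$lon, center)
  mcp_area_xy(xy$x, xy$y, percent)
}

#' Corrected sinuosity index of a daily path
#'
#' Computes 2 * [p * ((1 + c)/(1 - c) + b^2)]^(-1/2), where p is the mean
#' step length (km), c the mean cosine of turning angles and b the
#' coefficient of variation of step length. Units 1/sqrt(km); 0 in the
#' straight-path limit c -> 1 (flagged via attribute `straight`).
#'
#' @param fixes Data frame of at least three fixes (lat, lon), time-sorted.
#' @return Sinuosity index (numeric scalar).
#' @export
sinuosity <- function(fixes) {
  n <- nrow(fixes)
  if (n < 3L) stop("sinuosity needs >= 3 fixes", call. = FALSE)
  center <- c(mean(fixes$lat), mean(fixes$lon))
  xy <- aeqd_project(fixes$lat, fixes$lon, center)
  dx <- diff(xy$x); dy <- diff(xy$y)
  len <- sqrt(dx^2 + dy^2)
  keep <- len > 0
  dx <- dx[keep]; dy <- dy[keep]; len <- len[keep]
  if (length(len) < 2L) return(structure(0, straight = TRUE))
  ang <- atan2(dy, dx)
  turn <- diff(ang)
  cbar <- mean(cos(turn))
  p <- mean(len)
  b <- stats::sd(len) / p
  if (cbar >= 1 - 1e-12) return(structure(0, straight = TRUE))
  2 / sqrt(p * ((1 + cbar) / (1 - cbar) + b^2))
}

#' Daily movement statistics for one regularised track
#'
#' For every QC-included day, computes mean speed, percent-MCP range and
#' sinuosity. Steps crossing local midnight belong to the day in which
#' they end, so each day's speed uses its own fixes plus the immediately
#' preceding fix of the track (when present). Interpolated fixes
#' participate like observed ones.
#'
#' @param track Regularised track data frame.
#' @param qc Day table from [qc_days()]; computed if NULL.
#' @param mcp_percent MCP percentage.
#' @return Data frame: id, date, n_fixes, mean_speed_kmh, mcp95_km2,
#'   sinuosity.
#' @export
daily_metrics <- function(track, qc = NULL, mcp_percent = 95) {
  if (is.null(qc)) qc <- qc_days(track)
  qc <- qc[qc$included, , drop = FALSE]
  if (nrow(qc) == 0L) {
    return(data.frame(id = character(0), date = as.Date(character(0)),
                      n_fixes = integer(0), mean_speed_kmh = numeric(0),
                      mcp95_km2 = numeric(0), sinuosity = numeric(0)))
  }
  d <- fix_date(track$timestamp)
  rows <- lapply(seq_len(nrow(qc)), function(i) {
    ix <- which(d == qc$date[i])
    if (min(ix) > 1L) ix <- c(min(ix) - 1L, ix)  # step ending at first fix
    day_fixes <- track[ix, , drop = FALSE]
    own <- track[d == qc$date[i], , drop = FALSE]
    data.frame(id = qc$id[i], date = qc$date[i], n_fixes = qc$n_fixes[i],
               mean_speed_kmh = daily_mean_speed(day_fixes),
               mcp95_km2 = mcp_km2(own, mcp_percent),
               sinuosity = as.numeric(sinuosity(own)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
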