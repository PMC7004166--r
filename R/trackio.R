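# Readers, writers and labelling rules for GPS fixes, field observations of
# musth signals, and the study roster.

STUDY_TZ <- "Etc/GMT-3"  # study-site civil time (UTC+3); defines the calendar day

#' Parse ISO-8601 timestamps with zone to POSIXct (UTC)
#'
#' Accepts `...Z`, `...+HH:MM` / `-HH:MM` offsets, and a plain
#' `YYYY-MM-DD HH:MM:SS`, which is taken as UTC.
#'
#' @param x Character vector of timestamps.
#' @return POSIXct in UTC; NA where unparseable.
#' @export
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", " +0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", " \\1\\2", x)
  has_off <- grepl("[+-][0-9]{4}$", x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (any(has_off)) {
    out[has_off] <- as.POSIXct(x[has_off], tz = "UTC", format = "%Y-%m-%d %H:%M:%S %z")
  }
  if (any(!has_off)) {
    out[!has_off] <- as.POSIXct(x[!has_off], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Calendar date of a fix in study-site time
#'
#' Days throughout the pipeline are bounded at local (UTC+3) midnight.
#'
#' @param timestamp POSIXct vector.
#' @return Date vector.
#' @export
fix_date <- function(timestamp) {
  as.Date(format(timestamp, "%Y-%m-%d", tz = STUDY_TZ))
}

#' Integer age on a date under the fixed 31-August birthday anchor
#'
#' Every bull is assigned a 31 August birthday (the midpoint of the dry
#' season, when few bulls are in musth), so age changes once a year and
#' never during the peak musth periods.
#'
#' @param birth_year Integer year(s) of birth.
#' @param date Date(s) of observation.
#' @return Integer age in completed years.
#' @export
age_on_date <- function(birth_year, date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  anchor <- as.Date(sprintf("%d-08-31", yr))
  ifelse(date >= anchor, yr - birth_year, yr - 1L - birth_year)
}

validate_fix_rows <- function(df, line_no) {
  bad <- character(0)
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  ts <- parse_timestamp(df$timestamp)
  probs <- list(
    "unparseable timestamp" = is.na(ts),
    "lat outside [-90, 90]" = !is.na(lat) & (lat < -90 | lat > 90),
    "lon outside (-180, 180]" = !is.na(lon) & (lon <= -180 | lon > 180),
    "non-numeric coordinate" = is.na(lat) | is.na(lon),
    "empty id" = is.na(df$id) | df$id == ""
  )
  for (what in names(probs)) {
    idx <- which(probs[[what]])
    if (length(idx)) {
      bad <- c(bad, sprintf("line %d: %s", line_no[idx], what))
    }
  }
  if (length(bad)) {
    stop("invalid fix rows:\n", paste(unique(bad), collapse = "\n"), call. = FALSE)
  }
  data.frame(id = as.character(df$id), timestamp = ts, lat = lat, lon = lon,
             interpolated = if ("interpolated" %in% names(df))
               as.logical(df$interpolated) else FALSE,
             stringsAsFactors = FALSE)
}

#' Read a fixes CSV into a set of per-individual tracks
#'
#' The file must have columns `id,timestamp,lat,lon` and may carry an
#' `interpolated` flag. Fixes are grouped per individual and sorted by
#' time; rows duplicating an (id, timestamp) pair are collapsed to the
#' first occurrence with a warning. Invalid rows abort with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return A named list of track data frames (class `track_set`), each with
#'   columns id, timestamp (POSIXct UTC), lat, lon, interpolated.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop("fixes CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  fx <- validate_fix_rows(df, line_no = seq_len(nrow(df)) + 1L)
  as_track_set(fx)
}

#' Build a track set from a fixes data frame
#'
#' @param fixes Data frame with id, timestamp, lat, lon and optionally
#'   interpolated.
#' @return Named list of per-individual tracks, class `track_set`.
#' @export
as_track_set <- function(fixes) {
  if (is.null(fixes$interpolated)) fixes$interpolated <- FALSE
  out <- lapply(split(fixes, fixes$id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    dup <- duplicated(tr$timestamp)
    if (any(dup)) {
      warning(sprintf("%s: dropped %d duplicate timestamp(s), first kept",
                      tr$id[1], sum(dup)), call. = FALSE)
      tr <- tr[!dup, , drop = FALSE]
    }
    rownames(tr) <- NULL
    tr
  })
  structure(out, class = "track_set")
}

#' Write a track set to the canonical fixes CSV
#'
#' Canonical form: columns `id,timestamp,lat,lon,interpolated`, ISO-8601
#' UTC timestamps, coordinates to six decimal places, individuals in list
#' order. [read_fixes()] followed by `write_fixes()` reproduces a canonical
#' file byte-for-byte.
#'
#' @param tracks A `track_set`.
#' @param path Output CSV path.
#' @export
write_fixes <- function(tracks, path) {
  df <- do.call(rbind, lapply(unname(tracks), function(tr) {
    data.frame(id = tr$id, timestamp = format_timestamp(tr$timestamp),
               lat = sprintf("%.6f", tr$lat), lon = sprintf("%.6f", tr$lon),
               interpolated = tolower(as.character(tr$interpolated)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Label musth observations from signal counts
#'
#' A bull is scored for up to three musth signals (temporal gland swelling,
#' temporal gland secretion, urine dribbling). Two or three signals label
#' the day `musth`; exactly one signal is ambiguous and labelled
#' `excluded` (retained but skipped downstream); zero signals label
#' `non_musth`.
#'
#' @param obs Data frame with columns `id`, `date` and either `n_signals`
#'   (0-3) or, with `prelabelled = TRUE`, a `label` column.
#' @param prelabelled Accept a pre-assigned musth/non_musth label column
#'   instead of signal counts.
#' @return Data frame id, date, n_signals (NA if prelabelled), label.
#' @export
label_observations <- function(obs, prelabelled = FALSE) {
  stopifnot(all(c("id", "date") %in% names(obs)))
  date <- as.Date(obs$date)
  if (prelabelled) {
    lab <- as.character(obs$label)
    ok <- lab %in% c("musth", "non_musth", "excluded")
    if (!all(ok)) stop("unknown label(s): ", paste(unique(lab[!ok]), collapse = ", "),
                       call. = FALSE)
    return(data.frame(id = as.character(obs$id), date = date,
                      n_signals = NA_integer_, label = lab,
                      stringsAsFactors = FALSE))
  }
  n <- suppressWarnings(as.integer(obs$n_signals))
  if (any(is.na(n) | n < 0L | n > 3L)) {
    stop("n_signals must be an integer in 0-3", call. = FALSE)
  }
  lab <- ifelse(n >= 2L, "musth", ifelse(n == 1L, "excluded", "non_musth"))
  data.frame(id = as.character(obs$id), date = date, n_signals = n, label = lab,
             stringsAsFactors = FALSE)
}

#' Read an observations CSV
#'
#' @param path CSV with columns `id,date,n_signals` (or `id,date,label`
#'   with `prelabelled = TRUE`).
#' @param prelabelled See [label_observations()].
#' @return Labelled observation data frame.
#' @export
read_observations <- function(path, prelabelled = FALSE) {
  label_observations(utils::read.csv(path, stringsAsFactors = FALSE), prelabelled)
}

#' Read the packaged study roster
#'
#' One row per collared bull: name, minimum and maximum age attained during
#' the study, observation days by state, and total GPS tracking days
#' analysed by state (which include the day either side of each
#' observation). Totals are never stored; use [tally_roster()].
#'
#' @param path Roster CSV; defaults to the packaged field-study roster of
#'   the 25 tracked bulls.
#' @return Roster data frame.
#' @export
read_roster <- function(path = system.file("extdata", "bull_roster.csv",
                                           package = "musthmove")) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "min_age", "max_age", "obs_days_nonmusth", "obs_days_musth",
            "total_days_nonmusth", "total_days_musth")
  if (!all(need %in% names(r))) {
    stop("roster CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  counts <- c("obs_days_nonmusth", "obs_days_musth",
              "total_days_nonmusth", "total_days_musth")
  if (any(r$min_age > r$max_age)) stop("roster: min_age > max_age", call. = FALSE)
  if (any(as.matrix(r[counts]) < 0)) stop("roster: negative count", call. = FALSE)
  r
}

#' Summarise a roster
#'
#' @param roster Data frame as returned by [read_roster()].
#' @return List with n_individuals, min_age, max_age and the four column
#'   totals (observation and tracking days by state).
#' @export
tally_roster <- function(roster) {
  if (is.null(roster) || nrow(roster) == 0L) stop("empty roster", call. = FALSE)
  list(
    n_individuals = nrow(roster),
    min_age = min(roster$min_age),
    max_age = max(roster$max_age),
    obs_days_nonmusth = sum(roster$obs_days_nonmusth),
    obs_days_musth = sum(roster$obs_days_musth),
    total_days_nonmusth = sum(roster$total_days_nonmusth),
    total_days_musth = sum(roster$total_days_musth)
  )
}
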