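# Scoring decoded musth days against field observations.

#' Expand observations to daily state labels
#'
#' A bull is assumed to be in the observed state the day before and the
#' day after each field observation, so every usable observation labels
#' three days. When expansions conflict (one day claimed both musth and
#' non-musth), a same-day observation wins; otherwise the day is dropped
#' with a warning. Excluded (single-signal) observations are skipped.
#'
#' @param observations Labelled observation table from
#'   [label_observations()].
#' @return Data frame: id, date, label (musth / non_musth).
#' @export
expand_labels <- function(observations) {
  obs <- observations[observations$label != "excluded", , drop = FALSE]
  if (nrow(obs) == 0L) {
    return(data.frame(id = character(0), date = as.Date(character(0)),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ex <- do.call(rbind, lapply(c(-1L, 0L, 1L), function(off) {
    data.frame(id = obs$id, date = obs$date + off, label = obs$label,
               same_day = off == 0L, stringsAsFactors = FALSE)
  }))
  key <- paste(ex$id, ex$date)
  rows <- lapply(split(ex, key), function(g) {
    labs <- unique(g$label)
    if (length(labs) == 1L) {
      return(data.frame(id = g$id[1], date = g$date[1], label = labs,
                        stringsAsFactors = FALSE))
    }
    same <- unique(g$label[g$same_day])
    if (length(same) == 1L) {
      return(data.frame(id = g$id[1], date = g$date[1], label = same,
                        stringsAsFactors = FALSE))
    }
    warning(sprintf("%s %s: conflicting expanded labels, day dropped",
                    g$id[1], g$date[1]), call. = FALSE)
    NULL
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confusion summary of decoded states against daily labels
#'
#' Counts true/false positives and negatives on labelled days present in
#' the decode, per individual and pooled. The primary aggregation is the
#' mean of per-individual sensitivity and specificity (individuals without
#' labelled positives or negatives drop out of the respective mean);
#' pooled metrics are always reported alongside.
#'
#' @param decoded Data frame with columns id, date, assigned (logical
#'   musth assignment).
#' @param labels Daily label table from [expand_labels()].
#' @return List: `per_individual` (data frame with counts and rates),
#'   `pooled` (counts plus sensitivity, specificity, accuracy),
#'   `mean_individual` (sensitivity, specificity).
#' @export
confusion <- function(decoded, labels) {
  m <- merge(labels, decoded[, c("id", "date", "assigned")], by = c("id", "date"))
  if (nrow(m) == 0L) stop("no labelled days overlap the decode", call. = FALSE)
  per <- do.call(rbind, lapply(split(m, m$id), function(g) {
    tp <- sum(g$label == "musth" & g$assigned)
    fn <- sum(g$label == "musth" & !g$assigned)
    tn <- sum(g$label == "non_musth" & !g$assigned)
    fp <- sum(g$label == "non_musth" & g$assigned)
    data.frame(id = g$id[1], tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  tp <- sum(per$tp); fp <- sum(per$fp); tn <- sum(per$tn); fn <- sum(per$fn)
  pooled <- list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / nrow(m))
  list(per_individual = per, pooled = pooled,
       mean_individual = list(
         sensitivity = mean(per$sensitivity, na.rm = TRUE),
         specificity = mean(per$specificity, na.rm = TRUE)))
}
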