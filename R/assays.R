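#' Detachment detection in a contact-count series
#'
#' The ligand counts as detached at the first frame where the contact count
#' reaches zero; later re-binding is ignored ("first time" rule). With
#' `persistence > 1` the count must stay at zero for that many consecutive
#' frames (off by default).
#'
#' @param counts per-frame contact counts (`habind_count_series` or integer
#'   vector).
#' @param dt time per frame (ns).
#' @param t_end censoring time (ns): the simulation end. Required - the
#'   observation window is an experimental input, never a default.
#' @param field_tag label of the applied field condition.
#' @param replica replica identifier.
#' @param persistence consecutive zero frames required (default 1).
#' @return one-row data.frame of class `habind_detachment`: `replica`,
#'   `detached`, `time` (ns, NA when censored), `censored_at`, `field`.
#' @export
detect_detachment <- function(counts, dt, t_end, field_tag = "field",
                              replica = 1L, persistence = 1L) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("empty contact-count series")
  if (any(counts < 0)) stop("negative contact counts")
  if (missing(t_end) || is.null(t_end)) stop("censoring time t_end is required")
  zero <- counts == 0
  hit <- NA_integer_
  if (persistence <= 1L) {
    w <- which(zero)
    if (length(w)) hit <- w[1]
  } else {
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= persistence)
    if (length(ok)) hit <- ends[ok[1]] - r$lengths[ok[1]] + 1L
  }
  detached <- !is.na(hit)
  out <- data.frame(replica = replica, detached = detached,
                    time = if (detached) (hit - 1) * dt else NA_real_,
                    censored_at = t_end, field = field_tag,
                    stringsAsFactors = FALSE)
  class(out) <- c("habind_detachment", "data.frame")
  out
}

#' Summarise detachment records
#'
#' Detachment fraction over all replicas; mean detachment time and its
#' standard error over the detached replicas only. With one or zero
#' detachments the SE is `NA` (the table's "N/A" sentinel); with zero the
#' mean time is `NA` too.
#'
#' @param records data.frame of stacked detachment records (one field tag).
#' @return list of class `habind_detachment_summary`: `n`, `n_detached`,
#'   `fraction` (percent), `mean_time`, `se_time`, `field`.
#' @export
summarize_detachments <- function(records) {
  if (!nrow(records)) stop("no detachment records")
  if (length(unique(records$field)) != 1)
    stop("records mix field tags; summarise one condition at a time")
  n <- nrow(records)
  det <- records$time[records$detached]
  nd <- length(det)
  out <- list(n = n, n_detached = nd, fraction = 100 * nd / n,
              mean_time = if (nd >= 1) mean(det) else NA_real_,
              se_time = if (nd > 1) sd(det) / sqrt(nd) else NA_real_,
              field = records$field[1])
  class(out) <- "habind_detachment_summary"
  out
}

#' @export
print.habind_detachment_summary <- function(x, ...) {
  cat(sprintf("<detachments> %s: %.0f%% (%d/%d), mean time %s +- %s ns\n",
              x$field, x$fraction, x$n_detached, x$n,
              ifelse(is.na(x$mean_time), "N/A", sprintf("%.2f", x$mean_time)),
              ifelse(is.na(x$se_time), "N/A", sprintf("%.2f", x$se_time))))
  invisible(x)
}

#' Contact centroid along the polymer at one frame
#'
#' Contact-count-weighted mean of the polymer monosaccharide positions
#' (1-based from the reducing end). Returns `NA` (not an error) at frames
#' with no contacts so tracks can tolerate gaps.
#'
#' @param contour a `habind_contour`.
#' @param frame frame index.
#' @export
contact_centroid <- function(contour, frame) {
  cnt <- contour[, frame]
  if (sum(cnt) == 0) return(NA_real_)
  pos <- attr(contour, "mono_pos")
  sum(pos * cnt) / sum(cnt)
}

#' Sliding track of the receptor along the polymer
#'
#' Per-frame contact centroid (monosaccharide units) with linear
#' interpolation over zero-contact gaps up to `max_gap` frames (transient
#' partial detachments); longer gaps stay undefined. Reports net
#' displacement and maximum excursion from the first defined centroid.
#'
#' @param contour a `habind_contour`.
#' @param dt time per frame (ns).
#' @param max_gap longest gap (frames) bridged by interpolation (default 20).
#' @return list of class `habind_sliding_track`: `time`, `centroid`,
#'   `total_contacts`, `net_displacement`, `max_excursion`.
#' @export
sliding_track <- function(contour, dt = 1, max_gap = 20L) {
  nf <- ncol(contour)
  if (!nf) stop("empty contour")
  cent <- vapply(seq_len(nf), function(f) contact_centroid(contour, f),
                 numeric(1))
  total <- colSums(contour)
  defined <- which(!is.na(cent))
  if (length(defined) >= 2) {
    gaps <- which(is.na(cent))
    for (g in split(gaps, cumsum(c(1, diff(gaps) != 1))[seq_along(gaps)])) {
      lo <- g[1] - 1L; hi <- g[length(g)] + 1L
      if (lo >= 1 && hi <= nf && !is.na(cent[lo]) && !is.na(cent[hi]) &&
          length(g) <= max_gap)
        cent[g] <- cent[lo] + (cent[hi] - cent[lo]) *
          (g - lo) / (hi - lo)
    }
  }
  defined <- which(!is.na(cent))
  net <- if (length(defined) >= 2)
    cent[defined[length(defined)]] - cent[defined[1]] else 0
  maxexc <- if (length(defined) >= 2)
    max(abs(cent[defined] - cent[defined[1]])) else 0
  structure(list(time = (seq_len(nf) - 1) * dt, centroid = cent,
                 total_contacts = as.numeric(total),
                 net_displacement = net, max_excursion = maxexc),
            class = "habind_sliding_track")
}

#' Partial-detachment events
#'
#' Stretches where the total contact count falls below a low watermark
#' (default a quarter of the track median) while at least one residue of the
#' retained set (the 108-114 hydrogen-bond band by default) stays in contact
#' throughout. Full detachments (no residue in contact) are not partial
#' events.
#'
#' @param series a `habind_contact_series` (frames x residues).
#' @param counts per-frame total contact counts (same frames).
#' @param retained_set residue numbers that must persist (default 108:114).
#' @param watermark_frac fraction of the median count defining the
#'   low-contact watermark (default 0.25).
#' @return data.frame with `start`, `end` (frame indices), `length`,
#'   `retained` (comma-joined persisting residues).
#' @export
detect_partial_detachment <- function(series, counts, retained_set = 108:114,
                                      watermark_frac = 0.25) {
  if (!length(retained_set)) stop("retained set must not be empty")
  counts <- as.numeric(counts)
  stopifnot(length(counts) == nrow(series))
  keep <- intersect(as.character(retained_set), colnames(series))
  if (!length(keep)) stop("no retained-set residues present in the series")
  wm <- watermark_frac * median(counts)
  low <- counts < wm
  ret_ok <- rowSums(series[, keep, drop = FALSE]) > 0
  events <- data.frame(start = integer(), end = integer(), length = integer(),
                       retained = character(), stringsAsFactors = FALSE)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    span <- starts[i]:ends[i]
    if (all(ret_ok[span])) {
      persisting <- keep[colSums(series[span, keep, drop = FALSE]) == length(span)]
      events <- rbind(events, data.frame(
        start = starts[i], end = ends[i], length = length(span),
        retained = paste(persisting, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  events
}

#' One-dimensional mean squared displacement of a sliding track
#'
#' MSD over lag times, averaged over all time origins where the centroid is
#' defined at both ends of the lag.
#'
#' @param track a `habind_sliding_track`.
#' @param max_lag maximum lag in frames (must be < track length).
#' @return data.frame with `lag` (frames), `tau` (time units of the track),
#'   `msd` (monosaccharide units squared), `n_pairs`.
#' @export
msd_1d <- function(track, max_lag) {
  x <- track$centroid
  nf <- length(x)
  if (max_lag >= nf) stop("max_lag must be smaller than the track length")
  if (sum(!is.na(x)) < 2) stop("need at least two defined centroid frames")
  dt <- if (nf > 1) track$time[2] - track$time[1] else 1
  lag <- seq_len(max_lag)
  msd <- numeric(max_lag); np <- integer(max_lag)
  for (l in lag) {
    d <- x[(1 + l):nf] - x[1:(nf - l)]
    ok <- !is.na(d)
    np[l] <- sum(ok)
    msd[l] <- if (np[l]) mean(d[ok]^2) else NA_real_
  }
  data.frame(lag = lag, tau = lag * dt, msd = msd, n_pairs = np)
}

#' Export a sliding track as TSV
#' @param track a `habind_sliding_track`.
#' @param path output file.
#' @export
write_sliding_track <- function(track, path) {
  write.table(data.frame(time = track$time, centroid = track$centroid,
                         total_contacts = track$total_contacts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
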