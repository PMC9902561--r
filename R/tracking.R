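## Bead tracking: circle detection in the first frame, fixed-position
## intensity-variance traces through the stack, and per-bead dissociation
## calls. Tethered beads are laterally confined, so ROIs never re-centre.

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

box3 <- function(m) {
  s <- m
  for (dy in -1:1) for (dx in -1:1)
    if (dy != 0 || dx != 0) s <- s + shift_mat(m, dy, dx)
  s
}

#' Detect circular beads in a single frame
#'
#' Gradient-accumulator circular Hough transform: image gradients are
#' computed by central differences, strong-gradient pixels vote along their
#' gradient direction (towards brighter intensity, i.e. towards the centre
#' of a bright-centred bead) at each candidate radius, and accumulator
#' peaks normalised by circle circumference become detections. Deterministic
#' for a fixed frame and parameters.
#'
#' @param frame 2-D grayscale matrix (finite values).
#' @param radius_range Numeric c(min, max) candidate radii in pixels;
#'   integer radii in this range are scanned.
#' @param sensitivity Minimum fraction of a circle's circumference that must
#'   vote (within the smoothed 3x3 peak neighbourhood) for a detection;
#'   lower values admit weaker circles. Default 0.3.
#' @param min_peak_dist Non-maximum-suppression distance between accepted
#'   centres; defaults to 1.5 x the largest candidate radius.
#' @return A data frame of class `bead_tracks`, one row per detection sorted
#'   by decreasing score: bead_id, y_px, x_px, radius, score. Zero rows when
#'   nothing exceeds `sensitivity`.
#' @export
detect_beads <- function(frame, radius_range = c(3, 6), sensitivity = 0.3,
                         min_peak_dist = NULL) {
  if (!is.matrix(frame) || length(frame) == 0 || any(!is.finite(frame)))
    stop("`frame` must be a non-empty finite numeric matrix", call. = FALSE)
  stopifnot(length(radius_range) == 2L, radius_range[1] >= 1,
            radius_range[2] >= radius_range[1])
  if (is.null(min_peak_dist)) min_peak_dist <- 1.5 * radius_range[2]
  h <- nrow(frame); w <- ncol(frame)
  gx <- (shift_mat(frame, 0, -1) - shift_mat(frame, 0, 1)) / 2
  gy <- (shift_mat(frame, -1, 0) - shift_mat(frame, 1, 0)) / 2
  gx[, c(1, w)] <- 0; gy[c(1, h), ] <- 0
  mag <- sqrt(gx^2 + gy^2)
  thr <- max(mean(mag) + 2 * stats::sd(mag), 0.2 * max(mag))
  sel <- which(mag > thr)
  empty <- structure(
    data.frame(bead_id = integer(0), y_px = numeric(0), x_px = numeric(0),
               radius = numeric(0), score = numeric(0)),
    class = c("bead_tracks", "data.frame"))
  if (length(sel) == 0) return(empty)
  pos <- arrayInd(sel, dim(frame))
  yi <- pos[, 1]; xi <- pos[, 2]
  uy <- gy[sel] / mag[sel]; ux <- gx[sel] / mag[sel]
  radii <- seq(ceiling(radius_range[1]), floor(radius_range[2]))
  best_score <- matrix(0, h, w)
  best_r <- matrix(NA_real_, h, w)
  for (r in radii) {
    ci <- round(yi + r * uy); cj <- round(xi + r * ux)
    ok <- ci >= 1 & ci <= h & cj >= 1 & cj <= w
    if (!any(ok)) next
    counts <- tabulate((cj[ok] - 1) * h + ci[ok], nbins = h * w)
    score <- box3(matrix(counts, h, w)) / (2 * pi * r)
    upd <- score > best_score
    best_score[upd] <- score[upd]
    best_r[upd] <- r
  }
  cand <- which(best_score >= sensitivity)
  if (length(cand) == 0) return(empty)
  # polarity check: a bead centre must be brighter than its surround; this
  # rejects diffuse accumulator ridges cast outside real beads by the
  # outward gradients of the dark annulus
  noise_scale <- stats::mad(as.vector(frame))
  centre_ok <- vapply(cand, function(ix) {
    p <- arrayInd(ix, dim(frame))
    r <- best_r[ix]
    b <- roi_bounds(p[1], p[2], ceiling(2 * r), h, w)
    if (!b$inside) return(FALSE)
    roi <- frame[b$ys, b$xs]
    d <- sqrt(outer((b$ys - p[1])^2, (b$xs - p[2])^2, "+"))
    mean(roi[d <= r]) - mean(roi[d > r]) > 2 * noise_scale
  }, logical(1))
  cand <- cand[centre_ok]
  if (length(cand) == 0) return(empty)
  cand <- cand[order(best_score[cand], decreasing = TRUE)]
  cpos <- arrayInd(cand, dim(frame))
  keep_y <- keep_x <- keep_r <- keep_s <- numeric(0)
  for (i in seq_along(cand)) {
    y <- cpos[i, 1]; x <- cpos[i, 2]
    if (length(keep_y) == 0 ||
        all(sqrt((keep_y - y)^2 + (keep_x - x)^2) >= min_peak_dist)) {
      keep_y <- c(keep_y, y); keep_x <- c(keep_x, x)
      keep_r <- c(keep_r, best_r[cand[i]])
      keep_s <- c(keep_s, best_score[cand[i]])
    }
  }
  structure(
    data.frame(bead_id = seq_along(keep_y), y_px = keep_y, x_px = keep_x,
               radius = keep_r, score = keep_s),
    class = c("bead_tracks", "data.frame"))
}

roi_bounds <- function(y, x, half_width, h, w) {
  list(ys = (y - half_width):(y + half_width),
       xs = (x - half_width):(x + half_width),
       inside = y - half_width >= 1 && y + half_width <= h &&
                x - half_width >= 1 && x + half_width <= w)
}

laplacian_energy <- function(frame, y, x, half_width) {
  b <- roi_bounds(y, x, half_width, nrow(frame), ncol(frame))
  roi <- frame[b$ys, b$xs]
  lap <- 4 * roi - shift_mat(roi, 1, 0) - shift_mat(roi, -1, 0) -
    shift_mat(roi, 0, 1) - shift_mat(roi, 0, -1)
  inner <- lap[2:(nrow(lap) - 1), 2:(ncol(lap) - 1)]
  mean(inner^2)
}

#' Exclude clustered, edge-clipped and out-of-focus detections
#'
#' Applies the pre-screening rules before any variance analysis: any pair of
#' detections closer than `min_separation_px` is excluded (both members,
#' reason "clustered"); detections whose ROI would clip the frame edge are
#' excluded (reason "edge"); detections whose first-frame focus metric
#' (Laplacian energy in the ROI) falls outside `focus_band` are excluded
#' (reason "off_focus") since atypical focus suggests multiple tethers.
#' The outcome is independent of detection order.
#'
#' @param tracks A `bead_tracks` data frame from [detect_beads()].
#' @param frame The first analysed frame.
#' @param min_separation_px Minimum allowed centre-to-centre distance.
#' @param focus_band Numeric c(lo, hi) band of acceptable Laplacian energy,
#'   or NULL to derive it as median +/- 3 x MAD over the surviving
#'   detections.
#' @param roi_scale ROI half-width = ceiling(roi_scale x detected radius).
#' @return `tracks` with added columns `excluded` (logical), `reason`
#'   (NA, "clustered", "edge" or "off_focus") and `focus` (the metric).
#' @export
apply_exclusions <- function(tracks, frame, min_separation_px = 10,
                             focus_band = NULL, roi_scale = 1.5) {
  stopifnot(is.data.frame(tracks), is.matrix(frame))
  n <- nrow(tracks)
  tracks$excluded <- rep(FALSE, n)
  tracks$reason <- rep(NA_character_, n)
  tracks$focus <- rep(NA_real_, n)
  if (n == 0) return(tracks)
  d <- as.matrix(stats::dist(cbind(tracks$y_px, tracks$x_px)))
  diag(d) <- Inf
  clustered <- apply(d < min_separation_px, 1, any)
  tracks$excluded[clustered] <- TRUE
  tracks$reason[clustered] <- "clustered"
  hw <- ceiling(roi_scale * tracks$radius)
  h <- nrow(frame); w <- ncol(frame)
  edge <- tracks$y_px - hw < 1 | tracks$y_px + hw > h |
          tracks$x_px - hw < 1 | tracks$x_px + hw > w
  mark <- edge & !tracks$excluded
  tracks$excluded[mark] <- TRUE
  tracks$reason[mark] <- "edge"
  alive <- !tracks$excluded
  if (any(alive)) {
    tracks$focus[alive] <- vapply(which(alive), function(i)
      laplacian_energy(frame, tracks$y_px[i], tracks$x_px[i], hw[i]),
      numeric(1))
    if (is.null(focus_band)) {
      med <- stats::median(tracks$focus[alive])
      bw <- 3 * stats::mad(tracks$focus[alive])
      if (bw == 0) bw <- 0.5 * med  # all metrics identical: wide fallback
      focus_band <- c(med - bw, med + bw)
    }
    off <- alive & (tracks$focus < focus_band[1] |
                    tracks$focus > focus_band[2])
    tracks$excluded[off] <- TRUE
    tracks$reason[off] <- "off_focus"
  }
  tracks
}

#' Per-frame intensity variance in a fixed ROI
#'
#' The variance of pixel intensities in the (2w+1)^2 square centred at the
#' bead's first-frame position, for every frame. The ROI never re-centres:
#' tethered beads are laterally confined, and the dissociation signature is
#' the sharp variance drop when the bead leaves the field.
#'
#' @param stack Array height x width x frames.
#' @param y_px,x_px Bead centre (1-based pixels).
#' @param half_width ROI half-width w in pixels.
#' @return Numeric vector, one variance per frame.
#' @export
variance_trace <- function(stack, y_px, x_px, half_width) {
  stopifnot(length(dim(stack)) == 3L)
  b <- roi_bounds(y_px, x_px, half_width, dim(stack)[1], dim(stack)[2])
  if (!b$inside)
    stop("ROI clips the frame edge; exclude this track instead",
         call. = FALSE)
  roi <- stack[b$ys, b$xs, , drop = FALSE]
  m <- matrix(roi, nrow = length(b$ys) * length(b$xs))
  n <- nrow(m)
  colSums(m^2) / (n - 1) - colSums(m)^2 / (n * (n - 1))
}

#' Call dissociation from a variance trace
#'
#' The baseline is the 90th percentile of the variance over the first
#' `baseline_frames` frames; the upper quantile (rather than the median)
#' keeps the baseline anchored to the bead-present level even when the bead
#' dissociates within the baseline window itself, so very early events are
#' still called. A dissociation is called at the first frame whose variance drops
#' below `theta` x baseline and stays below for at least `persistence`
#' consecutive saved frames; the dissociation time is that frame's offset
#' from time zero. A trace that never sustains a drop is censored; a trace
#' that sustains a drop and later recovers above threshold shows multiple
#' variance transitions and is excluded (possible multiple tethers).
#'
#' @param trace Per-frame variance vector (finite; frame 1 is time zero).
#' @param frame_interval Seconds between saved frames.
#' @param theta Drop threshold as a fraction of baseline (default 0.5).
#' @param persistence Minimum consecutive frames below threshold (default 3).
#' @param baseline_frames Frames used for the baseline median (default 5).
#' @return A list with `call` ("dissociated", "censored" or "excluded"),
#'   `time` (seconds, NA unless dissociated) and `reason`
#'   ("multiple_drops" when excluded).
#' @export
call_dissociation <- function(trace, frame_interval, theta = 0.5,
                              persistence = 3, baseline_frames = 5) {
  if (!is.numeric(trace) || any(!is.finite(trace)))
    stop("`trace` must be finite numeric", call. = FALSE)
  if (length(trace) < persistence + 1)
    stop("trace shorter than persistence + 1 frames", call. = FALSE)
  baseline <- stats::quantile(trace[seq_len(min(baseline_frames,
                                                length(trace)))],
                              0.9, names = FALSE)
  below <- trace < theta * baseline
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qual <- which(r$values & r$lengths >= persistence)
  if (length(qual) == 0)
    return(list(call = "censored", time = NA_real_, reason = NA_character_))
  first <- qual[1]
  if (ends[first] < length(trace))  # variance recovered after the drop
    return(list(call = "excluded", time = NA_real_,
                reason = "multiple_drops"))
  list(call = "dissociated",
       time = (starts[first] - 1) * frame_interval,
       reason = NA_character_)
}

#' Track a full force-clamp movie and extract a dissociation dataset
#'
#' Composition of the tracking stages: detect beads in the time-zero frame,
#' apply the clustering / edge / focus exclusions, compute fixed-ROI
#' variance traces, and call each bead. Only non-excluded beads enter the
#' dataset; censored beads are recorded at the movie end with the censoring
#' flag set. Time zero is the first frame at final RPM (`t0_frame`); earlier
#' spin-up frames are ignored.
#'
#' @param stack Array height x width x frames, time-ordered.
#' @param cfg An [acquisition_config()] supplying `frame_interval` and the
#'   force via `rpm`.
#' @param t0_frame 1-based index of the first frame at final RPM.
#' @param construct,replicate Labels stored in the dataset.
#' @param radius_range,sensitivity Passed to [detect_beads()].
#' @param min_separation_px,focus_band,roi_scale Passed to
#'   [apply_exclusions()].
#' @param theta,persistence,baseline_frames Passed to [call_dissociation()].
#' @return A list with `dataset` (a `dissociation_dataset`), `tracks` (all
#'   detections with their calls) and `log` (attrition counts by reason and
#'   the parameters used).
#' @export
track_experiment <- function(stack, cfg, t0_frame = 1L,
                             construct = "construct", replicate = 1L,
                             radius_range = c(3, 6), sensitivity = 0.3,
                             min_separation_px = 10, focus_band = NULL,
                             roi_scale = 1.5, theta = 0.5, persistence = 3,
                             baseline_frames = 5) {
  stopifnot(length(dim(stack)) == 3L, t0_frame >= 1,
            t0_frame < dim(stack)[3])
  sub <- stack[, , t0_frame:dim(stack)[3], drop = FALSE]
  n_frames <- dim(sub)[3]
  first <- sub[, , 1]
  tracks <- detect_beads(first, radius_range, sensitivity)
  tracks <- apply_exclusions(tracks, first, min_separation_px, focus_band,
                             roi_scale)
  tracks$call <- rep(NA_character_, nrow(tracks))
  tracks$time_s <- rep(NA_real_, nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    if (tracks$excluded[i]) next
    hw <- ceiling(roi_scale * tracks$radius[i])
    tr <- variance_trace(sub, tracks$y_px[i], tracks$x_px[i], hw)
    cl <- call_dissociation(tr, cfg$frame_interval, theta, persistence,
                            baseline_frames)
    tracks$call[i] <- cl$call
    tracks$time_s[i] <- cl$time
    if (cl$call == "excluded") {
      tracks$excluded[i] <- TRUE
      tracks$reason[i] <- cl$reason
    }
  }
  t_end <- (n_frames - 1) * cfg$frame_interval
  keep <- !tracks$excluded & !is.na(tracks$call)
  dataset <- data.frame(
    bead_id = tracks$bead_id[keep],
    time_s = ifelse(tracks$call[keep] == "dissociated",
                    tracks$time_s[keep], t_end),
    censored = as.integer(tracks$call[keep] == "censored"),
    construct = construct, replicate = as.integer(replicate),
    force_pN = rpm_to_force(cfg$rpm, cfg)
  )
  attr(dataset, "duration") <- t_end
  class(dataset) <- c("dissociation_dataset", "data.frame")
  reason_counts <- table(tracks$reason[tracks$excluded])
  log <- list(
    n_detected = nrow(tracks),
    n_excluded = sum(tracks$excluded),
    excluded_by_reason = as.list(reason_counts),
    n_events = sum(dataset$censored == 0),
    n_censored = sum(dataset$censored == 1),
    parameters = list(t0_frame = t0_frame, radius_range = radius_range,
                      sensitivity = sensitivity,
                      min_separation_px = min_separation_px,
                      roi_scale = roi_scale, theta = theta,
                      persistence = persistence,
                      baseline_frames = baseline_frames,
                      frame_interval = cfg$frame_interval)
  )
  list(dataset = dataset, tracks = tracks, log = log)
}
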