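#' Population model for a tethered-bead dissociation experiment
#'
#' Describes the statistical structure of one force-clamp run: most beads
#' are single tethers dissociating as a first-order (exponential) process,
#' a small fraction are stuck (anomalous tethers that never release), and a
#' rare fraction dissociate on a much slower time scale, as expected for
#' beads held by multiple tethers.
#'
#' @param n_tethers Number of tethered beads.
#' @param off_rate First-order off-rate of normal single tethers, s^-1.
#' @param stuck_fraction Probability a bead is stuck (censored for the whole
#'   run). Default 0.02.
#' @param slow_fraction Probability a bead carries multiple tethers and
#'   dissociates at `slow_rate`. Default 0.01.
#' @param slow_rate Off-rate of the slow (multi-tether) class, s^-1; must be
#'   below `off_rate`. Default `off_rate / 10`.
#' @param duration Length of the recording, seconds; times beyond it are
#'   censored at `duration`, never discarded.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `tether_population_model`.
#' @export
tether_population_model <- function(n_tethers,
                                    off_rate,
                                    stuck_fraction = 0.02,
                                    slow_fraction = 0.01,
                                    slow_rate = off_rate / 10,
                                    duration = 7200,
                                    seed = 1L) {
  stopifnot(
    is.numeric(n_tethers), length(n_tethers) == 1L, n_tethers >= 1,
    is.numeric(off_rate), off_rate > 0, is.finite(off_rate),
    is.numeric(stuck_fraction), stuck_fraction >= 0, stuck_fraction <= 1,
    is.numeric(slow_fraction), slow_fraction >= 0, slow_fraction <= 1,
    is.numeric(slow_rate), slow_rate > 0,
    is.numeric(duration), duration > 0,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  if (stuck_fraction + slow_fraction > 1)
    stop("stuck_fraction + slow_fraction must be <= 1", call. = FALSE)
  if (slow_fraction > 0 && slow_rate >= off_rate)
    stop("slow_rate must be below off_rate", call. = FALSE)
  structure(
    list(n_tethers = as.integer(n_tethers), off_rate = off_rate,
         stuck_fraction = stuck_fraction, slow_fraction = slow_fraction,
         slow_rate = slow_rate, duration = duration, seed = as.integer(seed)),
    class = "tether_population_model"
  )
}

#' Derive a per-replicate seed from a master seed
#'
#' Fixed integer mixing rule (multiplicative congruential step modulo the
#' Mersenne prime 2^31 - 1) so that multi-replicate runs are reproducible
#' from a single master seed while replicates stay decorrelated.
#'
#' @param master Master seed (integer).
#' @param index Replicate index (1-based integer).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), index >= 1)
  m <- 2147483647 # 2^31 - 1
  s <- (abs(master) %% m) * 48271 + index * 1000003
  as.integer(s %% m + 1)
}

#' Sample dissociation times from a tether population model
#'
#' Normal beads draw lifetimes from Exponential(`off_rate`), slow
#' (multi-tether) beads from Exponential(`slow_rate`), and stuck beads never
#' dissociate. Any lifetime exceeding `duration` is recorded as censored at
#' `duration`. The draw is fully determined by `model$seed`.
#'
#' @param model A [tether_population_model()].
#' @param construct Construct label stored in the dataset.
#' @param replicate Replicate identifier (integer).
#' @param force_pN Applied force recorded with the dataset, piconewtons.
#' @return A list with components `dataset` (a `dissociation_dataset`
#'   data frame: bead_id, time_s, censored, construct, replicate, force_pN,
#'   with the recording length in `attr(, "duration")`) and `truth` (the
#'   per-bead ground truth: bead_id, class, true_time_s, censored).
#' @examples
#' m <- tether_population_model(100, off_rate = 0.02, stuck_fraction = 0,
#'                              slow_fraction = 0, duration = 600, seed = 7)
#' d <- sample_dissociation_times(m)
#' mean(d$dataset$time_s[d$dataset$censored == 0])
#' @export
sample_dissociation_times <- function(model, construct = "construct",
                                      replicate = 1L, force_pN = NA_real_) {
  if (!inherits(model, "tether_population_model"))
    stop("`model` must be a tether_population_model", call. = FALSE)
  n <- model$n_tethers
  set.seed(model$seed)
  u <- stats::runif(n)
  class_lab <- ifelse(u < model$stuck_fraction, "stuck",
               ifelse(u < model$stuck_fraction + model$slow_fraction,
                      "slow", "normal"))
  t_true <- rep(Inf, n)
  is_norm <- class_lab == "normal"
  is_slow <- class_lab == "slow"
  t_true[is_norm] <- stats::rexp(sum(is_norm), rate = model$off_rate)
  t_true[is_slow] <- stats::rexp(sum(is_slow), rate = model$slow_rate)
  censored <- as.integer(t_true > model$duration)
  time_s <- ifelse(censored == 1L, model$duration, t_true)
  dataset <- data.frame(
    bead_id = seq_len(n), time_s = time_s, censored = censored,
    construct = construct, replicate = as.integer(replicate),
    force_pN = force_pN
  )
  attr(dataset, "duration") <- model$duration
  class(dataset) <- c("dissociation_dataset", "data.frame")
  truth <- data.frame(bead_id = seq_len(n), class = class_lab,
                      true_time_s = t_true, censored = censored)
  list(dataset = dataset, truth = truth)
}

#' Simulate a paired stack/control experiment with known stacking energy
#'
#' The two arms share every parameter except the off-rate: the stacked
#' construct dissociates at `control_rate * exp(dG_stack / (R * T))`, so a
#' stabilising (negative) stacking energy slows dissociation. Each replicate
#' of each arm gets an independent seed derived from the master seed via
#' [derive_seed()].
#'
#' @param dG_stack Ground-truth stacking free energy, kcal/mol (negative =
#'   stabilising).
#' @param control_rate Off-rate of the no-stack control arm, s^-1.
#' @param temperature Absolute temperature, kelvin.
#' @param model_base A [tether_population_model()] supplying n_tethers,
#'   stuck/slow structure and duration; its `off_rate` and `seed` are
#'   overridden per arm and replicate.
#' @param n_replicates Number of replicate runs per arm (paper-style
#'   experiments use at least 3).
#' @param force_pN Nominal force recorded with both arms.
#' @param seed Master seed.
#' @return A list with `stack` and `control` (lists of
#'   `dissociation_dataset`), the ground-truth `stack_rate` and
#'   `control_rate`, `dG_stack` and `temperature`.
#' @export
paired_experiment <- function(dG_stack, control_rate,
                              temperature = 294.15,
                              model_base = tether_population_model(
                                500, off_rate = control_rate),
                              n_replicates = 3L,
                              force_pN = 15,
                              seed = 1L) {
  stopifnot(is.numeric(dG_stack), is.finite(dG_stack),
            is.numeric(control_rate), control_rate > 0,
            n_replicates >= 1)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be positive", call. = FALSE)
  stack_rate <- control_rate * exp(dG_stack / rt_kcal(temperature))
  one_arm <- function(rate, label, offset) {
    lapply(seq_len(n_replicates), function(i) {
      m <- model_base
      m$off_rate <- rate
      m$slow_rate <- min(m$slow_rate, rate / 10)
      m$seed <- derive_seed(seed, offset + i)
      sample_dissociation_times(m, construct = label, replicate = i,
                                force_pN = force_pN)$dataset
    })
  }
  list(
    stack = one_arm(stack_rate, "stack", 0L),
    control = one_arm(control_rate, "control", 1000L),
    stack_rate = stack_rate, control_rate = control_rate,
    dG_stack = dG_stack, temperature = temperature
  )
}

#' Specification of a rendered bead movie
#'
#' Geometry and noise model for a synthetic image stack emulating a
#' head-on CFM view of tethered microspheres: each bead is a bright-centred
#' disc with a dark annulus (high local intensity variance) on a flat
#' background with additive Gaussian pixel noise.
#'
#' @param frame_shape Integer c(height, width) in pixels.
#' @param bead_radius_px Bead disc radius, pixels (>= 2).
#' @param bead_contrast Intensity step of the bright centre above background
#'   (frames are on a 0..1 scale).
#' @param background_level Background intensity.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param frame_interval Seconds between saved frames.
#' @param n_frames Number of frames (>= 2).
#' @param min_separation_px Minimum centre-to-centre distance between beads.
#' @param seed Integer seed for bead placement and pixel noise.
#' @return An object of class `movie_spec`.
#' @export
movie_spec <- function(frame_shape = c(256L, 256L),
                       bead_radius_px = 4,
                       bead_contrast = 0.5,
                       background_level = 0.2,
                       noise_sd = 0.05,
                       frame_interval = 5,
                       n_frames = 100L,
                       min_separation_px = 14,
                       seed = 1L) {
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 16),
            bead_radius_px >= 2, bead_contrast > 0,
            background_level >= 0, noise_sd >= 0,
            frame_interval > 0, n_frames >= 2, min_separation_px > 0)
  structure(
    list(frame_shape = as.integer(frame_shape),
         bead_radius_px = bead_radius_px, bead_contrast = bead_contrast,
         background_level = background_level, noise_sd = noise_sd,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         min_separation_px = min_separation_px, seed = as.integer(seed)),
    class = "movie_spec"
  )
}

#' Place bead centres uniformly with a minimum separation
#'
#' Rejection-samples positions inside the frame with a margin of twice the
#' bead radius from every edge and at least `min_separation_px` between
#' centres; retries are bounded.
#'
#' @param spec A [movie_spec()].
#' @param n Number of beads to place.
#' @param max_tries Bound on rejection-sampling attempts.
#' @return Data frame with columns x_px, y_px (1-based pixel coordinates).
#' @export
place_beads <- function(spec, n, max_tries = 20000L) {
  margin <- ceiling(2 * spec$bead_radius_px) + 2
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  if (n == 0L) return(data.frame(x_px = numeric(0), y_px = numeric(0)))
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " beads with min separation ",
           spec$min_separation_px, " in a ", h, "x", w, " frame",
           call. = FALSE)
    x <- stats::runif(1, margin, w - margin)
    y <- stats::runif(1, margin, h - margin)
    if (length(xs) == 0 ||
        all(sqrt((xs - x)^2 + (ys - y)^2) >= spec$min_separation_px)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x_px = round(xs), y_px = round(ys))
}

# Additive intensity profile of one bead: bright disc of radius r at
# +contrast, dark annulus r..1.6r at -0.6*contrast. A positive blur_sigma
# replaces the sharp profile with a wide Gaussian blob of the same peak,
# emulating an out-of-focus bead (low edge sharpness, low Laplacian energy).
bead_profile <- function(d, radius, contrast, blur_sigma = 0) {
  if (blur_sigma > 0) return(contrast * exp(-d^2 / (2 * blur_sigma^2)))
  out <- numeric(length(d))
  out[d <= radius] <- contrast
  ann <- d > radius & d <= 1.6 * radius
  out[ann] <- -0.6 * contrast
  out
}

#' Render a synthetic bead movie from ground truth
#'
#' Each bead is drawn from frame 1 until the last frame whose time stamp is
#' strictly below its true dissociation time, and is absent afterwards
#' (disappearance is instantaneous between consecutive saved frames, as
#' tethered beads fall out of focus once the tether releases). Frame f
#' (1-based) has time stamp (f - 1) * frame_interval. Gaussian noise of sd
#' `noise_sd` is added to every frame; the whole stack is deterministic
#' given `spec$seed`.
#'
#' @param spec A [movie_spec()].
#' @param truth Data frame with one row per bead: x_px, y_px, true_time_s
#'   (Inf or > movie end for beads that never dissociate), and optionally
#'   `blur_sigma` (> 0 renders the bead defocused for the whole movie).
#' @return A list with `stack` (array height x width x n_frames, values in
#'   [0, 1]) and `truth` (the input truth with bead_id and the censoring
#'   flag at the movie end filled in).
#' @export
render_movie <- function(spec, truth) {
  stopifnot(inherits(spec, "movie_spec"), is.data.frame(truth))
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  n <- nrow(truth)
  if (n > 0) {
    stopifnot(all(c("x_px", "y_px", "true_time_s") %in% names(truth)))
    margin <- spec$bead_radius_px
    if (any(truth$x_px < 1 + margin | truth$x_px > w - margin |
            truth$y_px < 1 + margin | truth$y_px > h - margin))
      stop("bead positions must fit inside the frame with a margin of ",
           "one bead radius", call. = FALSE)
  }
  if (is.null(truth$blur_sigma)) truth$blur_sigma <- rep(0, n)
  set.seed(spec$seed)
  base <- matrix(spec$background_level, h, w)
  patches <- vector("list", n)
  ext <- ceiling(2.2 * spec$bead_radius_px)
  for (i in seq_len(n)) {
    sigma <- truth$blur_sigma[i]
    e <- if (sigma > 0) max(ext, ceiling(3 * sigma)) else ext
    xs <- max(1, truth$x_px[i] - e):min(w, truth$x_px[i] + e)
    ys <- max(1, truth$y_px[i] - e):min(h, truth$y_px[i] + e)
    d <- sqrt(outer((ys - truth$y_px[i])^2, (xs - truth$x_px[i])^2, "+"))
    patches[[i]] <- list(
      ys = ys, xs = xs,
      add = bead_profile(d, spec$bead_radius_px, spec$bead_contrast, sigma))
  }
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  stack <- array(0, dim = c(h, w, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    frame <- base
    for (i in seq_len(n)) {
      if (times[f] < truth$true_time_s[i]) {
        p <- patches[[i]]
        frame[p$ys, p$xs] <- frame[p$ys, p$xs] + p$add
      }
    }
    if (spec$noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    stack[, , f] <- pmin(pmax(frame, 0), 1)
  }
  t_end <- times[spec$n_frames]
  truth$bead_id <- seq_len(max(n, 0L)) + 0L
  truth$censored <- as.integer(truth$true_time_s > t_end)
  list(stack = stack, truth = truth)
}

#' Simulate a complete movie: population model + rendering + sidecar truth
#'
#' Draws dissociation times from `model`, places the beads, renders the
#' stack, and returns both the movie and its ground truth so that the
#' tracker can be validated bead by bead.
#'
#' @param model A [tether_population_model()] (its `duration` is clipped to
#'   the movie length).
#' @param spec A [movie_spec()].
#' @return A list with `stack`, `truth` (x_px, y_px, class, true_time_s,
#'   censored) and `frame_interval`.
#' @export
simulate_movie <- function(model, spec) {
  s <- sample_dissociation_times(model)
  set.seed(derive_seed(spec$seed, 7L))
  pos <- place_beads(spec, model$n_tethers)
  truth <- cbind(pos, s$truth)
  truth$true_time_s[truth$class == "stuck"] <- Inf
  rm <- render_movie(spec, truth)
  list(stack = rm$stack, truth = rm$truth,
       frame_interval = spec$frame_interval)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' @param stack Array height x width x frames with values in [0, 1].
#' @param path Output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(length(dim(stack)) == 3L, bits_per_sample %in% c(8L, 16L))
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @return Array height x width x frames with values in [0, 1].
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  drop_channel <- function(m) if (length(dim(m)) == 3L) m[, , 1] else m
  frames <- lapply(frames, drop_channel)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write / read a dissociation dataset as CSV
#'
#' Column layout: bead_id, time_s, censored, construct, replicate, force_pN;
#' the recording length travels in a `# duration_s:` header comment so that
#' censoring at the experiment end survives a round trip.
#'
#' @param dataset A `dissociation_dataset`.
#' @param path File path.
#' @return `path` invisibly (write) or the dataset (read).
#' @export
write_dissociation_csv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dur <- attr(dataset, "duration")
  if (!is.null(dur)) writeLines(sprintf("# duration_s: %.10g", dur), con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissociation_csv
#' @export
read_dissociation_csv <- function(path) {
  first <- readLines(path, n = 1L)
  dur <- NULL
  if (startsWith(first, "# duration_s:"))
    dur <- as.numeric(sub("# duration_s:", "", first))
  d <- utils::read.csv(path, comment.char = "#")
  if (!is.null(dur)) attr(d, "duration") <- dur
  class(d) <- c("dissociation_dataset", "data.frame")
  d
}
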