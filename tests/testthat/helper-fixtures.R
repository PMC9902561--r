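# Shared fixtures, built in code at test time.

# Off-rate estimate with chosen moments, for energetics tests.
make_estimate <- function(k, sd = 0, force = 15, construct = "x",
                          n_replicates = 3L) {
  structure(list(k_mean = k, k_sd = sd, n_replicates = n_replicates,
                 n_tethers_total = 300L, construct = construct,
                 force = force, low_replicates = n_replicates < 3),
            class = "off_rate_estimate")
}

# The saved-frame grid snaps a continuous dissociation time to the first
# frame from which the bead is absent.
expected_frame_time <- function(true_time, frame_interval) {
  frame_interval * ceiling(true_time / frame_interval)
}

# Match each track to the nearest ground-truth bead.
match_truth <- function(tracks, truth) {
  vapply(seq_len(nrow(tracks)), function(i)
    which.min((truth$y_px - tracks$y_px[i])^2 +
              (truth$x_px - tracks$x_px[i])^2), integer(1))
}

# Clean 100-bead movie used by tracking and acceptance tests
# (contrast/noise = 10).
make_100_bead_movie <- function(seed = 5L) {
  spec <- movie_spec(frame_shape = c(360L, 360L), n_frames = 100L,
                     noise_sd = 0.05, seed = seed)
  model <- tether_population_model(100, off_rate = 0.01,
                                   stuck_fraction = 0, slow_fraction = 0,
                                   duration = 495, seed = seed + 4L)
  simulate_movie(model, spec)
}

# Deterministic 16-bead demo movie with frame-aligned dissociation times,
# so the tracker can be checked for exact event-time reproduction.
demo_movie_16 <- function(seed = 16L) {
  spec <- movie_spec(frame_shape = c(220L, 220L), n_frames = 64L,
                     frame_interval = 5, noise_sd = 0.04, seed = seed)
  set.seed(derive_seed(seed, 3L))
  pos <- place_beads(spec, 16)
  truth <- data.frame(pos, true_time_s = 5 * 2 * seq_len(16))
  mv <- render_movie(spec, truth)
  list(stack = mv$stack, truth = mv$truth, frame_interval = 5)
}
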