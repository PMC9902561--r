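test_that("circle detection localises rendered beads", {
  # one disc at a known centre
  spec <- movie_spec(frame_shape = c(64L, 64L), n_frames = 3L,
                     noise_sd = 0.03, seed = 3)
  mv <- render_movie(spec, data.frame(x_px = 32, y_px = 30,
                                      true_time_s = Inf))
  det <- detect_beads(mv$stack[, , 1])
  expect_equal(nrow(det), 1)
  expect_lte(abs(det$y_px - 30), 1)
  expect_lte(abs(det$x_px - 32), 1)

  # blank noise frame: nothing above threshold
  set.seed(2)
  blank <- matrix(0.2 + rnorm(200 * 200, 0, 0.05), 200, 200)
  expect_equal(nrow(detect_beads(blank)), 0)

  # 100 discs, low noise: at least 95 recovered within 2 px of truth
  mv100 <- make_100_bead_movie()
  det100 <- detect_beads(mv100$stack[, , 1])
  dmin <- apply(sqrt(outer(det100$y_px, mv100$truth$y_px, "-")^2 +
                     outer(det100$x_px, mv100$truth$x_px, "-")^2), 2, min)
  expect_gte(sum(dmin <= 2), 95)

  expect_error(detect_beads(matrix(NaN, 4, 4)), "finite")
})

test_that("clustered, edge and out-of-focus beads are excluded", {
  spec <- movie_spec(frame_shape = c(128L, 128L), n_frames = 3L,
                     noise_sd = 0.02, seed = 9)
  # a close pair (9 px apart) plus two well-separated beads
  truth <- data.frame(x_px = c(40, 49, 90, 90), y_px = c(40, 40, 40, 90),
                      true_time_s = Inf)
  mv <- render_movie(spec, truth)
  det <- detect_beads(mv$stack[, , 1])
  exc <- apply_exclusions(det, mv$stack[, , 1], min_separation_px = 10)
  close_pair <- det$y_px == 40 & det$x_px %in% c(40, 49)
  expect_true(all(exc$excluded[close_pair]))
  expect_true(all(exc$reason[close_pair] == "clustered"))
  expect_false(any(exc$excluded[!close_pair]))

  # all well-separated, in-focus discs: no exclusions
  spec2 <- movie_spec(frame_shape = c(200L, 200L), n_frames = 3L,
                      noise_sd = 0.01, seed = 12)
  set.seed(30)
  pos <- place_beads(spec2, 12)
  mv2 <- render_movie(spec2, data.frame(pos, true_time_s = Inf))
  det2 <- detect_beads(mv2$stack[, , 1])
  exc2 <- apply_exclusions(det2, mv2$stack[, , 1])
  expect_equal(sum(exc2$excluded), 0)

  # one defocused disc among sharp ones is flagged off_focus
  spec3 <- movie_spec(frame_shape = c(200L, 200L), n_frames = 3L,
                      noise_sd = 0.03, seed = 4)
  set.seed(10)
  pos3 <- place_beads(spec3, 10)
  truth3 <- data.frame(pos3, true_time_s = Inf,
                       blur_sigma = c(rep(0, 9), 2.5))
  mv3 <- render_movie(spec3, truth3)
  exc3 <- apply_exclusions(detect_beads(mv3$stack[, , 1]),
                           mv3$stack[, , 1])
  flagged <- which(exc3$reason == "off_focus")
  expect_equal(length(flagged), 1)
  expect_lte(sqrt((exc3$y_px[flagged] - truth3$y_px[10])^2 +
                  (exc3$x_px[flagged] - truth3$x_px[10])^2), 3)
})

test_that("variance traces separate present, absent and vanishing beads", {
  spec <- movie_spec(frame_shape = c(64L, 64L), n_frames = 20L,
                     frame_interval = 1, noise_sd = 0.03, seed = 21)
  mv <- render_movie(spec, data.frame(x_px = 32, y_px = 32,
                                      true_time_s = 10))
  tr <- variance_trace(mv$stack, 32, 32, 6)
  expect_length(tr, 20)
  # present: high and roughly constant; absent: noise-level
  expect_lt(max(tr[1:10]) / min(tr[1:10]), 1.5)
  expect_lt(max(tr[11:20]), 2 * spec$noise_sd^2)
  # drop across the dissociation frame is at least the contrast factor
  expect_gt(tr[10] / tr[11], 5)
  # absent throughout: variance stays at noise level
  far <- variance_trace(mv$stack, 12, 12, 6)
  expect_lt(max(far), 2.5 * spec$noise_sd^2)
  expect_error(variance_trace(mv$stack, 2, 2, 6), "clips")
})

test_that("dissociation calling follows the variance-drop rule", {
  # constructed step: drop at the 4th frame, 5 s frames -> t = 15 s
  cl <- call_dissociation(c(100, 100, 100, 5, 5, 5), frame_interval = 5,
                          theta = 0.5, persistence = 2)
  expect_equal(cl$call, "dissociated")
  expect_equal(cl$time, 15)
  # constant trace never drops: censored
  expect_equal(call_dissociation(rep(100, 30), 5)$call, "censored")
  # drop followed by recovery: excluded as possible multiple tethers
  cl2 <- call_dissociation(c(100, 5, 5, 100, 100, 5, 5), frame_interval = 5,
                           theta = 0.5, persistence = 2)
  expect_equal(cl2$call, "excluded")
  expect_equal(cl2$reason, "multiple_drops")
  # sub-persistence dips are ignored
  expect_equal(call_dissociation(c(100, 5, 100, 100, 100, 100), 5,
                                 persistence = 3)$call, "censored")
  expect_error(call_dissociation(c(100, NA, 5), 5), "finite")
  expect_error(call_dissociation(c(100, 5), 5, persistence = 3), "shorter")
})

test_that("lowering the drop threshold never produces an earlier call", {
  set.seed(40)
  thetas <- c(0.7, 0.5, 0.3, 0.15)
  for (rep in 1:20) {
    drop_at <- sample(6:25, 1)
    trace <- c(rnorm(drop_at - 1, 100, 5), rnorm(31 - drop_at, 8, 4))
    trace <- pmax(trace, 0.1)
    times <- vapply(thetas, function(th) {
      cl <- call_dissociation(trace, 1, theta = th, persistence = 3)
      if (cl$call == "dissociated") cl$time else Inf
    }, numeric(1))
    expect_true(all(diff(times) >= 0))  # theta decreasing -> time non-decreasing
  }
})

test_that("end-to-end tracking recovers ground-truth dissociation times", {
  mv <- demo_movie_16()
  cfg <- acquisition_config(rpm = 1221, frame_interval = 5)
  tr <- track_experiment(mv$stack, cfg, focus_band = c(0, Inf))
  expect_equal(nrow(tr$dataset), 16)
  expect_true(all(tr$dataset$censored == 0))
  idx <- match_truth(tr$tracks, mv$truth)
  expect_equal(sort(tr$dataset$time_s),
               sort(expected_frame_time(mv$truth$true_time_s[idx], 5)))
  # determinism: identical stack and parameters give identical calls
  tr2 <- track_experiment(mv$stack, cfg, focus_band = c(0, Inf))
  expect_identical(tr$dataset, tr2$dataset)
})

test_that("tracking a movie of stuck beads yields an all-censored dataset", {
  spec <- movie_spec(frame_shape = c(160L, 160L), n_frames = 30L,
                     noise_sd = 0.03, seed = 13)
  set.seed(14)
  pos <- place_beads(spec, 8)
  mv <- render_movie(spec, data.frame(pos, true_time_s = Inf))
  cfg <- acquisition_config(rpm = 1221, frame_interval = 5)
  tr <- track_experiment(mv$stack, cfg, focus_band = c(0, Inf))
  expect_equal(nrow(tr$dataset), 8)
  expect_true(all(tr$dataset$censored == 1))
  expect_equal(tr$log$n_events, 0)
})

test_that("attrition log reports clustered exclusions and clean counts", {
  spec <- movie_spec(frame_shape = c(240L, 240L), n_frames = 40L,
                     noise_sd = 0.03, seed = 17)
  set.seed(18)
  pos <- place_beads(spec, 12)
  pos <- rbind(pos, data.frame(x_px = pos$x_px[1] + 10, y_px = pos$y_px[1]))
  truth <- data.frame(pos, true_time_s = c(5 * (3:14), 40))
  mv <- render_movie(spec, truth)
  cfg <- acquisition_config(rpm = 1221, frame_interval = 5)
  tr <- track_experiment(mv$stack, cfg, focus_band = c(0, Inf),
                         min_separation_px = 12)
  expect_equal(tr$log$excluded_by_reason$clustered, 2L)
  expect_equal(nrow(tr$dataset), tr$log$n_detected - tr$log$n_excluded)
  # no censored or excluded bead contributes an event time
  expect_true(all(tr$dataset$censored %in% c(0L, 1L)))
  expect_false(any(tr$tracks$excluded &
                   tr$tracks$bead_id %in%
                     tr$dataset$bead_id[tr$dataset$censored == 0]))
})
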