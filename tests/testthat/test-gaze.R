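make_traj <- function(x, y, valid = TRUE, rate = 1000) {
  n <- length(x)
  gaze_trajectory(data.frame(t_ms = seq_len(n) * (1000 / rate), x_px = x,
                             y_px = y,
                             valid = rep_len(valid, n)))
}

test_that("gaze preprocessing censors blinks, filters, and emits 60 samples", {
  # constant trajectory is unchanged and decimated to 60 samples
  tr <- make_traj(rep(100, 2500), rep(200, 2500))
  out <- gaze_preprocess(tr)
  expect_equal(nrow(out$samples), 60)
  expect_true(all(out$samples$x_px == 100))
  expect_true(all(out$samples$y_px == 200))
  expect_true(all(out$samples$valid))
  # a single-sample spike is removed exactly by the 84-sample median window
  x <- rep(50, 2500); x[1200] <- 150
  sp <- gaze_preprocess(make_traj(x, rep(0, 2500)))
  expect_true(all(sp$samples$x_px == 50))
  # sliding-median oracle on a rough trajectory
  set.seed(41)
  xr <- cumsum(rnorm(500))
  tr2 <- make_traj(xr, rep(0, 500))
  out2 <- gaze_preprocess(tr2, window_ms = 84, out_samples = 20)
  med <- sapply(seq_len(500), function(i)
    median(xr[max(1, i - 41):min(500, i + 42)]))
  # output frames anchored at the first sample time, one per frame midpoint
  frame_t <- 1 + (seq_len(20) - 0.5) * 500 / 20
  pick <- sapply(frame_t, function(ft) which.min(abs(seq_len(500) - ft)))
  expect_equal(out2$samples$x_px, med[pick], tolerance = 1e-12)
  # blink spans are linearly interpolated from flanking valid samples
  xv <- seq(0, 249, length.out = 250)
  valid <- rep(TRUE, 250); valid[100:120] <- FALSE
  xb <- xv; xb[100:120] <- 9999
  out3 <- gaze_preprocess(make_traj(xb, xv * 0, valid = valid),
                          window_ms = 1, out_samples = 250)
  expect_equal(out3$samples$x_px, xv, tolerance = 1e-9)
  # fully invalid trial raises the trial-excluded condition
  expect_error(gaze_preprocess(make_traj(1:100, 1:100, valid = FALSE)),
               class = "trial_excluded")
})

test_that("gaze RDM sums per-frame Euclidean distances", {
  base <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  t1 <- make_traj(base[, 1], base[, 2])
  t1$stimulus_id <- "a"
  t2 <- make_traj(base[, 1] + 3, base[, 2] + 4)
  t2$stimulus_id <- "b"
  r <- gaze_rdm(list(t1, t2))
  expect_equal(rdm_vec(r), 5 * 60)
  # identical trajectories -> 0
  t3 <- t1; t3$stimulus_id <- "c"
  expect_equal(as.matrix(gaze_rdm(list(t1, t3)))["a", "c"], 0)
  # random trajectories vs double-loop oracle
  set.seed(43)
  trs <- lapply(1:5, function(k) {
    tr <- make_traj(rnorm(30, sd = 50), rnorm(30, sd = 50))
    tr$stimulus_id <- sprintf("s%d", k)
    tr
  })
  rr <- gaze_rdm(trs)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (f in 1:30)
      acc <- acc + sqrt((trs[[i]]$samples$x_px[f] - trs[[j]]$samples$x_px[f])^2 +
                        (trs[[i]]$samples$y_px[f] - trs[[j]]$samples$y_px[f])^2)
    expect_equal(as.matrix(rr)[i, j], acc, tolerance = 1e-10)
  }
  # rigid translation of all trajectories leaves the RDM unchanged
  shifted <- lapply(trs, function(tr) {
    tr$samples$x_px <- tr$samples$x_px + 500
    tr$samples$y_px <- tr$samples$y_px - 200
    tr
  })
  expect_equal(as.matrix(gaze_rdm(shifted)), as.matrix(rr),
               tolerance = 1e-9)
  expect_error(gaze_rdm(list(t1, make_traj(1:10, 1:10))), "sample count")
})

test_that("reliability screening drops unreliable participants and averages the rest", {
  r1 <- random_rdm(6, seed = 51)
  # identical blocks: reliability 1, retained at threshold .1
  # rank-reversed blocks: negative reliability, dropped
  rev_m <- max(as.matrix(r1)) - as.matrix(r1)
  diag(rev_m) <- 0
  blocks <- list(
    good = list(r1, r1, r1),
    bad = list(r1, rdm(rev_m, r1$labels)))
  res <- gaze_reliability_screen(blocks, threshold = 0.1)
  expect_equal(unname(res$reliability["good"]), 1, tolerance = 1e-12)
  expect_lt(res$reliability[["bad"]], 0)
  expect_equal(res$retained, "good")
  expect_equal(as.matrix(res$rdm), as.matrix(r1))
  # mean pairwise correlation matches a loop oracle on 4 random blocks
  set.seed(53)
  bl <- lapply(1:4, function(i) random_rdm(6, seed = 60 + i))
  rel <- gaze_reliability_screen(list(p = bl), threshold = -1)$reliability
  acc <- c()
  for (i in 1:4) for (j in seq_len(i - 1))
    acc <- c(acc, oracle_pearson(rdm_vec(bl[[i]]), rdm_vec(bl[[j]])))
  expect_equal(unname(rel["p"]), mean(acc), tolerance = 1e-12)
  expect_error(gaze_reliability_screen(blocks["bad"], threshold = 0.1),
               "empty cohort")
})

test_that("simulated gaze sessions are reliable within participant and reproducible", {
  st <- make_stimulus_set(4, 2)
  trials <- simulate_gaze_session(st, n_blocks = 4, blink_rate = 0,
                                  seed = 71, duration_ms = 600)
  expect_length(trials, 32)
  expect_true(all(vapply(trials, function(tr) nrow(tr$samples),
                         integer(1)) == 600))
  expect_true(all(vapply(trials, function(tr) all(tr$samples$valid),
                         logical(1))))
  # full-length trials carry 2500 samples
  one <- simulate_gaze_session(st[1, , drop = FALSE], n_blocks = 1,
                               blink_rate = 0, seed = 3)
  class(one) <- "list"
  expect_equal(nrow(one[[1]]$samples), 2500)
  # inter-block gaze-RDM reliability beats the screening threshold
  prep <- lapply(trials, gaze_preprocess, window_ms = 84, out_samples = 60)
  by_block <- split(prep, vapply(prep, `[[`, integer(1), "block"))
  brdms <- lapply(by_block, gaze_rdm)
  rel <- gaze_reliability_screen(list(sim = brdms), threshold = -1)
  expect_gt(rel$reliability[["sim"]], 0.1)
  # determinism
  again <- simulate_gaze_session(st, n_blocks = 4, blink_rate = 0,
                                 seed = 71, duration_ms = 600)
  expect_identical(trials, again)
  # blink flags appear at positive blink rates
  blinky <- simulate_gaze_session(st, n_blocks = 2, blink_rate = 1,
                                  seed = 5, duration_ms = 500)
  expect_true(all(vapply(blinky, function(tr) any(!tr$samples$valid),
                         logical(1))))
})

test_that("gaze CSV round-trips trajectories", {
  st <- make_stimulus_set(2, 2)
  trials <- simulate_gaze_session(st, n_blocks = 2, blink_rate = 0.5,
                                  seed = 81, duration_ms = 120)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze(trials, path)
  back <- read_gaze(path)
  expect_length(back, length(trials))
  expect_equal(back[[3]]$samples$x_px, trials[[3]]$samples$x_px)
  expect_equal(back[[3]]$samples$valid, trials[[3]]$samples$valid)
  expect_equal(back[[3]]$stimulus_id, trials[[3]]$stimulus_id)
})
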