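test_that("counterbalanced sequences cover every ordered type pair exactly once cyclically", {
  for (n in 2:8) {
    s <- generate_type1_sequence(n, seed = 100 + n)
    expect_length(s, n^2)
    pairs <- paste(s, c(s[-1], s[1]))
    counts <- table(pairs)
    expect_equal(length(counts), n^2)
    expect_true(all(counts == 1L))
  }
})

test_that("the two-type sequence has the unique serially balanced structure", {
  s <- generate_type1_sequence(2, seed = 4, labels = c("A", "B"))
  expect_length(s, 4)
  adj <- sort(paste0(s, c(s[-1], s[1])))
  expect_equal(adj, c("AA", "AB", "BA", "BB"))
})

test_that("block-balanced sequences add run-wise balance on top of pair coverage", {
  for (n in c(6, 20)) {
    s <- generate_type1_sequence(n, seed = n, blocked = TRUE)
    expect_length(s, n^2)
    expect_equal(length(unique(paste(s, c(s[-1], s[1])))), n^2)
    blocks <- matrix(s, nrow = n, byrow = TRUE)
    expect_true(all(apply(blocks, 1, function(b) length(unique(b)) == n)))
  }
  # no block-balanced sequence exists for 4 types
  expect_error(generate_type1_sequence(4, seed = 1, blocked = TRUE,
                                       max_restarts = 40),
               "generation-failure")
  expect_error(generate_type1_sequence(1), "n_types")
})

test_that("sequence generation is deterministic under a fixed seed", {
  expect_identical(generate_type1_sequence(6, seed = 9),
                   generate_type1_sequence(6, seed = 9))
  expect_identical(generate_type1_sequence(8, seed = 9, blocked = TRUE),
                   generate_type1_sequence(8, seed = 9, blocked = TRUE))
})

test_that("probe repair replaces trailing probes after fixation or probe, and only those", {
  expect_equal(repair_probe_constraints(c("a", "fixation", "probe", "b")),
               c("a", "fixation", "fixation", "b"))
  expect_equal(repair_probe_constraints(c("probe", "probe")),
               c("probe", "fixation"))
  s <- c("a", "probe", "b", "fixation", "b")
  expect_equal(repair_probe_constraints(s), s)
  # idempotence on random sequences
  set.seed(2)
  for (i in 1:20) {
    s <- sample(c("a", "b", "fixation", "probe"), 30, replace = TRUE)
    r <- repair_probe_constraints(s)
    expect_identical(repair_probe_constraints(r), r)
    bad <- which(r == "probe" & c("", head(r, -1)) %in% c("fixation", "probe"))
    expect_length(bad, 0)
    expect_true(all(r[s != "probe"] == s[s != "probe"]))
  }
})

test_that("session build yields balanced runs with context trials and exact durations", {
  n_types <- 20
  cats <- sprintf("cat%02d", 1:18)
  s <- generate_type1_sequence(n_types, seed = 7, blocked = TRUE,
                               labels = c(cats, "fixation", "probe"))
  s <- repair_probe_constraints(s)
  runs <- build_session(s, n_exemplars = 5, n_runs = 4, seed = 8)
  expect_length(runs, 4)
  for (run in runs) {
    main <- run[-(1:attr(run, "n_prepended")), ]
    expect_equal(nrow(main), 100)
    # each exemplar of each category exactly once per run
    ex <- main$exemplar_id[main$trial_type %in% cats]
    expect_equal(sort(ex), sort(sprintf("%s_e%d", rep(cats, each = 5), 1:5)))
    # prepended trials come from a disjoint preparatory pool
    pre <- run[1:3, ]
    expect_false(any(stats::na.omit(pre$exemplar_id) %in% main$exemplar_id))
    # probes occur five times per run unless a repair fell inside
    expect_lte(sum(main$trial_type == "probe"), 5)
    expect_equal(run_duration(run), 535)
    expect_true(all(diff(run$onset_s) > 0))
    expect_true(all(run$isi_s >= 2))
  }
  # two sessions: 8 trials per stimulus overall
  s2 <- repair_probe_constraints(generate_type1_sequence(
    n_types, seed = 17, blocked = TRUE, labels = c(cats, "fixation", "probe")))
  runs2 <- build_session(s2, n_exemplars = 5, n_runs = 4, seed = 18,
                         session_id = 2)
  ex_all <- unlist(lapply(c(runs, runs2), function(run) {
    main <- run[-(1:3), ]
    main$exemplar_id[main$trial_type %in% cats]
  }))
  counts <- table(ex_all)
  expect_equal(length(counts), 90)
  expect_true(all(counts == 8L))
})

test_that("onset schedules respect the ISI floor and the exact total null time", {
  ons <- generate_onsets(100, mean_isi_s = 2.5, min_isi_s = 2,
                         total_null_s = 250, n_candidates = 3, seed = 5)
  expect_true(all(ons$isi_s >= 2))
  expect_equal(sum(ons$isi_s), 250)
  expect_equal(mean(ons$isi_s), 2.5)
  expect_equal(ons$candidate_index, which.max(ons$efficiency))
  # selection is monotone: chosen candidate's score >= all others
  expect_true(all(ons$efficiency[ons$candidate_index] >= ons$efficiency))
  one <- generate_onsets(10, 2.5, 2, 25, n_candidates = 1, seed = 5)
  expect_equal(one$candidate_index, 1L)
  expect_error(generate_onsets(10, 2.5, 2, total_null_s = 19),
               "total_null_s")
})

test_that("design efficiency matches its closed forms and an explicit inverse oracle", {
  # orthonormal X, identity contrasts over k columns -> e = 1/k
  q <- qr.Q(qr(matrix(rnorm(50 * 4), 50)))
  expect_equal(design_efficiency(q), 1 / 4, tolerance = 1e-12)
  # scaling X by 2 multiplies e by 4
  set.seed(6)
  X <- matrix(rnorm(50 * 5), 50)
  C <- matrix(rnorm(2 * 5), 2)
  expect_equal(design_efficiency(2 * X, C), 4 * design_efficiency(X, C),
               tolerance = 1e-10)
  # explicit matrix-inverse oracle
  e_oracle <- 1 / sum(diag(C %*% solve(t(X) %*% X) %*% t(C)))
  expect_equal(design_efficiency(X, C), e_oracle, tolerance = 1e-10)
  # invariance to contrast row order
  expect_equal(design_efficiency(X, C[2:1, ]), design_efficiency(X, C))
  expect_error(design_efficiency(cbind(X, X[, 1])), "rank-deficient")
})

test_that("run duration equals an explicit per-event sum", {
  cats <- sprintf("cat%02d", 1:18)
  s <- repair_probe_constraints(generate_type1_sequence(
    20, seed = 3, blocked = TRUE, labels = c(cats, "fixation", "probe")))
  run <- build_session(s, 5, 4, seed = 4)[[1]]
  loop_total <- attr(run, "lead_fix_s") + attr(run, "trail_fix_s")
  for (i in seq_len(nrow(run)))
    loop_total <- loop_total + run$stim_duration_s[i] + run$isi_s[i]
  expect_equal(run_duration(run), loop_total)
  # additivity: no trials at all
  empty <- structure(data.frame(stim_duration_s = numeric(0),
                                isi_s = numeric(0)),
                     lead_fix_s = 5, trail_fix_s = 15)
  expect_equal(run_duration(empty), 20)
})

test_that("timing files round-trip the event table", {
  cats <- sprintf("cat%02d", 1:18)
  s <- repair_probe_constraints(generate_type1_sequence(
    20, seed = 3, blocked = TRUE, labels = c(cats, "fixation", "probe")))
  runs <- build_session(s, 5, 4, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_timing(runs[1], dir)
  tab <- read.table(paths[1], sep = "\t", header = TRUE)
  expect_equal(nrow(tab), nrow(runs[[1]]))
  expect_equal(tab$onset_s, runs[[1]]$onset_s)
})
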