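# recording with one planted template copy and known span
planted_fixture <- function() {
  motif <- burst_motif(80)                     # 2 s at 40 Hz
  st <- idle_stream(1200, noise_sd = 0)        # 30 s, noiseless
  st <- plant_motif(st, motif, 401)            # samples 401..480 = 10.0-12.0 s
  tpl <- activity_template("grab", motif + rep(c(0, 0, 9.81), each = 80),
                           span_ms = c(10000, 12000), source_recording = "src",
                           fingerprint = preprocess_fingerprint(
                             preprocess_config("raw", FALSE)))
  list(stream = st, template = tpl,
       cfg = preprocess_config("raw", FALSE), span = c(10000, 12000))
}

test_that("match_template recovers a verbatim planted copy exactly", {
  fx <- planted_fixture()
  cand <- match_template(fx$template, fx$stream, fx$cfg)
  expect_equal(cand$distance[1], 0)
  expect_equal(c(cand$start_ms[1], cand$end_ms[1]), fx$span)

  # constant stream vs non-constant template: everything scores > 0
  const <- idle_stream(400)
  cand2 <- match_template(fx$template, const, fx$cfg)
  expect_true(all(cand2$distance > 0))

  # fingerprint mismatch is a config error
  other <- preprocess_config("linear", TRUE)
  expect_error(match_template(fx$template, fx$stream, other), "config error")
})

test_that("delta selection applies the greedy exclusion rule", {
  cand <- data.frame(start_ms = c(0, 1500, 5000), end_ms = c(0, 1500, 5000) + 1000,
                     distance = c(1, 2, 3), template_label = "a",
                     template_id = "t", start_index = 1:3, end_index = 2:4)
  sel <- select_topk_delta(cand, k = 2, delta_ms = 2000)
  expect_setequal(sel$start_ms, c(0, 5000))

  # single candidate is always returned
  expect_equal(nrow(select_topk_delta(cand[1, ], k = 5)), 1)

  # property: pairwise spacing >= delta and size <= k, random inputs
  set.seed(99)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    cc <- data.frame(start_ms = sample(0:60000, n), end_ms = 0, distance = runif(n),
                     template_label = "x", template_id = "x",
                     start_index = 1, end_index = 1)
    cc$end_ms <- cc$start_ms + 800
    k <- sample(1:15, 1)
    out <- select_topk_delta(cc, k, 2000)
    expect_lte(nrow(out), k)
    if (nrow(out) > 1) {
      expect_gte(min(dist(out$start_ms)), 2000)
    }
    # the best candidate always survives
    expect_true(min(cc$distance) %in% out$distance)
  }
})

test_that("zeroline selection keeps only candidates that beat the idle baseline", {
  zrow <- c(5, 5, 0, 0, 5, 5, 5, 0.2)
  cand <- data.frame(start_ms = c(0, 100, 200, 300), end_ms = c(50, 150, 250, 350),
                     distance = c(1, 0.5, 2, 0.1), template_label = "a",
                     template_id = "t", start_index = 1:4,
                     end_index = c(1, 3, 5, 8))
  out <- select_topk_zeroline(cand, zrow, k = 10)
  # candidate 2 ends where the zeroline scores 0 (idle) -> filtered;
  # candidate 4 (0.1) beats the 0.2 baseline -> kept
  expect_setequal(out$start_ms, c(0, 200, 300))
  expect_true(!is.unsorted(out$distance))
  # output is a subset of the input and k truncates by distance
  out1 <- select_topk_zeroline(cand, zrow, k = 1)
  expect_equal(out1$distance, 0.1)
  # all filtered -> empty result
  none <- select_topk_zeroline(cand, rep(0, 8), k = 5)
  expect_equal(nrow(none), 0)
})

test_that("sliding fixed-length matcher finds the planted span", {
  fx <- planted_fixture()
  hit <- sliding_fixed_match(fx$template, fx$stream, fx$cfg, stride_samples = 1)
  expect_equal(hit$distance, 0)
  expect_equal(c(hit$start_ms, hit$end_ms), fx$span)

  # coarser strides can only do worse (windows are a subset)
  d_by_stride <- vapply(c(1, 3, 7), function(s)
    sliding_fixed_match(fx$template, fx$stream, fx$cfg, s)$distance, numeric(1))
  expect_true(!is.unsorted(d_by_stride))

  # the less noisy of two planted copies wins
  withr::with_seed(5, {
    motif <- burst_motif(60)
    st <- idle_stream(1000, noise_sd = 0)
    st <- plant_motif(st, motif + matrix(rnorm(180, sd = 0.4), 60, 3), 101)
    st <- plant_motif(st, motif + matrix(rnorm(180, sd = 0.02), 60, 3), 601)
  })
  tpl <- activity_template("m", motif + rep(c(0, 0, 9.81), each = 60),
                           c(0, 1500), "src")
  best <- sliding_fixed_match(tpl, st, fx$cfg, stride_samples = 1)
  expect_lte(abs(best$start_index - 601), 5)

  short <- idle_stream(10)
  expect_error(sliding_fixed_match(fx$template, short, fx$cfg), "shorter")
})

test_that("best_subset maximizes mutual overlap with lexicographic ties", {
  same <- data.frame(start_ms = rep(1000, 6), end_ms = rep(3000, 6),
                     distance = 1:6 / 10, template_label = "a",
                     template_id = letters[1:6], start_index = 1, end_index = 2)
  outl <- data.frame(start_ms = c(20000, 40000), end_ms = c(22000, 42000),
                     distance = c(0.01, 0.02), template_label = "a",
                     template_id = c("x", "y"), start_index = 1, end_index = 2)
  pool <- rbind(same, outl)
  sel <- best_subset(pool, 6)
  expect_setequal(sel$template_id, letters[1:6])

  # all disjoint: any subset scores 0; lexicographic tie-break -> first k
  disj <- data.frame(start_ms = seq(0, by = 5000, length.out = 5),
                     end_ms = seq(1000, by = 5000, length.out = 5),
                     distance = 1, template_label = "a",
                     template_id = paste0("t", 1:5), start_index = 1, end_index = 2)
  expect_equal(best_subset(disj, 3)$template_id, c("t1", "t2", "t3"))

  # k = n returns everything
  expect_equal(nrow(best_subset(disj, 5)), 5)
  expect_error(best_subset(disj, 1), "k must be >= 2")
  expect_error(best_subset(disj, 6), "fewer candidates")
})

test_that("recommend pools templates, selects once, and is deterministic", {
  cfg <- preprocess_config("linear", TRUE)
  sc <- sim_config(seed = 77, duration_s = 60, n_activities = 3, noise_sd = 0.1)
  rec <- generate_recording(sc)
  tpls <- extract_templates(rec, cfg)
  sel <- selection_config("delta", k = 10)
  a <- recommend(rec, tpls, cfg, sel)
  b <- recommend(rec, tpls, cfg, sel)
  expect_identical(a, b)
  expect_lte(nrow(a), 10)
  expect_true(!is.unsorted(a$start_ms))
  # every planted activity is overlapped at this SNR
  expect_equal(recall_at_k(a, rec$labels), 1)

  # k = 1 returns the single globally best candidate
  one <- recommend(rec, tpls, cfg, selection_config("delta", k = 1))
  expect_equal(nrow(one), 1)
  expect_equal(one$distance, 0)   # self-match: templates came from this recording

  expect_error(recommend(rec, list(), cfg, sel), "no activity templates")
})

test_that("candidate CSV round-trips as provisional labels", {
  cand <- data.frame(start_ms = c(1000, 5000), end_ms = c(2000, 6400),
                     distance = c(0.1, 0.4), template_label = c("grab", "stir"),
                     template_id = c("a", "b"), start_index = 1:2, end_index = 3:4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_candidates_csv(cand, f)
  df <- read.csv(f)
  expect_equal(df$start_ms, cand$start_ms)
  labs <- candidates_as_labels(cand)
  expect_s3_class(labs, "label_intervals")
  expect_equal(labs$label, c("grab", "stir"))
})
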