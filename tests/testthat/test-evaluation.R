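test_that("interval overlap is Jaccard with the documented properties", {
  expect_equal(interval_overlap(c(2, 4), c(3, 5)), 1 / 3)
  expect_equal(interval_overlap(c(10, 20), c(10, 20)), 1)
  expect_equal(interval_overlap(c(0, 5), c(5, 9)), 0)   # abutting half-open
  expect_equal(interval_overlap(c(0, 4), c(2, 4), mode = "truth"), 1)
  # symmetry, bounds, and 1 iff equal
  set.seed(12)
  for (i in 1:30) {
    a <- sort(sample(0:100, 2)); b <- sort(sample(0:100, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    ov <- interval_overlap(a, b)
    expect_equal(ov, interval_overlap(b, a))
    expect_gte(ov, 0); expect_lte(ov, 1)
    if (ov == 1) expect_equal(a, b)
  }
  expect_error(interval_overlap(c(5, 5), c(0, 1)), "start < end")
})

test_that("boundary deltas measure start and duration offsets in seconds", {
  expect_equal(boundary_deltas(c(1000, 3000), c(1500, 3500)),
               c(delta_start_s = 0.5, delta_duration_s = 0))
  expect_equal(boundary_deltas(c(0, 2000), c(0, 2000)),
               c(delta_start_s = 0, delta_duration_s = 0))
  expect_equal(boundary_deltas(c(0, 4000), c(0, 2000)),
               c(delta_start_s = 0, delta_duration_s = 2))
})

test_that("candidate-to-label distance is 0 on overlap, else the nearest gap", {
  labs <- label_intervals(c(3000, 10000), c(4000, 12000), c("a", "b"))
  expect_equal(candidate_label_distance(c(3200, 3600), labs), 0)
  expect_equal(candidate_label_distance(c(0, 1000), labs), 2)
  # equidistant labels
  labs2 <- label_intervals(c(0, 7000), c(1000, 8000), c("a", "b"))
  expect_equal(candidate_label_distance(c(2500, 5500), labs2), 1.5)
  expect_error(candidate_label_distance(c(0, 1),
                                        label_intervals(integer(0), integer(0),
                                                        character(0))),
               "empty label")
})

test_that("recall counts labels overlapped by any candidate", {
  labs <- label_intervals(c(0, 10000, 20000, 30000),
                          c(2000, 12000, 22000, 32000), rep("a", 4))
  cand <- function(s, e) data.frame(start_ms = s, end_ms = e)
  expect_equal(recall_at_k(cand(c(500, 10500, 20500, 30500),
                                c(1500, 11500, 21500, 31500)), labs), 1)
  expect_equal(recall_at_k(cand(integer(0), integer(0)), labs), 0)
  expect_equal(recall_at_k(cand(c(500, 10500), c(1500, 11500)), labs), 0.5)
})

test_that("roc_curve performs a standard monotone threshold sweep", {
  # perfect separation passes through (0,1)
  r <- roc_curve(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  expect_equal(attr(r, "auc"), 1)
  # all-equal scores: only the two endpoint behaviors
  r2 <- roc_curve(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$fpr[nrow(r2)], 1)
  expect_equal(r2$tpr[nrow(r2)], 1)
  expect_equal(attr(r2, "auc"), 0.5)
  # inverted scores: area 0
  r3 <- roc_curve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(r3, "auc"), 0)
  # monotone coordinates
  set.seed(2)
  r4 <- roc_curve(rnorm(50), rep(c(TRUE, FALSE), 25))
  expect_true(!is.unsorted(r4$fpr))
  expect_true(!is.unsorted(r4$tpr))
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
})

test_that("roc_curve agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- rnorm(80)
  y <- scores + rnorm(80) > 0
  if (!any(y) || all(y)) y[1:2] <- c(TRUE, FALSE)
  ours <- attr(roc_curve(scores, y), "auc")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, scores,
                                                         direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("score_windows labels windows by ground truth and scores by distance", {
  cfg <- preprocess_config("linear", TRUE)
  sc <- sim_config(seed = 55, duration_s = 60, n_activities = 2, noise_sd = 0.1)
  rec <- generate_recording(sc)
  tpls <- extract_templates(rec, cfg)
  sw <- score_windows(rec, tpls, cfg)
  expect_true(any(sw$is_positive) && any(!sw$is_positive))
  # windows over the planted activities score higher on average
  expect_gt(mean(sw$score[sw$is_positive]), mean(sw$score[!sw$is_positive]))
  roc <- roc_curve(sw$score, sw$is_positive)
  expect_gt(attr(roc, "auc"), 0.8)
})

test_that("sweep_grid covers the grid deterministically", {
  cfg <- preprocess_config("linear", TRUE)
  sc <- sim_config(seed = 70, duration_s = 60, n_activities = 2, noise_sd = 0.1)
  recs <- generate_cohort(sc, 2)
  tpls <- unlist(lapply(recs, extract_templates, cfg = cfg), recursive = FALSE)
  g1 <- sweep_grid(recs, tpls, c(1, 2), c(3, 5), cfg, seed = 4)
  expect_equal(nrow(g1), 4)
  expect_true(all(g1$min_s <= g1$median_s & g1$median_s <= g1$max_s))
  g2 <- sweep_grid(recs, tpls, c(1, 2), c(3, 5), cfg, seed = 4)
  expect_identical(g1, g2)
  expect_error(sweep_grid(recs, tpls, 99, 5, cfg), "exceeds")
})

test_that("leave-one-out excludes the held-out recording's own templates", {
  cfg <- preprocess_config("linear", TRUE)
  sc <- sim_config(seed = 81, duration_s = 60, n_activities = 2, noise_sd = 0.1)
  recs <- generate_cohort(sc, 3)
  sel <- selection_config("delta", k = 8)
  res <- leave_one_out(recs, cfg, sel, seed = 2)
  expect_equal(nrow(res$folds), 3)
  expect_setequal(res$folds$held_out,
                  vapply(recs, `[[`, character(1), "recording_id"))
  expect_true(all(res$folds$n_candidates <= 8))
  expect_error(leave_one_out(recs[1], cfg, sel), "2 recordings")

  # duplicated recordings: every fold contains that exact signal -> near-zero
  twin <- recs[c(1, 1)]
  twin[[2]]$recording_id <- "copy"
  res2 <- leave_one_out(twin, cfg, sel, seed = 2)
  expect_true(all(res2$folds$min_s < 0.5))
  expect_equal(res2$folds$recall, c(1, 1))
})
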