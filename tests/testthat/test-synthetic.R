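test_that("truth sampler returns normalised, reproducible, ladder-ranged weights", {
  tw <- sample_true_weights(4, seed = 3)
  expect_equal(sum(tw$weight), 1, tolerance = 1e-9)
  expect_true(all(tw$weight > 0))
  expect_equal(tw, sample_true_weights(4, seed = 3))
  expect_false(identical(tw$weight, sample_true_weights(4, seed = 5)$weight))
  expect_error(sample_true_weights(1), ">= 2")
  # identifiability restrictions: consecutive distinct ratios >= one rung,
  # spread capped at the ladder ceiling
  withr::with_seed(13, {
    for (rep in 1:20) {
      w <- sort(sample_true_weights(sample(3:9, 1))$weight, decreasing = TRUE)
      r <- w[-length(w)] / w[-1]
      expect_true(all(r >= 1.5 - 1e-9 | abs(r - 1) < 1e-9))
      expect_true(max(w) / min(w) <= 9 + 1e-9)
    }
  })
  # unrestricted draw is a plain normalised Dirichlet sample
  w0 <- sample_true_weights(6, seed = 8, min_ratio = 1, max_spread = Inf)
  expect_equal(sum(w0$weight), 1, tolerance = 1e-12)
})

test_that("ideal judgments quantise weight ratios onto the ladder", {
  expect_equal(ideal_judgment(0.3, 0.3), 1L)
  expect_equal(ideal_judgment(0.97, 0.1), 9L)  # ratio 9.7 clips to 9
  expect_equal(ideal_judgment(0.6, 0.2), 3L)
  expect_equal(ideal_judgment(0.2, 0.6), -3L)
  expect_error(ideal_judgment(0, 1), "positive")
  # the reciprocal cell carries the analytic inverse of the forward TFN
  m <- ideal_matrix(c(a = 0.6, b = 0.2))
  fw <- m[m$item_i == "a" & m$item_j == "b", ]
  bw <- m[m$item_i == "b" & m$item_j == "a", ]
  expect_equal(unlist(fw[c("l", "m", "u")]),
               unclass(scale_lookup(3)$forward)[1, ], ignore_attr = TRUE)
  expect_equal(unlist(bw[c("l", "m", "u")]),
               unclass(tfn_inv(scale_lookup(3)$forward))[1, ], ignore_attr = TRUE)
})

test_that("zero-noise panels repeat the ideal matrix for every expert", {
  tw <- sample_true_weights(5, seed = 21)
  pan <- generate_panel(tw, n_experts = 4, step_probability = 0, seed = 21)
  ideal <- ideal_matrix(tw)
  for (e in unique(pan$judgments$expert_id)) {
    blk <- pan$judgments[pan$judgments$expert_id == e,
                         c("item_i", "item_j", "l", "m", "u")]
    expect_equal(as.data.frame(blk), as.data.frame(ideal), ignore_attr = TRUE)
  }
})

test_that("generated panels are valid, sized 22 by default, and reproducible", {
  tw <- sample_true_weights(4, seed = 6)
  pan <- generate_panel(tw, step_probability = 0.4, seed = 6)
  expect_equal(length(unique(pan$judgments$expert_id)), 22L)
  expect_equal(nrow(panel_completeness(pan$judgments)), 0L)
  pan2 <- generate_panel(tw, step_probability = 0.4, seed = 6)
  expect_identical(pan$judgments, pan2$judgments)
  # every generated matrix validates by construction
  for (e in unique(pan$judgments$expert_id)[1:5]) {
    blk <- pan$judgments[pan$judgments$expert_id == e,
                         c("item_i", "item_j", "l", "m", "u")]
    expect_silent(validate_pcm(blk, tol = 1e-9))
  }
  # multi-node truths give one matrix per node per expert
  multi <- generate_panel(list(GOAL = tw, F1 = sample_true_weights(3, seed = 7)),
                          n_experts = 2, step_probability = 0.2, seed = 9)
  expect_equal(sort(unique(multi$judgments$node)), c("F1", "GOAL"))
  expect_equal(nrow(multi$judgments), 2 * (16 + 9))
})

test_that("ladder noise stays on the ladder and zero steps change nothing", {
  tw <- sample_true_weights(4, seed = 10)
  noisy <- generate_panel(tw, n_experts = 10, step_probability = 1,
                          max_steps = 3, seed = 10)
  sc <- fuzzy_scale()
  legal <- unique(c(sc$m, 1 / sc$m))
  expect_true(all(vapply(noisy$judgments$m,
                         function(x) any(abs(x - legal) < 1e-12), logical(1))))
  frozen <- generate_panel(tw, n_experts = 3, step_probability = 1,
                           max_steps = 0, seed = 10)
  expect_equal(as.data.frame(frozen$judgments[frozen$judgments$expert_id == "E01",
                                              c("l", "m", "u")]),
               as.data.frame(ideal_matrix(tw)[c("l", "m", "u")]),
               ignore_attr = TRUE)
  expect_error(generate_panel(tw, step_probability = 2), "step_probability")
})

test_that("reference tables carry the published scores and codes", {
  tabs <- hospital_bed_tables()
  expect_equal(sum(tabs$factors$score), 0.999)
  expect_equal(tabs$subfactors$score[tabs$subfactors$code == "C44"], 0.444)
  expect_equal(tabs$subfactors$priority[tabs$subfactors$code == "C44"], 1L)
  expect_false("C31" %in% tabs$subfactors$code)
  expect_equal(nrow(tabs$subfactors), 54L)
  expect_equal(tabs$factors$score[tabs$factors$code == "F8"], 0.249)
  expect_equal(nrow(tabs$scale), 9L)
})

test_that("recovery experiment is deterministic under a fixed seed", {
  r1 <- recovery_experiment(n_items = 4, n_experts = 5, replicates = 8, seed = 33)
  r2 <- recovery_experiment(n_items = 4, n_experts = 5, replicates = 8, seed = 33)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_true(all(r1$spearman >= -1 & r1$spearman <= 1, na.rm = TRUE))
  g <- glance(r1)
  expect_equal(g$replicates, 8L)
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("heavy ladder noise degrades single-expert recovery below zero noise", {
  # single-expert panels isolate the noise effect: with several experts the
  # geometric mean dithers quantisation error and can even help
  quiet <- recovery_experiment(n_items = 5, n_experts = 1, step_probability = 0,
                               replicates = 30, seed = 44)
  loud <- recovery_experiment(n_items = 5, n_experts = 1, step_probability = 1,
                              max_steps = 4, replicates = 30, seed = 44)
  expect_true(mean(loud$spearman, na.rm = TRUE) <
                mean(quiet$spearman, na.rm = TRUE))
})
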