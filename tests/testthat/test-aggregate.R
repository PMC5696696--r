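panel_of <- function(...) {
  mats <- list(...)
  dplyr::bind_rows(purrr::imap(mats, ~ dplyr::mutate(.x, expert_id = paste0("e", .y))))
}

test_that("geometric aggregation: identity on one expert, idempotent on clones", {
  m <- worked_2x2()
  one <- aggregate_judgments(panel_of(m))
  expect_equal(one[c("item_i", "item_j", "l", "m", "u")], m, ignore_attr = TRUE)
  five <- aggregate_judgments(panel_of(m, m, m, m, m))
  expect_equal(five$l, m$l, tolerance = 1e-12)
  expect_equal(five$m, m$m, tolerance = 1e-12)
  expect_equal(five$u, m$u, tolerance = 1e-12)
})

test_that("two-expert geometric mean matches the componentwise square root", {
  a <- as_pcm(data.frame(item_i = "x", item_j = "y", l = 1, m = 3, u = 5))
  b <- as_pcm(data.frame(item_i = "x", item_j = "y", l = 0.2, m = 0.33, u = 1))
  agg <- aggregate_judgments(panel_of(a, b))
  cell <- agg[agg$item_i == "x" & agg$item_j == "y", ]
  expect_equal(cell$l, sqrt(1 * 0.2), tolerance = 1e-12)
  expect_equal(cell$m, sqrt(3 * 0.33), tolerance = 1e-12)
  expect_equal(cell$u, sqrt(5 * 1), tolerance = 1e-12)
  expect_equal(round(c(cell$l, cell$m, cell$u), 3), c(0.447, 0.995, 2.236))
})

test_that("geometric aggregation preserves reciprocity to machine precision", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      n <- sample(3:6, 1)
      mats <- purrr::map(1:4, ~ random_ladder_pcm(n))
      agg <- aggregate_judgments(do.call(panel_of, mats))
      p <- extentahp:::.pcm_mats(agg)
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        expect_equal(p$L[j, i], 1 / p$U[i, j], tolerance = 1e-12)
        expect_equal(p$M[j, i], 1 / p$M[i, j], tolerance = 1e-12)
        expect_equal(p$U[j, i], 1 / p$L[i, j], tolerance = 1e-12)
      }
      expect_silent(validate_pcm(agg, tol = 1e-9))
    }
  })
})

test_that("aggregation is invariant to expert order and monotone in judgments", {
  withr::with_seed(83, {
    mats <- purrr::map(1:5, ~ random_ladder_pcm(4))
    fwd <- aggregate_judgments(do.call(panel_of, mats))
    bwd <- aggregate_judgments(do.call(panel_of, rev(mats)))
    expect_equal(fwd, bwd, tolerance = 1e-12)
  })
  # raising one expert's (i, j) judgment never lowers the aggregated (i, j)
  lower <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 1, m = 3, u = 5))
  other <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 1, m = 2, u = 3))
  raised <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 3, m = 5, u = 7))
  base_agg <- aggregate_judgments(panel_of(lower, other))
  high_agg <- aggregate_judgments(panel_of(raised, other))
  cell <- base_agg$item_i == "a" & base_agg$item_j == "b"
  expect_true(all(unlist(high_agg[cell, c("l", "m", "u")]) >=
                    unlist(base_agg[cell, c("l", "m", "u")])))
})

test_that("arithmetic aggregation is available and averages componentwise", {
  a <- as_pcm(data.frame(item_i = "x", item_j = "y", l = 1, m = 3, u = 5))
  b <- as_pcm(data.frame(item_i = "x", item_j = "y", l = 1, m = 1, u = 1))
  agg <- aggregate_judgments(panel_of(a, b), method = "arithmetic")
  cell <- agg[agg$item_i == "x" & agg$item_j == "y", ]
  expect_equal(c(cell$l, cell$m, cell$u), c(1, 2, 3))
})

test_that("aggregation errors on empty or mismatched panels", {
  expect_error(aggregate_judgments(worked_2x2()[0, ]), "empty|columns")
  a <- dplyr::mutate(worked_2x2(), expert_id = "e1")
  b <- dplyr::mutate(
    as_pcm(data.frame(item_i = "a", item_j = "c", l = 1, m = 2, u = 3)),
    expert_id = "e2")
  expect_error(aggregate_judgments(dplyr::bind_rows(a, b)), "different item sets")
})

test_that("panel completeness reports missing nodes and bad matrices", {
  tw <- sample_true_weights(3, seed = 2)
  pan <- generate_panel(list(F1 = tw, F2 = tw), n_experts = 3,
                        step_probability = 0, seed = 2)
  expect_equal(nrow(panel_completeness(pan$judgments)), 0L)
  drop <- pan$judgments[!(pan$judgments$expert_id == "E02" &
                            pan$judgments$node == "F2"), ]
  rep1 <- panel_completeness(drop)
  expect_equal(rep1$issue, "missing_node")
  expect_equal(rep1$expert_id, "E02")
  expect_equal(rep1$node, "F2")
  # transposed-but-not-inverted entry
  broken <- pan$judgments
  k <- which(broken$expert_id == "E01" & broken$node == "F1" &
               broken$item_i == "X2" & broken$item_j == "X1")
  src <- which(broken$expert_id == "E01" & broken$node == "F1" &
                 broken$item_i == "X1" & broken$item_j == "X2")
  broken[k, c("l", "m", "u")] <- broken[src, c("l", "m", "u")]
  rep2 <- panel_completeness(broken)
  expect_true(any(rep2$issue == "invalid_matrix" & rep2$expert_id == "E01" &
                    rep2$node == "F1"))
})

test_that("panels round-trip through the long text format", {
  tw <- sample_true_weights(3, seed = 4)
  pan <- generate_panel(tw, n_experts = 2, step_probability = 0.3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan$judgments, path)
  back <- read_panel(path)
  expect_equal(dplyr::arrange(back, expert_id, node, item_i, item_j),
               dplyr::arrange(pan$judgments, expert_id, node, item_i, item_j),
               tolerance = 1e-12)
})

test_that("linguistic label panels translate through the scale", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    expert_id = "e1", node = "F1", item_i = "a", item_j = "b",
    label = "Moderately more important"), path)
  pan <- read_panel(path)
  cell <- pan[pan$item_i == "a" & pan$item_j == "b", ]
  expect_equal(c(cell$l, cell$m, cell$u), c(1, 3, 5))
  recip <- pan[pan$item_i == "b" & pan$item_j == "a", ]
  expect_equal(c(recip$l, recip$m, recip$u), c(1 / 5, 1 / 3, 1))
})
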