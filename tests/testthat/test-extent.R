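test_that("matrix validation accepts reciprocal pairs and reports violations", {
  expect_silent(validate_pcm(worked_2x2()))
  bad_recip <- tibble::tibble(
    item_i = c("a", "a", "b", "b"), item_j = c("a", "b", "a", "b"),
    l = c(1, 1, 1, 1), m = c(1, 3, 3, 1), u = c(1, 5, 5, 1))
  expect_error(validate_pcm(bad_recip), "reciprocity")
  bad_diag <- worked_2x2()
  bad_diag[bad_diag$item_i == "a" & bad_diag$item_j == "a",
           c("l", "m", "u")] <- list(1, 2, 3)
  expect_error(validate_pcm(bad_diag), "diagonal")
  expect_error(validate_pcm(worked_2x2()[1:3, ]), "complete square")
  expect_error(validate_pcm(as_pcm(data.frame(item_i = "a", item_j = "a",
                                              l = 1, m = 1, u = 1))),
               "at least 2")
})

test_that("synthetic extents match hand evaluation and the identity matrix case", {
  ident <- function(n) {
    items <- letters[seq_len(n)]
    as_pcm(tidyr::expand_grid(item_i = items, item_j = items) |>
             dplyr::mutate(l = 1, m = 1, u = 1))
  }
  for (n in 2:3) {
    S <- synthetic_extents(ident(n))
    expect_equal(S$l, rep(n / (n * n), n))
    expect_equal(S$m, rep(1 / n, n))
    expect_equal(S$u, rep(1 / n, n))
  }
  S <- synthetic_extents(worked_2x2())
  # grand sum (3.2, 5.33, 8); rows (2,4,6) and (1.2,1.33,2)
  expect_equal(S$l, c(2 / 8, 1.2 / 8), tolerance = 1e-12)
  expect_equal(S$m, c(4 / 5.33, 1.33 / 5.33), tolerance = 1e-12)
  expect_equal(S$u, c(6 / 3.2, 2 / 3.2), tolerance = 1e-12)
  orc <- oracle_extents(worked_2x2())
  expect_equal(S$l, orc$l)
  expect_equal(S$m, orc$m)
  expect_equal(S$u, orc$u)
})

test_that("modal extent components always sum to one", {
  withr::with_seed(23, {
    for (rep in 1:40) {
      n <- sample(2:9, 1)
      S <- synthetic_extents(random_ladder_pcm(n), validate = FALSE)
      expect_equal(sum(S$m), 1, tolerance = 1e-9)
    }
  })
})

test_that("possibility degree handles dominance, disjointness and crossing", {
  expect_equal(possibility_degree(tfn(1, 2, 3), tfn(1, 2, 3)), 1)
  expect_equal(possibility_degree(tfn(1, 2, 3), tfn(4, 5, 6)), 0)
  expect_equal(possibility_degree(tfn(1, 2, 4), tfn(3, 5, 7)), 0.25)
  # touching supports have intersection height zero
  expect_equal(possibility_degree(tfn(1, 2, 3), tfn(3, 4, 5)), 0)
  # one direction always certain
  withr::with_seed(5, {
    for (rep in 1:50) {
      a <- random_tfn(); b <- random_tfn()
      expect_equal(max(possibility_degree(a, b), possibility_degree(b, a)), 1)
    }
  })
})

test_that("possibility degree agrees with the grid-search oracle", {
  withr::with_seed(31, {
    for (rep in 1:60) {
      a <- random_tfn(); b <- random_tfn()
      expect_equal(possibility_degree(a, b), oracle_possibility(a, b),
                   tolerance = 1e-4)
    }
  })
})

test_that("min possibility picks the weakest comparison", {
  S <- tibble::tibble(item = c("a", "b"), l = c(1, 1), m = c(2, 2), u = c(3, 3))
  expect_equal(min_possibility(S, 1), 1)
  expect_equal(min_possibility(S, 2), 1)
  Sw <- synthetic_extents(worked_2x2())
  expect_equal(min_possibility(Sw, 1), 1)
  v21 <- (Sw$u[2] - Sw$l[1]) / ((Sw$u[2] - Sw$l[1]) + (Sw$m[1] - Sw$m[2]))
  expect_equal(min_possibility(Sw, 2), v21)
  expect_error(min_possibility(Sw, 3), "out of range")
  # disjoint lower support forces zero
  S0 <- tibble::tibble(item = c("a", "b"), l = c(0.1, 5), m = c(0.2, 6),
                       u = c(0.3, 7))
  expect_equal(min_possibility(S0, 1), 0)
})

test_that("extent-analysis weights: uniform, worked and degenerate cases", {
  items <- letters[1:4]
  ident <- as_pcm(tidyr::expand_grid(item_i = items, item_j = items) |>
                    dplyr::mutate(l = 1, m = 1, u = 1))
  expect_equal(compute_weights(ident)$weight, rep(0.25, 4))
  w <- compute_weights(worked_2x2())
  expect_equal(w$v_min[1], 1)
  expect_equal(w$weight, w$v_min / sum(w$v_min))
  expect_equal(sum(w$weight), 1)
  # crisp strong dominance: dominated item gets exactly zero
  crisp <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 5, m = 5, u = 5))
  expect_equal(compute_weights(crisp)$weight, c(1, 0))
  expect_error(extentahp:::.normalise_wprime(c(0, 0, 0)), "degenerate")
})

test_that("weights are permutation-equivariant and deterministic", {
  withr::with_seed(47, {
    for (rep in 1:10) {
      n <- sample(3:6, 1)
      pcm <- random_ladder_pcm(n)
      w1 <- compute_weights(pcm)
      perm <- sample(unique(pcm$item_i))
      pcm2 <- pcm[order(match(pcm$item_i, perm), match(pcm$item_j, perm)), ]
      w2 <- compute_weights(as_pcm(pcm2, items = perm))
      expect_equal(w2$weight[match(w1$item, w2$item)], w1$weight,
                   tolerance = 1e-12)
      expect_identical(compute_weights(pcm)$weight, w1$weight)
      expect_equal(sum(w1$weight), 1, tolerance = 1e-9)
    }
  })
})

test_that("comparison matrices round-trip through delimited and JSON grid forms", {
  withr::with_seed(59, {
    pcm <- random_ladder_pcm(4)
    for (ext in c(".csv", ".tsv", ".json")) {
      path <- withr::local_tempfile(fileext = ext)
      write_pcm(pcm, path)
      back <- read_pcm(path)
      expect_equal(as.data.frame(back), as.data.frame(pcm), tolerance = 1e-12,
                   info = ext)
    }
  })
})

test_that("weight objects support broom-style tidiers and autoplot", {
  w <- compute_weights(worked_2x2())
  expect_s3_class(tidy(w), "tbl_df")
  g <- glance(w)
  expect_equal(g$n_items, 2L)
  expect_equal(g$n_zero, 0L)
  expect_s3_class(autoplot(w), "ggplot")
})
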