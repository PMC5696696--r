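# Independent oracles and random-case generators used across the suite.
# These deliberately avoid the package's computational path: memberships are
# evaluated pointwise on grids and sums are taken straight off the long
# tables.

# Triangular membership function.
tri_membership <- function(x, l, m, u) {
  up <- if (m > l) (x - l) / (m - l) else as.numeric(x == m)
  dn <- if (u > m) (u - x) / (u - m) else as.numeric(x == m)
  pmax(pmin(up, dn, 1), 0)
}

# Grid-search oracle for the possibility degree V(a >= b): 1 when the first
# mode dominates, otherwise the maximised min-membership (intersection
# height), located on a coarse grid and refined around the argmax.
oracle_possibility <- function(a, b, n_coarse = 4001, n_fine = 20001) {
  a <- unclass(extentahp::as_tfn(a))[1, ]
  b <- unclass(extentahp::as_tfn(b))[1, ]
  if (a["m"] >= b["m"]) return(1)
  lo <- min(a["l"], b["l"]); hi <- max(a["u"], b["u"])
  g <- seq(lo, hi, length.out = n_coarse)
  h <- pmin(tri_membership(g, a["l"], a["m"], a["u"]),
            tri_membership(g, b["l"], b["m"], b["u"]))
  i <- which.max(h)
  step <- g[2] - g[1]
  g2 <- seq(max(lo, g[i] - 2 * step), min(hi, g[i] + 2 * step),
            length.out = n_fine)
  h2 <- pmin(tri_membership(g2, a["l"], a["m"], a["u"]),
             tri_membership(g2, b["l"], b["m"], b["u"]))
  max(h2)
}

# Direct evaluation of the synthetic-extent formula from the long table,
# without the package's matrix plumbing.
oracle_extents <- function(pcm) {
  items <- unique(pcm$item_i)
  gl <- sum(pcm$l); gm <- sum(pcm$m); gu <- sum(pcm$u)
  do.call(rbind, lapply(items, function(it) {
    row <- pcm[pcm$item_i == it, ]
    data.frame(item = it, l = sum(row$l) / gu, m = sum(row$m) / gm,
               u = sum(row$u) / gl)
  }))
}

# Extent-analysis weights evaluated entirely through the oracles above.
oracle_weights <- function(pcm) {
  S <- oracle_extents(pcm)
  n <- nrow(S)
  wp <- sapply(seq_len(n), function(i) {
    min(sapply(setdiff(seq_len(n), i), function(k) {
      oracle_possibility(extentahp::tfn(S$l[i], S$m[i], S$u[i]),
                         extentahp::tfn(S$l[k], S$m[k], S$u[k]))
    }))
  })
  data.frame(item = S$item, v_min = wp, weight = wp / sum(wp))
}

# Random TFN with component spread bounded away from zero so grid oracles
# stay sharp.
random_tfn <- function(min_width = 0.05, max_val = 10) {
  repeat {
    x <- sort(runif(3, 0.1, max_val))
    if (x[2] - x[1] >= min_width && x[3] - x[2] >= min_width)
      return(extentahp::tfn(x[1], x[2], x[3]))
  }
}

# Random valid comparison matrix built from ladder judgments through the
# public surface: random signed intensities on the upper triangle.
random_ladder_pcm <- function(n, items = paste0("X", seq_len(n))) {
  cells <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    k <- sample(1:9, 1)
    fw <- unclass(scale_lookup(k)$forward)[1, ]
    if (runif(1) < 0.5) {
      cells[[length(cells) + 1]] <- data.frame(
        item_i = items[i], item_j = items[j], l = fw["l"], m = fw["m"], u = fw["u"])
    } else {
      cells[[length(cells) + 1]] <- data.frame(
        item_i = items[j], item_j = items[i], l = fw["l"], m = fw["m"], u = fw["u"])
    }
  }
  as_pcm(do.call(rbind, cells), items = items)
}

# The worked two-item matrix used throughout: judgment "moderately more
# important" of a over b, reciprocal as printed at two decimals.
worked_2x2 <- function() {
  as_pcm(data.frame(item_i = c("a", "b"), item_j = c("b", "a"),
                    l = c(1, 0.2), m = c(3, 0.33), u = c(5, 1)))
}
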