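#' Synthetic extents of a fuzzy comparison matrix
#'
#' For each row \eqn{k} of a fuzzy pairwise comparison matrix the synthetic
#' extent is
#' \deqn{S_k = \sum_{j=1}^n M_{kj} \otimes \Big[\sum_{i=1}^n \sum_{j=1}^n M_{ij}\Big]^{-1},}
#' the fuzzy row sum scaled by the inverse of the grand sum over all cells.
#' The modal components of the extents always sum to exactly 1 (an algebraic
#' identity of the formula), so the extents are a fuzzy analogue of
#' normalised row weights.
#'
#' @param pcm A long-form comparison matrix (see [as_pcm()]).
#' @param validate Validate the matrix first (default `TRUE`).
#' @param tol Reciprocity tolerance passed to [validate_pcm()].
#' @return A tibble with columns `item`, `l`, `m`, `u`, one row per item.
#' @examples
#' m <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 1, m = 3, u = 5))
#' synthetic_extents(m)
#' @export
synthetic_extents <- function(pcm, validate = TRUE, tol = 0.01) {
  if (validate) validate_pcm(pcm, tol = tol)
  p <- .pcm_mats(pcm)
  S <- .extents_mats(p$L, p$M, p$U)
  tibble::tibble(item = p$items, l = S[, "l"], m = S[, "m"], u = S[, "u"])
}

# Internal fast path on component matrices; returns n x 3 matrix.
.extents_mats <- function(L, M, U) {
  cbind(l = rowSums(L) / sum(U), m = rowSums(M) / sum(M), u = rowSums(U) / sum(L))
}

#' Possibility degree that one fuzzy number exceeds another
#'
#' The possibility degree \eqn{V(M_1 \ge M_2)} is 1 when \eqn{m_1 \ge m_2};
#' otherwise it is the height of the intersection of the two triangular
#' membership functions,
#' \deqn{V(M_1 \ge M_2) = \frac{u_1 - l_2}{(u_1 - l_2) + (m_2 - m_1)},}
#' taken as 0 when the supports do not overlap (\eqn{u_1 \le l_2}, including
#' the touching case, where the intersection has height zero).
#'
#' @param a,b `tfn` objects (rows recycled); the degree is \eqn{V(a \ge b)}.
#' @return A numeric vector of degrees in \eqn{[0, 1]}.
#' @examples
#' possibility_degree(tfn(1, 2, 4), tfn(3, 5, 7)) # 0.25
#' @export
possibility_degree <- function(a, b) {
  ab <- .tfn_recycle(a, b)
  .vdeg(ab$a[, "l"], ab$a[, "m"], ab$a[, "u"],
        ab$b[, "l"], ab$b[, "m"], ab$b[, "u"])
}

.vdeg <- function(l1, m1, u1, l2, m2, u2) {
  as.numeric(ifelse(m1 >= m2, 1,
                    ifelse(u1 <= l2, 0, (u1 - l2) / ((u1 - l2) + (m2 - m1)))))
}

#' Minimum possibility degree of one extent against all others
#'
#' The non-normalised extent-analysis weight of item \eqn{i} is
#' \eqn{W'(x_i) = \min_{k \ne i} V(S_i \ge S_k)}: the degree to which item
#' \eqn{i}'s synthetic extent exceeds every other extent.
#'
#' @param extents A tibble of extents as returned by [synthetic_extents()]
#'   (columns `item`, `l`, `m`, `u`), or a `tfn` with one row per item.
#' @param index Integer position of the target item.
#' @return A single degree in \eqn{[0, 1]}.
#' @export
min_possibility <- function(extents, index) {
  S <- if (is_tfn(extents)) unclass(extents) else unclass(as_tfn(extents))
  n <- nrow(S)
  if (n < 2) stop("need at least 2 extents", call. = FALSE)
  if (!is.numeric(index) || length(index) != 1 || is.na(index) ||
      index < 1 || index > n)
    stop("index out of range: must be in 1..", n, call. = FALSE)
  others <- setdiff(seq_len(n), index)
  min(.vdeg(S[index, "l"], S[index, "m"], S[index, "u"],
            S[others, "l"], S[others, "m"], S[others, "u"]))
}

# Internal: W' for all items from component matrices of extents (n x 3).
.wprime_mats <- function(S) {
  n <- nrow(S)
  vapply(seq_len(n), function(i) {
    k <- setdiff(seq_len(n), i)
    min(.vdeg(S[i, "l"], S[i, "m"], S[i, "u"], S[k, "l"], S[k, "m"], S[k, "u"]))
  }, numeric(1))
}

#' Extent-analysis weights of a fuzzy comparison matrix
#'
#' Runs the full extent-analysis chain on one matrix: synthetic extents,
#' pairwise possibility degrees, min-aggregation into the non-normalised
#' weight vector \eqn{W'}, and normalisation of \eqn{W'} to sum 1.
#'
#' Extent analysis is known to assign weight exactly 0 to strongly dominated
#' items (most visibly with crisp judgments, where supports are points); such
#' zeros are returned as-is. If every item receives \eqn{W' = 0} the weights
#' are undefined and an error is raised naming the cause.
#'
#' @inheritParams synthetic_extents
#' @return A tibble of class `fahp_weights` with columns `item`, `v_min`
#'   (the non-normalised \eqn{W'}) and `weight` (normalised, summing to 1).
#'   The extents are attached as attribute `"extents"`.
#' @examples
#' m <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 1, m = 3, u = 5))
#' compute_weights(m)
#' @export
compute_weights <- function(pcm, validate = TRUE, tol = 0.01) {
  if (validate) validate_pcm(pcm, tol = tol)
  p <- .pcm_mats(pcm)
  S <- .extents_mats(p$L, p$M, p$U)
  wp <- .wprime_mats(S)
  out <- tibble::tibble(item = p$items, v_min = wp, weight = .normalise_wprime(wp))
  attr(out, "extents") <- tibble::tibble(item = p$items, l = S[, "l"],
                                         m = S[, "m"], u = S[, "u"])
  class(out) <- c("fahp_weights", class(out))
  out
}

# Normalise W' to sum 1; an all-zero vector means every item's extent is
# dominated with disjoint support -- weights are undefined.
.normalise_wprime <- function(wp) {
  s <- sum(wp)
  if (s <= 0)
    stop("degenerate weights: every item has minimum possibility degree 0 ",
         "(all synthetic extents are dominated with non-overlapping supports), ",
         "so normalised weights are undefined", call. = FALSE)
  wp / s
}

#' @export
print.fahp_weights <- function(x, ...) {
  cat("Extent-analysis weights (", nrow(x), " items)\n", sep = "")
  NextMethod()
}

#' Tidiers for extent-analysis weights
#'
#' `tidy()` returns the per-item weight table; `glance()` returns a one-row
#' summary with the item count, the smallest and largest normalised weight and
#' the number of exact zeros (the extent-analysis degeneracy indicator).
#'
#' @param x A `fahp_weights` object from [compute_weights()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fahp_weights <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.fahp_weights
#' @export
glance.fahp_weights <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x),
    min_weight = min(x$weight),
    max_weight = max(x$weight),
    n_zero = sum(x$v_min == 0)
  )
}

#' Plot extent-analysis weights
#'
#' Bar chart of normalised weights, ordered from highest to lowest priority.
#'
#' @param object A `fahp_weights` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fahp_weights <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(item, weight), y = weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalised weight") +
    ggplot2::theme_minimal()
}
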