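#' Sample a ground-truth weight vector
#'
#' Draws a positive, normalised weight vector from a symmetric
#' Dirichlet-style sampler (independent Gamma draws with a single
#' `concentration` knob, renormalised) and then restricts it to the range the
#' nine-level judgment ladder can express, so that the truth is identifiable
#' from the judgments it generates:
#'
#' * adjacent ratios (between consecutively ranked weights) below `min_ratio`
#'   are raised to `min_ratio` — ratios under 1.5 round to "equally
#'   important" on the ladder and are therefore indistinguishable in any
#'   questionnaire;
#' * weights more than `max_spread` below the largest weight are floored at
#'   `largest / max_spread` — the ladder saturates at ratio 9, so larger
#'   spreads are inexpressible. Floored items become exactly tied, which the
#'   sampler reports as genuine ties rather than pretending to a resolution
#'   the instrument lacks.
#'
#' Set `min_ratio = 1` and `max_spread = Inf` for an unrestricted Dirichlet
#' draw.
#'
#' @param n Number of items (at least 2).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param concentration Positive spread parameter of the Dirichlet-style
#'   sampler: large values give near-uniform weights, small values skewed
#'   ones.
#' @param min_ratio Minimum ratio between consecutively ranked distinct
#'   weights (default 1.5, one ladder rung).
#' @param max_spread Maximum ratio between the largest and smallest weight
#'   (default 9, the ladder ceiling).
#' @return A tibble of class `fahp_truth` with columns `item` (`X1`...`Xn`)
#'   and `weight` (positive, summing to 1), carrying the sampler settings as
#'   attributes.
#' @examples
#' sample_true_weights(4, seed = 1)
#' @export
sample_true_weights <- function(n, seed = NULL, concentration = 1,
                                min_ratio = 1.5, max_spread = 9) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("n must be a single integer >= 2", call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  if (min_ratio < 1) stop("min_ratio must be >= 1", call. = FALSE)
  if (max_spread < 1) stop("max_spread must be >= 1", call. = FALSE)
  n <- as.integer(n)
  w <- .with_seed(seed, {
    g <- stats::rgamma(n, shape = concentration)
    g / sum(g)
  })
  o <- order(w, decreasing = TRUE)
  ws <- w[o]
  for (i in seq(2, n)) ws[i] <- min(ws[i], ws[i - 1] / min_ratio)
  if (is.finite(max_spread)) {
    flr <- ws[1] / max_spread
    # weights at or within one rung of the ceiling-implied floor collapse onto
    # it: the ladder cannot distinguish them from the floor either
    ws[ws < flr * min_ratio] <- flr
  }
  ws <- ws / sum(ws)
  w[o] <- ws
  out <- tibble::tibble(item = paste0("X", seq_len(n)), weight = w)
  attr(out, "seed") <- seed
  attr(out, "concentration") <- concentration
  attr(out, "min_ratio") <- min_ratio
  attr(out, "max_spread") <- max_spread
  class(out) <- c("fahp_truth", class(out))
  out
}

#' Ideal ladder judgment implied by a weight ratio
#'
#' Maps a true weight ratio onto the nine-level intensity ladder: the
#' intensity is the half-up rounding of \eqn{w_i / w_j}, clipped to
#' \eqn{[1, 9]}. The result is signed: a positive value \eqn{k} means item
#' \eqn{i} is preferred at intensity \eqn{k} (the forward scale TFN goes in
#' cell \eqn{(i, j)}); a negative value means item \eqn{j} is preferred and
#' cell \eqn{(i, j)} receives the analytic reciprocal of intensity
#' \eqn{|k|}. Equal weights give intensity 1.
#'
#' @param w_i,w_j Positive weights (vectorised).
#' @return An integer vector of signed intensities in \eqn{\{-9..-2, 1..9\}}.
#' @examples
#' ideal_judgment(0.6, 0.2)  #  3
#' ideal_judgment(0.2, 0.6)  # -3
#' ideal_judgment(0.5, 0.5)  #  1
#' @export
ideal_judgment <- function(w_i, w_j) {
  if (any(w_i <= 0) || any(w_j <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  r <- w_i / w_j
  fwd <- pmin(pmax(floor(r + 0.5), 1), 9)
  bwd <- pmin(pmax(floor(1 / r + 0.5), 1), 9)
  out <- as.integer(ifelse(r >= 1, fwd, -bwd))
  out[out == -1L] <- 1L
  out
}

# Signed-intensity matrix of ideal judgments for a weight vector.
.ideal_int_mat <- function(w) {
  n <- length(w)
  I <- matrix(ideal_judgment(rep(w, times = n), rep(w, each = n)), n, n)
  diag(I) <- 1L
  # enforce antisymmetry exactly (guards against w_i/w_j rounding asymmetry
  # at cell boundaries): upper triangle wins
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) I[j, i] <- -I[i, j]
  I[I == -1L] <- 1L
  I
}

# Component matrices from a signed-intensity matrix.
.int_to_mats <- function(I) {
  sl <- c(1, 1, 1, 3, 3, 5, 5, 7, 7); sm <- as.numeric(1:9)
  su <- c(1, 3, 5, 5, 7, 7, 9, 9, 9)
  pos <- I > 0
  k <- abs(I)
  L <- ifelse(pos, sl[k], 1 / su[k])
  M <- ifelse(pos, sm[k], 1 / sm[k])
  U <- ifelse(pos, su[k], 1 / sl[k])
  dim(L) <- dim(M) <- dim(U) <- dim(I)
  list(L = L, M = M, U = U)
}

#' Ideal comparison matrix of a truth vector
#'
#' The noise-free fuzzy pairwise comparison matrix implied by a ground-truth
#' weight vector: every cell is the ladder TFN of [ideal_judgment()], with
#' reciprocals derived analytically so the matrix validates exactly.
#'
#' @param truth A `fahp_truth` tibble from [sample_true_weights()], a tibble
#'   with `item` and `weight` columns, or a named positive numeric vector.
#' @return A long-form comparison matrix tibble.
#' @export
ideal_matrix <- function(truth) {
  tw <- .as_truth(truth)
  p <- .int_to_mats(.ideal_int_mat(tw$weight))
  .mats_pcm(list(items = tw$item, L = p$L, M = p$M, U = p$U))
}

.as_truth <- function(truth) {
  if (is.data.frame(truth)) {
    if (!all(c("item", "weight") %in% names(truth)))
      stop("truth tibble must have columns item, weight", call. = FALSE)
    return(tibble::tibble(item = as.character(truth$item),
                          weight = as.numeric(truth$weight)))
  }
  if (is.numeric(truth)) {
    nm <- names(truth) %||% paste0("X", seq_along(truth))
    return(tibble::tibble(item = nm, weight = as.numeric(truth)))
  }
  stop("truth must be a tibble with item/weight or a numeric vector", call. = FALSE)
}

# Perturb the upper triangle of a signed-intensity matrix on the ladder:
# `max_steps` independent chances, each moving the absolute intensity one
# rung up or down with probability `step_probability`, clipped to [1, 9].
.perturb_int_mat <- function(I, step_probability, max_steps) {
  n <- nrow(I)
  if (n < 2 || max_steps == 0 || step_probability == 0) return(I)
  ut <- which(upper.tri(I))
  a <- abs(I[ut]); sgn <- sign(I[ut])
  for (s in seq_len(max_steps)) {
    move <- stats::runif(length(ut)) < step_probability
    dir <- sample(c(-1L, 1L), length(ut), replace = TRUE)
    a <- pmin(pmax(a + ifelse(move, dir, 0L), 1L), 9L)
  }
  I[ut] <- sgn * a
  I[I == -1L] <- 1L
  # rebuild lower triangle
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) I[j, i] <- -I[i, j]
  I[I == -1L] <- 1L
  I
}

#' Generate a synthetic expert panel with known ground truth
#'
#' Emulates a questionnaire study: for each hierarchy node a ground-truth
#' weight vector implies an ideal ladder judgment for every item pair;
#' each simulated expert reports that judgment after ladder noise (each
#' upper-triangle cell independently moves up to `max_steps` rungs, each with
#' probability `step_probability`, clipped to the 1--9 ladder). Reciprocal
#' cells are derived analytically, so every generated matrix is valid by
#' construction. The default panel size of 22 experts matches the reference
#' study.
#'
#' @param truth A single truth (see [ideal_matrix()]) or a named list of
#'   truths, one per hierarchy node.
#' @param n_experts Number of experts in the panel (default 22).
#' @param step_probability Chance that a judgment moves one rung on the
#'   ladder per step (default 0.2).
#' @param max_steps Maximum number of one-rung moves per judgment (default 1).
#' @param seed Optional integer seed; reruns with the same seed give an
#'   identical panel.
#' @return A list of class `fahp_panel` with elements `judgments` (long
#'   tibble: `expert_id`, `node`, `item_i`, `item_j`, `l`, `m`, `u`) and
#'   `truth` (tibble: `node`, `item`, `weight`), plus the generator settings
#'   as attributes.
#' @examples
#' tw <- sample_true_weights(4, seed = 7)
#' pan <- generate_panel(tw, n_experts = 3, step_probability = 0, seed = 7)
#' head(pan$judgments)
#' @export
generate_panel <- function(truth, n_experts = 22, step_probability = 0.2,
                           max_steps = 1, seed = NULL) {
  if (n_experts < 1) stop("n_experts must be >= 1", call. = FALSE)
  if (step_probability < 0 || step_probability > 1)
    stop("step_probability must be in [0, 1]", call. = FALSE)
  if (max_steps < 0) stop("max_steps must be >= 0", call. = FALSE)
  truths <- if (is.data.frame(truth) || is.numeric(truth)) list(node1 = truth) else truth
  if (!length(truths)) stop("no truth supplied", call. = FALSE)
  if (is.null(names(truths)) || any(!nzchar(names(truths))))
    stop("multi-node truths must be a named list (node code -> truth)", call. = FALSE)
  truths <- purrr::map(truths, .as_truth)
  expert_ids <- sprintf("E%02d", seq_len(n_experts))
  judgments <- .with_seed(seed, {
    purrr::imap_dfr(truths, function(tw, nd) {
      I0 <- .ideal_int_mat(tw$weight)
      purrr::map_dfr(expert_ids, function(e) {
        Ie <- .perturb_int_mat(I0, step_probability, max_steps)
        p <- .int_to_mats(Ie)
        out <- .mats_pcm(list(items = tw$item, L = p$L, M = p$M, U = p$U))
        out$expert_id <- e
        out$node <- nd
        out
      })
    })
  })
  judgments <- judgments[c("expert_id", "node", "item_i", "item_j", "l", "m", "u")]
  truth_tbl <- purrr::imap_dfr(truths, ~ tibble::tibble(node = .y, item = .x$item,
                                                        weight = .x$weight))
  out <- list(judgments = judgments, truth = truth_tbl)
  attr(out, "n_experts") <- n_experts
  attr(out, "step_probability") <- step_probability
  attr(out, "max_steps") <- max_steps
  attr(out, "seed") <- seed
  class(out) <- "fahp_panel"
  out
}

#' @export
print.fahp_panel <- function(x, ...) {
  cat("Synthetic expert panel: ", attr(x, "n_experts"), " experts, ",
      length(unique(x$judgments$node)), " node(s), step_probability = ",
      attr(x, "step_probability"), "\n", sep = "")
  print(utils::head(x$judgments, 10))
  invisible(x)
}

#' @rdname tidy.fahp_weights
#' @export
tidy.fahp_panel <- function(x, ...) x$judgments
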