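#' Fuzzy pairwise comparison matrices
#'
#' A fuzzy pairwise comparison matrix (PCM) over items \eqn{x_1, \dots, x_n}
#' is stored in long form: one row per ordered cell \eqn{(i, j)} with the
#' triangular fuzzy judgment \eqn{(l, m, u)} of item `item_i` against
#' `item_j`. A valid matrix has identity diagonal \eqn{(1,1,1)} and
#' reciprocal symmetry: the \eqn{(j, i)} cell equals the componentwise fuzzy
#' inverse \eqn{(1/u, 1/m, 1/l)} of the \eqn{(i, j)} cell.
#'
#' `as_pcm()` builds the long form from an upper-triangle specification (cells
#' with `item_i` preferred or equal), filling the diagonal and the analytic
#' reciprocals; cells already present for both directions are kept as given.
#'
#' @param judgments A data frame with columns `item_i`, `item_j`, `l`, `m`,
#'   `u`. Judgments may be supplied for one direction only.
#' @param items Optional character vector fixing the item order; defaults to
#'   first appearance in `judgments`.
#' @return A tibble with columns `item_i`, `item_j`, `l`, `m`, `u` covering
#'   all \eqn{n^2} cells, in row-major item order.
#' @examples
#' m <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 1, m = 3, u = 5))
#' validate_pcm(m)
#' @export
as_pcm <- function(judgments, items = NULL) {
  stopifnot(is.data.frame(judgments))
  need <- c("item_i", "item_j", "l", "m", "u")
  if (!all(need %in% names(judgments)))
    stop("judgments must have columns ", paste(need, collapse = ", "), call. = FALSE)
  judgments <- tibble::as_tibble(judgments)[need]
  items <- items %||% unique(c(rbind(judgments$item_i, judgments$item_j)))
  key <- function(i, j) paste(i, j, sep = "\r")
  have <- key(judgments$item_i, judgments$item_j)
  if (anyDuplicated(have))
    stop("duplicate cells in judgments: ",
         paste(unique(gsub("\r", " vs ", have[duplicated(have)])), collapse = "; "),
         call. = FALSE)
  grid <- tidyr::expand_grid(item_i = items, item_j = items)
  idx <- match(key(grid$item_i, grid$item_j), have)
  l <- judgments$l[idx]; m <- judgments$m[idx]; u <- judgments$u[idx]
  diag_cell <- grid$item_i == grid$item_j
  l[diag_cell] <- l[diag_cell] %|na|% 1
  m[diag_cell] <- m[diag_cell] %|na|% 1
  u[diag_cell] <- u[diag_cell] %|na|% 1
  # fill missing cells from the transposed cell's analytic inverse
  miss <- which(is.na(l))
  if (length(miss)) {
    tr <- match(key(grid$item_j[miss], grid$item_i[miss]), key(grid$item_i, grid$item_j))
    if (anyNA(l[tr]))
      stop("judgment missing for both directions of pair(s): ",
           paste(unique(paste(grid$item_i[miss][is.na(l[tr])],
                              grid$item_j[miss][is.na(l[tr])], sep = " vs ")),
                 collapse = "; "), call. = FALSE)
    l[miss] <- 1 / u[tr]; m[miss] <- 1 / m[tr]; u[miss] <- 1 / l[tr]
  }
  tibble::tibble(item_i = grid$item_i, item_j = grid$item_j, l = l, m = m, u = u)
}

#' Validate a fuzzy pairwise comparison matrix
#'
#' Checks that a long-form matrix is square and complete, that every entry is
#' a positive TFN, that the diagonal is \eqn{(1, 1, 1)}, and that reciprocal
#' symmetry holds within `tol` per component. All violations are reported
#' together, naming the offending cells.
#'
#' The default tolerance 0.01 accepts judgments entered from the published
#' two-decimal reciprocal triples.
#'
#' @param pcm A long-form PCM tibble (see [as_pcm()]).
#' @param tol Per-component absolute tolerance for reciprocity.
#' @return `pcm`, invisibly unchanged, if valid; otherwise an error listing
#'   every violating cell.
#' @export
validate_pcm <- function(pcm, tol = 0.01) {
  p <- .pcm_mats(pcm)
  n <- length(p$items)
  if (n < 2) stop("pairwise comparison matrix needs at least 2 items", call. = FALSE)
  probs <- character()
  bad_tfn <- p$L <= 0 | p$L > p$M + 1e-9 | p$M > p$U + 1e-9
  for (w in which(bad_tfn))
    probs <- c(probs, sprintf("cell (%s, %s): not a positive TFN with l <= m <= u",
                              p$items[row(p$L)[w]], p$items[col(p$L)[w]]))
  for (i in seq_len(n)) {
    if (abs(p$L[i, i] - 1) > 1e-9 || abs(p$M[i, i] - 1) > 1e-9 || abs(p$U[i, i] - 1) > 1e-9)
      probs <- c(probs, sprintf("diagonal cell (%s, %s): must be (1, 1, 1), got (%g, %g, %g)",
                                p$items[i], p$items[i], p$L[i, i], p$M[i, i], p$U[i, i]))
  }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dev <- max(abs(p$L[j, i] - 1 / p$U[i, j]),
               abs(p$M[j, i] - 1 / p$M[i, j]),
               abs(p$U[j, i] - 1 / p$L[i, j]))
    if (!is.finite(dev) || dev > tol)
      probs <- c(probs, sprintf(
        "reciprocity violated for (%s, %s): (%g, %g, %g) vs inverse of (%g, %g, %g) [max dev %.4g]",
        p$items[j], p$items[i], p$L[j, i], p$M[j, i], p$U[j, i],
        p$L[i, j], p$M[i, j], p$U[i, j], dev))
  }
  if (length(probs))
    stop("invalid pairwise comparison matrix:\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  invisible(pcm)
}

# Internal: long tibble <-> list(items, L, M, U) with n x n component matrices.
.pcm_mats <- function(pcm) {
  stopifnot(is.data.frame(pcm))
  need <- c("item_i", "item_j", "l", "m", "u")
  if (!all(need %in% names(pcm)))
    stop("PCM must have columns ", paste(need, collapse = ", "), call. = FALSE)
  items <- unique(c(rbind(pcm$item_i, pcm$item_j)))
  n <- length(items)
  if (nrow(pcm) != n * n)
    stop("PCM is not a complete square grid: ", nrow(pcm), " cells for ",
         n, " items (expected ", n * n, "); use as_pcm() to complete it",
         call. = FALSE)
  ri <- match(pcm$item_i, items); cj <- match(pcm$item_j, items)
  if (anyDuplicated(ri + n * cj)) stop("duplicate PCM cells", call. = FALSE)
  L <- M <- U <- matrix(NA_real_, n, n)
  idx <- cbind(ri, cj)
  L[idx] <- pcm$l; M[idx] <- pcm$m; U[idx] <- pcm$u
  list(items = items, L = L, M = M, U = U)
}

.mats_pcm <- function(p) {
  n <- length(p$items)
  tibble::tibble(
    item_i = rep(p$items, each = n),
    item_j = rep(p$items, times = n),
    l = as.vector(t(p$L)), m = as.vector(t(p$M)), u = as.vector(t(p$U))
  )
}

#' Build a comparison matrix from linguistic judgments
#'
#' Translates labelled judgments to fuzzy judgments through the nine-level
#' scale and completes the matrix. Each row states how `item_i` compares to
#' `item_j` as either a scale label or an intensity 1--9 (column `label` or
#' `intensity`); the reciprocal direction is derived analytically.
#'
#' @param judgments Data frame with columns `item_i`, `item_j` and one of
#'   `label` (scale label) or `intensity` (integer 1--9).
#' @inheritParams as_pcm
#' @return A complete long-form PCM tibble.
#' @examples
#' pcm_from_judgments(data.frame(item_i = "a", item_j = "b",
#'                               label = "Moderately more important"))
#' @export
pcm_from_judgments <- function(judgments, items = NULL) {
  stopifnot(is.data.frame(judgments))
  keys <- if ("label" %in% names(judgments)) judgments$label
          else if ("intensity" %in% names(judgments)) judgments$intensity
          else stop("judgments must have a 'label' or 'intensity' column", call. = FALSE)
  fw <- purrr::map(keys, function(k) unclass(scale_lookup(k)$forward)[1, ])
  out <- tibble::tibble(
    item_i = judgments$item_i, item_j = judgments$item_j,
    l = purrr::map_dbl(fw, "l"), m = purrr::map_dbl(fw, "m"), u = purrr::map_dbl(fw, "u")
  )
  as_pcm(out, items = items)
}

#' Read and write comparison matrices
#'
#' Long-format delimited text with columns `item_i`, `item_j`, `l`, `m`, `u`
#' (comma- or tab-separated by extension), and a JSON grid form holding the
#' item order plus the three component matrices row by row.
#'
#' @param pcm A long-form PCM tibble.
#' @param path Output or input file path (`.csv`/`.tsv` for the delimited
#'   form; `.json` for the grid form).
#' @return Readers return a long-form PCM tibble; writers return `path`
#'   invisibly.
#' @export
write_pcm <- function(pcm, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    p <- .pcm_mats(pcm)
    row_list <- function(x) lapply(asplit(x, 1), as.numeric)
    jsonlite::write_json(
      list(items = p$items, l = row_list(p$L), m = row_list(p$M),
           u = row_list(p$U)),
      path, digits = NA, auto_unbox = TRUE)
  } else if (tolower(tools::file_ext(path)) == "tsv") {
    readr::write_tsv(pcm, path)
  } else {
    readr::write_csv(pcm, path)
  }
  invisible(path)
}

#' @rdname write_pcm
#' @export
read_pcm <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    n <- length(x$items)
    as_grid <- function(z) {
      if (is.matrix(z)) matrix(as.numeric(z), n, n)  # one row per list entry
      else matrix(unlist(z, use.names = FALSE), n, byrow = TRUE)
    }
    return(.mats_pcm(list(items = x$items, L = as_grid(x$l),
                          M = as_grid(x$m), U = as_grid(x$u))))
  }
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_pcm(out)
}
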