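#' Aggregate an expert panel's judgment matrices
#'
#' Combines the fuzzy pairwise comparison matrices of several experts into a
#' single matrix per hierarchy node. The default rule is the componentwise
#' geometric mean, the standard group-AHP aggregation and the only common
#' rule that preserves reciprocal symmetry of fuzzy judgment matrices
#' exactly: the geometric mean of the experts' \eqn{(j, i)} cells equals the
#' fuzzy inverse of the geometric mean of their \eqn{(i, j)} cells. A
#' componentwise arithmetic mean is available for sensitivity analysis; it
#' does not preserve reciprocity, so downstream validation may need a looser
#' tolerance or `validate = FALSE`.
#'
#' @param panel A long judgment table with columns `expert_id`, `item_i`,
#'   `item_j`, `l`, `m`, `u` and (for multi-node panels) `node`. Each
#'   expert's per-node block must be a complete valid matrix over the same
#'   items.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @param validate Validate each expert matrix before aggregating.
#' @param tol Reciprocity tolerance for validation.
#' @return A long-form comparison matrix tibble; for multi-node panels,
#'   stacked with a leading `node` column.
#' @examples
#' one <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 1, m = 3, u = 5))
#' two <- as_pcm(data.frame(item_i = "a", item_j = "b", l = 0.2, m = 0.33, u = 1))
#' panel <- dplyr::bind_rows(
#'   dplyr::mutate(one, expert_id = "e1"),
#'   dplyr::mutate(two, expert_id = "e2")
#' )
#' aggregate_judgments(panel)
#' @export
aggregate_judgments <- function(panel, method = c("geometric", "arithmetic"),
                                validate = TRUE, tol = 0.01) {
  method <- match.arg(method)
  stopifnot(is.data.frame(panel))
  need <- c("expert_id", "item_i", "item_j", "l", "m", "u")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!nrow(panel)) stop("empty panel: no expert judgments", call. = FALSE)
  if ("node" %in% names(panel)) {
    out <- dplyr::group_modify(
      dplyr::group_by(panel, node),
      ~ .aggregate_one(.x, method, validate, tol))
    return(dplyr::ungroup(out))
  }
  .aggregate_one(panel, method, validate, tol)
}

.aggregate_one <- function(panel, method, validate, tol) {
  split_experts <- split(panel, panel$expert_id)
  mats <- purrr::map(split_experts, function(df) {
    if (validate) validate_pcm(df[c("item_i", "item_j", "l", "m", "u")], tol = tol)
    .pcm_mats(df)
  })
  items <- mats[[1]]$items
  same <- purrr::map_lgl(mats, ~ setequal(.x$items, items))
  if (!all(same))
    stop("experts cover different item sets: ",
         paste(names(mats)[!same], collapse = ", "), call. = FALSE)
  # align item order across experts
  mats <- purrr::map(mats, function(p) {
    o <- match(items, p$items)
    list(items = items, L = p$L[o, o], M = p$M[o, o], U = p$U[o, o])
  })
  E <- length(mats)
  comb <- function(f) {
    if (method == "geometric")
      exp(Reduce(`+`, purrr::map(mats, ~ log(.x[[f]]))) / E)
    else
      Reduce(`+`, purrr::map(mats, ~ .x[[f]])) / E
  }
  .mats_pcm(list(items = items, L = comb("L"), M = comb("M"), U = comb("U")))
}

#' Check an expert panel for completeness and consistency
#'
#' Report-only diagnostic over a multi-expert judgment panel: flags experts
#' missing a node covered by others, item sets that differ between experts
#' within a node, and per-expert matrix violations (diagonal, reciprocity,
#' malformed TFNs). Nothing is raised; questionnaire problems are the
#' dominant error source in practice and are best reviewed together.
#'
#' @inheritParams aggregate_judgments
#' @return A tibble with columns `expert_id`, `node`, `issue`, `detail`;
#'   zero rows for a clean panel.
#' @export
panel_completeness <- function(panel, tol = 0.01) {
  stopifnot(is.data.frame(panel))
  if (!nrow(panel))
    return(tibble::tibble(expert_id = character(), node = character(),
                          issue = character(), detail = character()))
  if (!"node" %in% names(panel)) panel$node <- "(single)"
  experts <- unique(panel$expert_id)
  nodes <- unique(panel$node)
  findings <- list()
  note <- function(e, nd, issue, detail)
    findings[[length(findings) + 1]] <<-
      tibble::tibble(expert_id = e, node = nd, issue = issue, detail = detail)
  for (nd in nodes) {
    blk <- panel[panel$node == nd, ]
    ref_items <- unique(c(rbind(blk$item_i, blk$item_j)))
    for (e in experts) {
      sub <- blk[blk$expert_id == e, ]
      if (!nrow(sub)) { note(e, nd, "missing_node", "no judgments for this node"); next }
      its <- unique(c(rbind(sub$item_i, sub$item_j)))
      if (!setequal(its, ref_items))
        note(e, nd, "item_mismatch",
             paste0("items differ from panel: missing ",
                    paste(setdiff(ref_items, its), collapse = ", ")))
      ok <- tryCatch({
        validate_pcm(sub[c("item_i", "item_j", "l", "m", "u")], tol = tol); TRUE
      }, error = function(err) conditionMessage(err))
      if (!isTRUE(ok)) note(e, nd, "invalid_matrix", ok)
    }
  }
  if (!length(findings))
    return(tibble::tibble(expert_id = character(), node = character(),
                          issue = character(), detail = character()))
  dplyr::bind_rows(findings)
}

#' Read and write expert judgment panels
#'
#' Panels are exchanged as long-format delimited text with columns
#' `expert_id`, `node`, `item_i`, `item_j` and either a linguistic `label`
#' (translated through [scale_lookup()]) or numeric `l`, `m`, `u` columns.
#' On reading, each expert-by-node block is completed to a full matrix
#' (diagonal and analytic reciprocals) via [as_pcm()].
#'
#' @param panel A long panel tibble.
#' @param path File path (`.csv` or `.tsv`).
#' @return `read_panel()` returns a completed long panel tibble with columns
#'   `expert_id`, `node`, `item_i`, `item_j`, `l`, `m`, `u`; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("expert_id", "item_i", "item_j") %in% names(raw)))
    stop("panel file must have columns expert_id, item_i, item_j", call. = FALSE)
  if (!"node" %in% names(raw)) raw$node <- "(single)"
  if (!all(c("l", "m", "u") %in% names(raw))) {
    if (!"label" %in% names(raw))
      stop("panel file needs either l/m/u columns or a linguistic label column",
           call. = FALSE)
    fw <- purrr::map(raw$label, ~ unclass(scale_lookup(.x)$forward)[1, ])
    raw$l <- purrr::map_dbl(fw, "l")
    raw$m <- purrr::map_dbl(fw, "m")
    raw$u <- purrr::map_dbl(fw, "u")
  }
  out <- dplyr::group_modify(
    dplyr::group_by(raw, expert_id, node),
    ~ as_pcm(.x[c("item_i", "item_j", "l", "m", "u")]))
  dplyr::ungroup(out)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  if (tolower(tools::file_ext(path)) == "tsv") readr::write_tsv(panel, path)
  else readr::write_csv(panel, path)
  invisible(path)
}
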