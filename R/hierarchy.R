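#' Dense descending ranking
#'
#' Ranks scores so the highest score receives priority 1, equal scores share
#' a priority, and the next distinct score receives the previous priority
#' plus one (dense ranking — no gaps after ties, unlike competition ranking).
#' This is the tie convention of the published priority tables, where two
#' subfactors scored 0.088 share priority 5 and the next score 0.054 takes
#' priority 6.
#'
#' Ties are decided by exact equality of the stored values; published scores
#' are stored at their three-decimal printed precision so printed ties rank
#' as ties.
#'
#' @param scores Numeric vector of scores (higher is better).
#' @return An integer vector of priorities, same length as `scores`.
#' @examples
#' rank_dense(c(0.160, 0.119, 0.088, 0.088, 0.054, 0.035, 0.201, 0.255))
#' @export
rank_dense <- function(scores) {
  if (length(scores) == 0) stop("cannot rank an empty score vector", call. = FALSE)
  if (!is.numeric(scores) || anyNA(scores))
    stop("scores must be numeric without NA", call. = FALSE)
  .dense_rank_desc(scores)
}

#' Add a dense priority column to a score table
#'
#' Tidy wrapper around [rank_dense()]: appends a `priority` column ranking a
#' score column, optionally within groups (e.g. per parent factor).
#'
#' @param data A data frame of scored items.
#' @param score Column holding the scores (tidy-eval; default `score`).
#' @param by Optional column to group by before ranking (tidy-eval).
#' @return `data` with an integer `priority` column.
#' @examples
#' add_priorities(hospital_bed_tables()$factors[1:3])
#' @export
add_priorities <- function(data, score = score, by = NULL) {
  score <- rlang::enquo(score)
  by <- rlang::enquo(by)
  if (!rlang::quo_is_null(by)) data <- dplyr::group_by(data, !!by)
  out <- dplyr::mutate(data, priority = rank_dense(!!score))
  dplyr::ungroup(out)
}

#' Assemble and validate a criterion hierarchy
#'
#' Builds a validated two-level hierarchy (goal, factors, subfactors) from a
#' long node table. Checks for a single root, unique codes, known parents
#' (no orphans), and at most two criterion levels below the goal.
#'
#' @param nodes A data frame with columns `code`, `label`, `parent` (`NA`
#'   parent marks the goal), optionally `local_weight`.
#' @return A tibble of class `fahp_hierarchy` with columns `code`, `label`,
#'   `parent`, `level` (0 = goal, 1 = factor, 2 = subfactor) and
#'   `local_weight` (NA when unset).
#' @examples
#' h <- assemble_hierarchy(hospital_bed_hierarchy())
#' dplyr::count(h, level)
#' @export
assemble_hierarchy <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  if (!all(c("code", "label", "parent") %in% names(nodes)))
    stop("nodes must have columns code, label, parent", call. = FALSE)
  nodes <- tibble::as_tibble(nodes)
  if (anyDuplicated(nodes$code))
    stop("duplicate node codes: ",
         paste(unique(nodes$code[duplicated(nodes$code)]), collapse = ", "),
         call. = FALSE)
  roots <- nodes$code[is.na(nodes$parent)]
  if (length(roots) != 1)
    stop("hierarchy must have exactly one goal node (parent = NA); found ",
         length(roots), call. = FALSE)
  orphans <- setdiff(stats::na.omit(nodes$parent), nodes$code)
  if (length(orphans))
    stop("orphan nodes: parent code(s) not defined: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  level <- integer(nrow(nodes))
  lv <- 0L; current <- roots
  while (length(current)) {
    level[nodes$code %in% current] <- lv
    current <- nodes$code[!is.na(nodes$parent) & nodes$parent %in% current]
    lv <- lv + 1L
    if (lv > 10L) stop("hierarchy contains a cycle", call. = FALSE)
  }
  if (max(level) > 2L)
    stop("hierarchy deeper than two criterion levels is not supported",
         call. = FALSE)
  if (!"local_weight" %in% names(nodes)) nodes$local_weight <- NA_real_
  out <- dplyr::mutate(nodes, level = level)
  out <- out[c("code", "label", "parent", "level", "local_weight")]
  class(out) <- c("fahp_hierarchy", class(out))
  out
}

#' Global weights of hierarchy leaves
#'
#' Composes local weights down the hierarchy: the global weight of a leaf is
#' its local weight times the local weight of its parent factor (the goal has
#' implicit weight 1). Sibling local weights are checked to sum to 1 within
#' `tol` — use a loose tolerance for weights loaded from three-decimal
#' printed tables (the published reference tables need 0.05: one printed
#' subfactor block sums to 0.959).
#'
#' @param hierarchy A hierarchy tibble from [assemble_hierarchy()] with
#'   `local_weight` set on every non-goal node, or a node table plus a
#'   separate `weights` table.
#' @param weights Optional tibble `code`, `local_weight` (or `code`,
#'   `weight`) used to fill the hierarchy's local weights.
#' @param tol Tolerance for sibling local-weight sums.
#' @return A tibble with one row per leaf: `code`, `label`, `parent`,
#'   `local_weight`, `global_weight`.
#' @examples
#' tabs <- hospital_bed_tables()
#' h <- hospital_bed_hierarchy()
#' w <- dplyr::bind_rows(
#'   dplyr::transmute(tabs$factors, code, local_weight = score),
#'   dplyr::transmute(tabs$subfactors, code, local_weight = score)
#' )
#' gw <- global_weights(h, w, tol = 0.05)
#' gw[gw$code == "C53", ] # 0.249 * 0.293
#' @export
global_weights <- function(hierarchy, weights = NULL, tol = 1e-6) {
  if (!inherits(hierarchy, "fahp_hierarchy")) hierarchy <- assemble_hierarchy(hierarchy)
  h <- tibble::as_tibble(hierarchy)
  if (!is.null(weights)) {
    wcol <- if ("local_weight" %in% names(weights)) "local_weight"
            else if ("weight" %in% names(weights)) "weight"
            else stop("weights must have a local_weight or weight column", call. = FALSE)
    h$local_weight <- weights[[wcol]][match(h$code, weights$code)]
  }
  unset <- h$code[h$level > 0 & is.na(h$local_weight)]
  if (length(unset))
    stop("local weight unset for node(s): ", paste(unset, collapse = ", "),
         call. = FALSE)
  sib <- dplyr::summarise(
    dplyr::group_by(h[h$level > 0, ], parent),
    s = sum(local_weight), .groups = "drop")
  bad <- sib$parent[abs(sib$s - 1) > tol]
  if (length(bad))
    stop("sibling local weights do not sum to 1 (tol ", tol, ") under: ",
         paste(bad, collapse = ", "), call. = FALSE)
  leaves <- h[!h$code %in% h$parent[!is.na(h$parent)] & h$level > 0, ]
  parent_w <- h$local_weight[match(leaves$parent, h$code)]
  parent_w[is.na(parent_w)] <- 1 # leaf directly under the goal
  dplyr::transmute(leaves, code, label, parent, local_weight,
                   global_weight = local_weight * parent_w)
}
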