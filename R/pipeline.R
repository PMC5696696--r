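#' Derive per-node weights from an expert panel
#'
#' End-to-end weighting step: checks panel completeness, aggregates each
#' node's expert matrices, and runs extent analysis per node. With `out_dir`
#' set, writes one weight table per node (`weights_<node>.tsv` with columns
#' `item`, `v_min`, `weight`), plus a `run_metadata.json` record holding the
#' seed, aggregation rule, package version and a hash of the configuration,
#' so identical configurations yield byte-identical outputs.
#'
#' @param panel A long judgment panel (tibble as from [generate_panel()]'s
#'   `$judgments`, [read_panel()], or a `fahp_panel`), or a path to a panel
#'   file.
#' @param aggregation `"geometric"` or `"arithmetic"`.
#' @param out_dir Optional output directory (created if needed).
#' @param seed Optional integer recorded in the metadata (the weighting step
#'   itself is deterministic).
#' @param tol Reciprocity tolerance for validation.
#' @return A tibble with columns `node`, `item`, `v_min`, `weight`.
#' @export
run_weights <- function(panel, aggregation = c("geometric", "arithmetic"),
                        out_dir = NULL, seed = NULL, tol = 0.01) {
  aggregation <- match.arg(aggregation)
  if (inherits(panel, "fahp_panel")) panel <- panel$judgments
  if (is.character(panel) && length(panel) == 1) panel <- read_panel(panel)
  if (!"node" %in% names(panel)) panel$node <- "(single)"
  report <- panel_completeness(panel, tol = tol)
  if (nrow(report))
    stop("panel is incomplete or inconsistent:\n  ",
         paste(sprintf("[%s / %s] %s: %s", report$expert_id, report$node,
                       report$issue, report$detail), collapse = "\n  "),
         call. = FALSE)
  agg <- aggregate_judgments(panel, method = aggregation, validate = FALSE)
  weights <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(agg, node),
    function(df, key) {
      w <- compute_weights(df[c("item_i", "item_j", "l", "m", "u")],
                           validate = aggregation == "geometric", tol = tol)
      tibble::as_tibble(w)
    }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nd in unique(weights$node)) {
      readr::write_tsv(weights[weights$node == nd, c("item", "v_min", "weight")],
                       file.path(out_dir, paste0("weights_", .safe_name(nd), ".tsv")))
    }
    .write_metadata(out_dir, list(step = "weights", aggregation = aggregation,
                                  seed = seed, nodes = unique(weights$node)))
  }
  weights
}

#' Rank a weighted hierarchy in the published table layout
#'
#' Combines per-node local weights with a hierarchy into dense-ranked
#' priority tables: one factor-level table (children of the goal) and one
#' subfactor table ranked within each factor, both with columns `code`,
#' `label`, `score`, `priority` and scores rounded to three decimals as in
#' the published layout. Global (composed) weights are included for leaves.
#'
#' @param weights A tibble of local weights: columns `node` (parent code),
#'   `item` (child code) and `weight`, as returned by [run_weights()]; or a
#'   tibble with `code`/`weight` when `hierarchy` codes are unambiguous.
#' @param hierarchy A node table (see [assemble_hierarchy()]); defaults to
#'   the built-in hospital-bed hierarchy.
#' @param out_dir Optional output directory for `rank_factors.tsv`,
#'   `rank_subfactors.tsv`, a markdown `report.md` and run metadata.
#' @param digits Rounding applied to reported scores (default 3, the
#'   published precision). Ranking uses the unrounded weights.
#' @param tol Sibling-sum tolerance passed to [global_weights()].
#' @return A list with tibbles `factors` and `subfactors`.
#' @export
run_rank <- function(weights, hierarchy = hospital_bed_hierarchy(),
                     out_dir = NULL, digits = 3, tol = 0.02) {
  h <- assemble_hierarchy(hierarchy)
  if (!nrow(weights)) stop("empty weight table", call. = FALSE)
  if (!all(c("node", "item", "weight") %in% names(weights)))
    stop("weights must have columns node, item, weight", call. = FALSE)
  goal <- h$code[h$level == 0]
  missing_items <- setdiff(weights$item, h$code)
  if (length(missing_items))
    stop("weight items not in hierarchy: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  local <- tibble::tibble(code = weights$item, local_weight = weights$weight)
  need <- h$code[h$level > 0]
  unset <- setdiff(need, local$code)
  if (length(unset))
    stop("missing weights for node(s): ", paste(unset, collapse = ", "),
         call. = FALSE)
  hw <- h
  hw$local_weight <- local$local_weight[match(hw$code, local$code)]
  fa <- hw[hw$level == 1, ]
  factors <- tibble::tibble(code = fa$code, label = fa$label,
                            score = round_half_up(fa$local_weight, digits),
                            priority = rank_dense(fa$local_weight))
  gw <- global_weights(hw, tol = tol)
  sf <- hw[hw$level == 2, ]
  subfactors <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(tibble::tibble(factor_code = sf$parent, code = sf$code,
                                   label = sf$label, weight = sf$local_weight),
                    factor_code),
    ~ tibble::tibble(code = .x$code, label = .x$label,
                     score = round_half_up(.x$weight, digits),
                     priority = rank_dense(.x$weight))))
  subfactors$global_weight <- gw$global_weight[match(subfactors$code, gw$code)]
  out <- list(factors = factors, subfactors = subfactors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(factors, file.path(out_dir, "rank_factors.tsv"))
    readr::write_tsv(subfactors, file.path(out_dir, "rank_subfactors.tsv"))
    writeLines(.rank_report_md(out), file.path(out_dir, "report.md"))
    .write_metadata(out_dir, list(step = "rank", goal = goal, digits = digits))
  }
  out
}

.rank_report_md <- function(ranked) {
  md_table <- function(df) {
    df$score <- sprintf("%.3f", df$score)
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }
  c("# Priority report",
    "", "## Factors", "",
    md_table(ranked$factors),
    "", "## Subfactors (ranked within factor)", "",
    md_table(ranked$subfactors[c("factor_code", "code", "label", "score", "priority")]))
}

#' Run and summarise a recovery experiment, writing results to disk
#'
#' Thin wrapper over [recovery_experiment()] that also writes the
#' per-replicate table (`recovery_replicates.tsv`), a one-row summary
#' (`recovery_summary.tsv`) and run metadata to `out_dir`.
#'
#' @inheritParams recovery_experiment
#' @param out_dir Optional output directory.
#' @return The `fahp_recovery` tibble, invisibly when `out_dir` is set.
#' @export
run_recover <- function(n_items = 8, n_experts = 22, step_probability = 0.2,
                        max_steps = 1, replicates = 200, seed = NULL,
                        concentration = 1, min_ratio = 1.5, max_spread = 9,
                        aggregation = "geometric", out_dir = NULL) {
  res <- recovery_experiment(n_items = n_items, n_experts = n_experts,
                             step_probability = step_probability,
                             max_steps = max_steps, replicates = replicates,
                             seed = seed, concentration = concentration,
                             min_ratio = min_ratio, max_spread = max_spread,
                             aggregation = aggregation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(res),
                     file.path(out_dir, "recovery_replicates.tsv"))
    readr::write_tsv(glance(res), file.path(out_dir, "recovery_summary.tsv"))
    .write_metadata(out_dir, attr(res, "settings"))
    return(invisible(res))
  }
  res
}

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

.write_metadata <- function(out_dir, config) {
  config <- config[order(names(config))]
  meta <- list(
    package = "extentahp",
    version = as.character(utils::packageVersion("extentahp")),
    config = config,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(meta)
}
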