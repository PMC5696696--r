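`%||%` <- function(x, y) if (is.null(x)) y else x

`%|na|%` <- function(x, y) {
  x[is.na(x)] <- y
  x
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the current RNG stream is used as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

.dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

utils::globalVariables(c(
  ".", "item", "item_i", "item_j", "l", "m", "u", "expert_id", "node",
  "weight", "v_min", "code", "label", "parent", "score", "priority",
  "level", "local_weight", "global_weight", "spearman", "exact",
  "replicate_id", "intensity", "factor_code", "n_items", "issue", "detail"
))
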