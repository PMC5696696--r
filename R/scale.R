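# Nine-level linguistic judgment scale. Forward triples are the published
# row-over-column TFNs; `recip_*` are the column-over-row triples exactly as
# printed at two decimals. Reciprocals used in computation are always derived
# analytically as (1/u, 1/m, 1/l); see the note in ?fuzzy_scale about the one
# printed rounding anomaly.
.scale_data <- function() {
  tibble::tibble(
    intensity = 1:9,
    label = c(
      "Equally important",
      "Equally important to moderately more important",
      "Moderately more important",
      "Moderately more important to strongly more important",
      "Strongly more important",
      "Strongly to very Strongly more important",
      "Very Strongly more important",
      "Very Strongly to extremely more important",
      "Extremely more important"
    ),
    l = c(1, 1, 1, 3, 3, 5, 5, 7, 7),
    m = as.numeric(1:9),
    u = c(1, 3, 5, 5, 7, 7, 9, 9, 9),
    recip_l = c(1, 0.33, 0.2, 0.2, 0.14, 0.14, 0.11, 0.11, 0.11),
    recip_m = c(1, 0.5, 0.33, 0.25, 0.2, 0.17, 0.14, 0.13, 0.11),
    recip_u = c(1, 1, 1, 0.33, 0.33, 0.2, 0.2, 0.14, 0.13)
  )
}

#' The nine-level linguistic judgment scale
#'
#' Returns the qualitative judgment scale used throughout the package: nine
#' intensity rungs from "Equally important" (1) to "Extremely more important"
#' (9), each with its forward triangular fuzzy number (preferred row over
#' column) and the published reciprocal triple (preferred column over row,
#' printed at two decimals).
#'
#' The modal value of each forward TFN equals its intensity; odd intensities
#' are the five pure judgment grades and even intensities the four
#' intermediate grades. Computations in this package never use the printed
#' two-decimal reciprocals: reciprocal matrix entries are derived analytically
#' as \eqn{(1/u, 1/m, 1/l)}. For eight of the nine rungs the analytic
#' reciprocal reproduces the printed triple after half-up rounding to two
#' decimals; the published upper reciprocal component of the (7, 9, 9) rung is
#' 0.13 whereas \eqn{1/7} rounds to 0.14 — a rounding anomaly in the printed
#' table that this package documents rather than reproduces.
#'
#' @return A tibble with columns `intensity`, `label`, `l`, `m`, `u`
#'   (forward TFN) and `recip_l`, `recip_m`, `recip_u` (printed reciprocal).
#' @examples
#' fuzzy_scale()
#' @export
fuzzy_scale <- function() .scale_data()

#' Look up a linguistic scale entry
#'
#' Retrieves one rung of the nine-level scale by its verbatim label
#' (case-insensitive) or by its intensity (1--9).
#'
#' @param key A single label string or an integer intensity in `1:9`.
#' @return A list with elements `intensity`, `label`, `forward` (a [tfn()]),
#'   `reciprocal` (the printed two-decimal [tfn()]) and `reciprocal_exact`
#'   (the analytic inverse of `forward`).
#' @examples
#' scale_lookup("Moderately more important")
#' scale_lookup(9)$forward
#' @export
scale_lookup <- function(key) {
  sc <- .scale_data()
  if (length(key) != 1) stop("key must be a single label or intensity", call. = FALSE)
  if (is.numeric(key)) {
    if (!key %in% 1:9)
      stop("unknown intensity ", key, "; valid intensities are 1-9", call. = FALSE)
    i <- match(as.integer(key), sc$intensity)
  } else if (is.character(key)) {
    i <- match(tolower(trimws(key)), tolower(sc$label))
    if (is.na(i))
      stop("unknown scale label ", dQuote(key), "; valid labels are: ",
           paste(dQuote(sc$label), collapse = ", "), call. = FALSE)
  } else {
    stop("key must be a label string or an intensity integer", call. = FALSE)
  }
  row <- sc[i, ]
  list(
    intensity = row$intensity,
    label = row$label,
    forward = tfn(row$l, row$m, row$u),
    reciprocal = tfn(row$recip_l, row$recip_m, row$recip_u),
    reciprocal_exact = tfn_inv(tfn(row$l, row$m, row$u))
  )
}

#' Read and write a linguistic scale
#'
#' Serialises a judgment scale (as returned by [fuzzy_scale()], or any tibble
#' with the same columns) to JSON or YAML, one document entry per rung with the
#' label, intensity, forward triple and reciprocal triple; and reads it back.
#' The format is inferred from the file extension unless given explicitly.
#'
#' @param scale A scale tibble (default the built-in nine-level scale).
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param format `"json"` or `"yaml"`; by default inferred from `path`.
#' @return `write_fuzzy_scale()` returns `path` invisibly; `read_fuzzy_scale()`
#'   returns a scale tibble with the same columns as [fuzzy_scale()].
#' @export
write_fuzzy_scale <- function(scale = fuzzy_scale(), path, format = NULL) {
  format <- format %||% .guess_format(path)
  entries <- purrr::pmap(scale, function(intensity, label, l, m, u,
                                         recip_l, recip_m, recip_u) {
    list(intensity = intensity, label = label,
         forward = c(l, m, u), reciprocal = c(recip_l, recip_m, recip_u))
  })
  if (format == "json") {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(entries, path)
  }
  invisible(path)
}

#' @rdname write_fuzzy_scale
#' @export
read_fuzzy_scale <- function(path, format = NULL) {
  format <- format %||% .guess_format(path)
  entries <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  purrr::map_dfr(entries, function(e) {
    fw <- as.numeric(unlist(e$forward))
    rc <- as.numeric(unlist(e$reciprocal))
    tibble::tibble(intensity = as.integer(e$intensity), label = e$label,
                   l = fw[1], m = fw[2], u = fw[3],
                   recip_l = rc[1], recip_m = rc[2], recip_u = rc[3])
  })
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("cannot infer scale format from ", dQuote(path),
       "; use format = \"json\" or \"yaml\"", call. = FALSE)
}
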