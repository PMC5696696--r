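#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is an ordered triple \eqn{(l, m, u)} with
#' \eqn{l \le m \le u}: membership rises linearly from the lower support bound
#' `l` to 1 at the modal value `m` and falls linearly to 0 at the upper support
#' bound `u`. TFNs encode the graded intensity of a linguistic pairwise
#' judgment ("moderately more important", ...) in fuzzy AHP.
#'
#' `tfn()` is vectorised: the object is a numeric matrix with one row per
#' fuzzy number and columns `l`, `m`, `u`.
#'
#' @param l,m,u Numeric vectors (recycled to a common length) with
#'   `l <= m <= u` elementwise.
#' @return An object of class `tfn`: an `n x 3` numeric matrix with columns
#'   `l`, `m`, `u`.
#' @examples
#' tfn(1, 3, 5)
#' tfn_add(tfn(1, 2, 3), tfn(3, 4, 5))
#' tfn_inv(tfn(1, 2, 3))
#' @seealso [fuzzy_scale()] for the nine-level linguistic scale.
#' @export
tfn <- function(l, m, u) {
  n <- max(length(l), length(m), length(u))
  x <- cbind(l = rep_len(as.numeric(l), n),
             m = rep_len(as.numeric(m), n),
             u = rep_len(as.numeric(u), n))
  if (anyNA(x)) stop("TFN components must not contain NA", call. = FALSE)
  bad <- x[, "l"] > x[, "m"] + 1e-12 | x[, "m"] > x[, "u"] + 1e-12
  if (any(bad)) {
    stop(sprintf("invalid TFN: need l <= m <= u (violated at row%s %s)",
                 if (sum(bad) > 1) "s" else "",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  structure(x, class = "tfn")
}

#' Coerce to a triangular fuzzy number
#'
#' Accepts a `tfn`, a numeric vector of length 3, an `n x 3` numeric matrix,
#' or a data frame with columns `l`, `m`, `u`.
#'
#' @param x Object to coerce.
#' @return A `tfn` object.
#' @export
as_tfn <- function(x) {
  if (is_tfn(x)) return(x)
  if (is.data.frame(x)) {
    if (!all(c("l", "m", "u") %in% names(x)))
      stop("data frame must have columns l, m, u", call. = FALSE)
    return(tfn(x$l, x$m, x$u))
  }
  if (is.matrix(x) && ncol(x) == 3) return(tfn(x[, 1], x[, 2], x[, 3]))
  if (is.numeric(x) && length(x) == 3) return(tfn(x[1], x[2], x[3]))
  stop("cannot coerce to tfn: expected length-3 numeric, n x 3 matrix, ",
       "or data frame with columns l, m, u", call. = FALSE)
}

#' @rdname as_tfn
#' @export
is_tfn <- function(x) inherits(x, "tfn")

.tfn_recycle <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  na <- nrow(a); nb <- nrow(b)
  if (na != nb) {
    if (na == 1) a <- a[rep(1L, nb), , drop = FALSE]
    else if (nb == 1) b <- b[rep(1L, na), , drop = FALSE]
    else stop("incompatible tfn lengths: ", na, " vs ", nb, call. = FALSE)
  }
  list(a = unclass(a), b = unclass(b))
}

#' Triangular fuzzy arithmetic
#'
#' Componentwise operations on triangular fuzzy numbers:
#' \deqn{M_1 + M_2 = (l_1 + l_2,\; m_1 + m_2,\; u_1 + u_2)}
#' \deqn{M_1 \times M_2 = (l_1 l_2,\; m_1 m_2,\; u_1 u_2)}
#' \deqn{M^{-1} = (1/u,\; 1/m,\; 1/l)}
#' The product and inverse are the standard triangular approximations used in
#' extent analysis and require strictly positive support. The `+` and `*`
#' operators are also available for `tfn` objects.
#'
#' @param a,b `tfn` objects (or objects coercible via [as_tfn()]); rows are
#'   recycled when one operand has a single row.
#' @return A `tfn` with one row per elementwise operation.
#' @examples
#' tfn_mul(tfn(1, 3, 5), tfn(0.2, 0.33, 1))
#' tfn_inv(tfn(3, 5, 7))
#' @export
tfn_add <- function(a, b) {
  ab <- .tfn_recycle(a, b)
  tfn(ab$a[, "l"] + ab$b[, "l"], ab$a[, "m"] + ab$b[, "m"], ab$a[, "u"] + ab$b[, "u"])
}

#' @rdname tfn_add
#' @export
tfn_mul <- function(a, b) {
  ab <- .tfn_recycle(a, b)
  if (any(ab$a[, "l"] <= 0) || any(ab$b[, "l"] <= 0))
    stop("tfn_mul requires strictly positive TFNs", call. = FALSE)
  tfn(ab$a[, "l"] * ab$b[, "l"], ab$a[, "m"] * ab$b[, "m"], ab$a[, "u"] * ab$b[, "u"])
}

#' @rdname tfn_add
#' @export
tfn_inv <- function(a) {
  a <- unclass(as_tfn(a))
  if (any(a[, "l"] <= 0))
    stop("tfn_inv requires strictly positive TFNs", call. = FALSE)
  tfn(1 / a[, "u"], 1 / a[, "m"], 1 / a[, "l"])
}

#' @export
Ops.tfn <- function(e1, e2) {
  switch(.Generic,
         "+" = tfn_add(e1, e2),
         "*" = tfn_mul(e1, e2),
         stop(sprintf("operator '%s' is not defined for tfn objects", .Generic),
              call. = FALSE))
}

#' @export
format.tfn <- function(x, digits = 4, ...) {
  x <- unclass(x)
  sprintf("(%s, %s, %s)",
          format(x[, "l"], digits = digits, trim = TRUE),
          format(x[, "m"], digits = digits, trim = TRUE),
          format(x[, "u"], digits = digits, trim = TRUE))
}

#' @export
print.tfn <- function(x, ...) {
  cat("<tfn[", nrow(x), "]>\n", sep = "")
  cat(format(x, ...), sep = "\n")
  invisible(x)
}

#' @export
`[.tfn` <- function(x, i, ...) {
  out <- unclass(x)[i, , drop = FALSE]
  structure(out, class = "tfn")
}

#' @export
as.data.frame.tfn <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Round half away from zero
#'
#' Rounds with the "half-up" convention used for comparisons against published
#' tables (e.g. 0.125 rounds to 0.13), unlike [round()] which rounds half to
#' even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
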