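#' @keywords internal
#' @useDynLib silkcode, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Symbol levels of a matrix-code cell
#'
#' Each square unit of an edible matrix code carries exactly one of four
#' levels: empty (`NONE`) or one of the three fluorescent silk inks
#' (`ECFP`, `EGFP`, `MKATE2`). The three colour openings never overlap in
#' a cell, so the per-cell alphabet is quaternary.
#'
#' @format Named integer vector mapping symbol names to stable codes 0-3.
#' @export
code_symbols <- c(NONE = 0L, ECFP = 1L, EGFP = 2L, MKATE2 = 3L)

#' Fluorescence channel names in their fixed concatenation order
#' @format Character vector of length 3.
#' @export
channel_order <- c("ECFP", "EGFP", "MKATE2")

.supported_n <- c(5L, 7L, 9L)

#' Construct a matrix code
#'
#' @param cells integer matrix (n x n) of symbol values in 0-3.
#' @param physical_metadata optional list (e.g. unit size in um, taggant
#'   size in mm); carried through untouched, never computed on.
#' @param allow_other_n allow odd grid sides other than 5, 7, 9.
#' @return A `matrix_code` object.
#' @export
matrix_code <- function(cells, physical_metadata = NULL, allow_other_n = FALSE) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  n <- nrow(cells)
  if (ncol(cells) != n)
    stop("cells must be a square matrix, got ", n, " x ", ncol(cells))
  check_grid_side(n, allow_other_n)
  if (anyNA(cells) || any(cells < 0L | cells > 3L))
    stop("cell symbols must be integers in 0-3 (NONE/ECFP/EGFP/MKATE2)")
  structure(list(n = n, cells = cells, physical_metadata = physical_metadata),
            class = "matrix_code")
}

check_grid_side <- function(n, allow_other_n = FALSE) {
  if (n %in% .supported_n) return(invisible(n))
  if (allow_other_n && n >= 3L && n %% 2L == 1L) return(invisible(n))
  stop("grid side n = ", n, " is not one of the supported sizes (5, 7, 9); ",
       "pass allow_other_n = TRUE for other odd n >= 3")
}

#' @export
print.matrix_code <- function(x, ...) {
  cat("matrix_code: ", x$n, " x ", x$n, " grid\n", sep = "")
  sym <- matrix(names(code_symbols)[x$cells + 1L], x$n, x$n)
  print(sym, quote = FALSE)
  invisible(x)
}

#' @export
`==.matrix_code` <- function(e1, e2) {
  e1$n == e2$n && all(e1$cells == e2$cells)
}

#' Draw a uniformly random matrix code
#'
#' Every cell is drawn independently and uniformly over the four symbol
#' levels. Deterministic for a fixed seed.
#'
#' @param n grid side (5, 7 or 9 unless `allow_other_n`).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @inheritParams matrix_code
#' @return A `matrix_code`.
#' @export
random_code <- function(n = 7L, seed = NULL, allow_other_n = FALSE) {
  check_grid_side(n, allow_other_n)
  if (!is.null(seed)) set.seed(seed)
  cells <- matrix(sample(0:3, n * n, replace = TRUE), n, n)
  matrix_code(cells, allow_other_n = allow_other_n)
}

#' Construct a per-channel binary key
#'
#' @param channel one of `"ECFP"`, `"EGFP"`, `"MKATE2"`.
#' @param bits integer vector of 0/1 values, row-major cell order.
#' @export
channel_key <- function(channel, bits) {
  channel <- match.arg(channel, channel_order)
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits < 0L | bits > 1L))
    stop("bits must be 0/1")
  structure(list(channel = channel, bits = bits), class = "channel_key")
}

# Row-major scan: row by row, left to right (R matrices are column-major,
# hence the transpose).
cells_row_major <- function(code) as.vector(t(code$cells))

#' Extract the three per-channel binary keys from a matrix code
#'
#' For channel X, bit i (row-major from the top-left) is 1 iff cell i
#' holds symbol X; empty cells contribute 0 to all three channels. A
#' 7 x 7 code yields three 49-bit keys.
#'
#' @param code a `matrix_code`.
#' @return Named list of three `channel_key`s in order ECFP, EGFP, MKATE2.
#' @export
encode_channels <- function(code) {
  stopifnot(inherits(code, "matrix_code"))
  v <- cells_row_major(code)
  keys <- lapply(channel_order, function(ch)
    channel_key(ch, as.integer(v == code_symbols[[ch]])))
  names(keys) <- channel_order
  keys
}

#' Concatenate three channel keys into a digitized key
#'
#' The binary keys of the three colour channels are concatenated in the
#' fixed order ECFP, EGFP, MKATE2, giving a digitized key of 3n^2 bits
#' (147 for a 7 x 7 code).
#'
#' @param k1,k2,k3 `channel_key`s for ECFP, EGFP and MKATE2 respectively;
#'   alternatively `k1` may be the list returned by [encode_channels()].
#' @return A `digitized_key`.
#' @export
concat_key <- function(k1, k2 = NULL, k3 = NULL) {
  if (is.null(k2) && is.list(k1) && !inherits(k1, "channel_key")) {
    k2 <- k1[[2]]; k3 <- k1[[3]]; k1 <- k1[[1]]
  }
  keys <- list(k1, k2, k3)
  if (!all(vapply(keys, inherits, TRUE, "channel_key")))
    stop("concat_key expects three channel_key objects")
  chans <- vapply(keys, `[[`, "", "channel")
  if (!identical(chans, channel_order))
    stop("channel keys must be supplied in order ECFP, EGFP, MKATE2; got ",
         paste(chans, collapse = ", "))
  lens <- vapply(keys, function(k) length(k$bits), 1L)
  if (length(unique(lens)) != 1L)
    stop("channel keys have mismatched lengths: ", paste(lens, collapse = ", "))
  n <- as.integer(round(sqrt(lens[1])))
  if (n * n != lens[1])
    stop("channel key length ", lens[1], " is not a square")
  digitized_key(c(k1$bits, k2$bits, k3$bits), n = n)
}

#' Construct a digitized key from raw bits
#'
#' A digitized key is the ordered concatenation of the three channel keys
#' (ECFP then EGFP then MKATE2), 3n^2 bits in total. Raw decoder output is
#' representable even when it violates per-cell exclusivity; validation
#' happens on conversion back to a matrix code.
#'
#' @param bits 0/1 integer vector of length 3n^2.
#' @param n grid side; inferred from `length(bits)` when `NULL`.
#' @export
digitized_key <- function(bits, n = NULL) {
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits < 0L | bits > 1L)) stop("bits must be 0/1")
  if (is.null(n)) {
    n <- as.integer(round(sqrt(length(bits) / 3)))
  }
  if (3L * n * n != length(bits))
    stop("digitized key length ", length(bits), " is not 3*n^2 for n = ", n)
  structure(list(bits = bits, n = as.integer(n), channel_order = channel_order),
            class = "digitized_key")
}

#' @export
print.digitized_key <- function(x, ...) {
  cat("digitized_key: ", length(x$bits), " bits (n = ", x$n,
      "; order ", paste(x$channel_order, collapse = ","), ")\n", sep = "")
  cat(paste(x$bits, collapse = ""), "\n")
  invisible(x)
}

channel_bits <- function(key, channel) {
  i <- match(channel, channel_order)
  s <- key$n^2
  key$bits[((i - 1L) * s + 1L):(i * s)]
}

#' Reconstruct the matrix code encoded by a digitized key
#'
#' Inverse of `concat_key(encode_channels(code))`. Each cell takes the
#' symbol of its unique set channel bit, or `NONE` when all three bits are
#' 0. A cell with two or more channel bits set is a decoding conflict and
#' raises a validation error naming the offending cell.
#'
#' @param key a `digitized_key`.
#' @inheritParams matrix_code
#' @return A `matrix_code`.
#' @export
key_to_matrix <- function(key, allow_other_n = FALSE) {
  stopifnot(inherits(key, "digitized_key"))
  n <- key$n
  b <- matrix(key$bits, ncol = 3L)        # column c = channel c, row-major cells
  conflicts <- which(rowSums(b) > 1L)
  if (length(conflicts))
    stop("per-cell exclusivity violated: cell(s) ",
         paste(conflicts - 1L, collapse = ", "),
         " (row-major, 0-based) have more than one channel bit set")
  digits <- as.integer(b %*% 1:3)
  matrix_code(matrix(digits, n, n, byrow = TRUE), allow_other_n = allow_other_n)
}

#' Reconstruct the quaternary key of a digitized key
#'
#' Digit i is the symbol value of cell i: 0 NONE, 1 eCFP, 2 eGFP,
#' 3 mKate2; n^2 digits in row-major order.
#'
#' @inheritParams key_to_matrix
#' @return A `quaternary_key` (list with `digits`).
#' @export
to_quaternary <- function(key) {
  code <- key_to_matrix(key, allow_other_n = TRUE)
  structure(list(digits = cells_row_major(code), n = code$n),
            class = "quaternary_key")
}

#' Reconstruct the double binary key of a digitized key
#'
#' Each quaternary digit is emitted as two bits, most-significant bit
#' first (3 -> 11, 2 -> 10, 1 -> 01, 0 -> 00); 2n^2 bits in total (98 for
#' a 7 x 7 code).
#'
#' @inheritParams key_to_matrix
#' @return 0/1 integer vector of length 2n^2.
#' @export
to_double_binary <- function(key) {
  q <- to_quaternary(key)$digits
  as.integer(rbind(q %/% 2L, q %% 2L))
}

# ---- exact big-integer arithmetic (base 1e4 limbs, little-endian) ----
# Kept deliberately tiny: the only consumers are encoding-capacity powers.

bigint <- function(x) {
  stopifnot(is.numeric(x), x >= 0, x == floor(x), x < 2^53)
  limbs <- integer(0)
  x <- as.numeric(x)
  repeat {
    limbs <- c(limbs, as.integer(x %% 1e4))
    x <- floor(x / 1e4)
    if (x == 0) break
  }
  structure(list(limbs = limbs), class = "bigint")
}

bigint_mul <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  acc <- numeric(length(la) + length(lb))
  for (i in seq_along(la)) {
    if (la[i] == 0) next
    idx <- (i - 1L) + seq_along(lb)
    acc[idx] <- acc[idx] + la[i] * lb
  }
  # carry propagation (doubles stay < 2^53 for the sizes used here)
  carry <- 0
  for (j in seq_along(acc)) {
    v <- acc[j] + carry
    acc[j] <- v %% 1e4
    carry <- floor(v / 1e4)
  }
  while (carry > 0) {
    acc <- c(acc, carry %% 1e4)
    carry <- floor(carry / 1e4)
  }
  while (length(acc) > 1 && acc[length(acc)] == 0) acc <- acc[-length(acc)]
  structure(list(limbs = as.integer(acc)), class = "bigint")
}

bigint_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  result <- bigint(1)
  b <- if (inherits(base, "bigint")) base else bigint(base)
  e <- as.integer(exp)
  while (e > 0L) {
    if (e %% 2L == 1L) result <- bigint_mul(result, b)
    b <- bigint_mul(b, b)
    e <- e %/% 2L
  }
  result
}

#' @export
format.bigint <- function(x, ...) {
  limbs <- rev(x$limbs)
  paste0(limbs[1], paste(sprintf("%04d", limbs[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' Scientific-notation approximation of a big integer
#'
#' @param x a big integer as returned by [capacity()].
#' @param digits significant digits in the mantissa.
#' @return String like `"1.78e+44"`.
#' @export
bigint_scientific <- function(x, digits = 3) {
  s <- format(x)
  exponent <- nchar(s) - 1L
  mantissa <- as.numeric(paste0(substr(s, 1, 1), ".",
                                substr(s, 2, min(nchar(s), digits + 4L))))
  mantissa <- signif(mantissa, digits)
  if (mantissa >= 10) { mantissa <- mantissa / 10; exponent <- exponent + 1L }
  sprintf("%.*ge+%02d", digits, mantissa, exponent)
}

#' Encoding capacity of a matrix code
#'
#' The number of possible output keys of an input matrix array is c^s,
#' where c is the bit-level of the keys (c = 2 for binary bits) and s the
#' key size. Computed as an exact arbitrary-precision integer; a 147-bit
#' binary key gives 2^147 (about 1.78e44).
#'
#' @param c bit-level, integer >= 2.
#' @param s key size in symbols, integer >= 0.
#' @return A `bigint`; its decimal rendering via `format()`, scientific
#'   approximation via [bigint_scientific()].
#' @export
capacity <- function(c, s) {
  stopifnot(c >= 2, c == floor(c), s >= 0, s == floor(s))
  bigint_pow(bigint(c), s)
}

#' Nominal and physically realizable capacities of an n x n code
#'
#' The nominal capacity treats the 3n^2 channel bits as free, 2^(3n^2).
#' Per-cell exclusivity (one symbol per cell) restricts realizable codes
#' to 4^(n^2), which is strictly smaller for every n >= 1.
#'
#' @param n grid side.
#' @return List with `nominal` and `physical` bigints and their
#'   scientific renderings.
#' @export
capacity_summary <- function(n) {
  nom <- capacity(2, 3L * n * n)
  phy <- capacity(4, n * n)
  list(nominal = nom, physical = phy,
       nominal_sci = bigint_scientific(nom),
       physical_sci = bigint_scientific(phy))
}

# strict less-than on bigints
bigint_lt <- function(a, b) {
  la <- length(a$limbs); lb <- length(b$limbs)
  if (la != lb) return(la < lb)
  for (i in rev(seq_len(la))) {
    if (a$limbs[i] != b$limbs[i]) return(a$limbs[i] < b$limbs[i])
  }
  FALSE
}

# ---- JSON serialization of keys and codes ----

#' Serialize a digitized key or matrix code to JSON
#'
#' Keys serialize as `{"n": int, "channel_order": [...], "bits": "0/1
#' string"}`; codes as `{"n": int, "cells": [[0-3,...],...]}` (rows of the
#' grid).
#'
#' @param x a `digitized_key` or `matrix_code`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
code_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "digitized_key")) {
    list(n = x$n, channel_order = x$channel_order,
         bits = paste(x$bits, collapse = ""))
  } else if (inherits(x, "matrix_code")) {
    list(n = x$n, cells = unname(lapply(seq_len(x$n), function(i) x$cells[i, ])))
  } else stop("unsupported type for JSON serialization")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Parse a digitized key or matrix code from JSON
#'
#' @param json JSON string or path to a JSON file.
#' @return A `digitized_key` or `matrix_code` depending on the payload.
#' @export
code_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (!is.null(obj$bits)) {
    bits <- as.integer(strsplit(obj$bits, "")[[1]])
    digitized_key(bits, n = obj$n)
  } else {
    matrix_code(matrix(as.integer(obj$cells), obj$n, obj$n), allow_other_n = TRUE)
  }
}
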