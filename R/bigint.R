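# Minimal arbitrary-precision non-negative integers.
#
# The architecture space holds up to 450^10 ~ 3.4e26 candidates, beyond the
# 2^53 exact range of doubles, so exact counting needs big integers.  Numbers
# are stored as little-endian base-1e4 limb vectors (doubles); limb products
# stay below 2^53 for any count this package ever forms.

BIG_BASE <- 1e4

#' Create a big integer
#'
#' Constructs an exact arbitrary-precision non-negative integer from a
#' numeric scalar or a decimal digit string.
#'
#' @param x A non-negative integer-valued scalar (must be below 2^53), or a
#'   string of decimal digits.
#' @return An object of class `bigint`.
#' @examples
#' bigint(450)
#' bigint("340507970680999119131250000")
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    s <- gsub("[ ,]", "", x)
    if (!grepl("^[0-9]+$", s)) stop("not a decimal digit string: ", x)
    s <- sub("^0+(?=.)", "", s, perl = TRUE)
    n <- nchar(s)
    # little-endian limbs, chunked in groups of four digits from the right
    ends <- seq(n, 1, by = -4L)
    limbs <- vapply(ends, function(i) {
      as.numeric(substr(s, max(1L, i - 3L), i))
    }, numeric(1))
    return(new_bigint(limbs))
  }
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x != floor(x))
    stop("bigint() needs a single non-negative integer value")
  if (x > 2^53) stop("value too large for exact conversion; pass a digit string")
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  new_bigint(limbs)
}

new_bigint <- function(limbs) {
  # strip leading (high-order) zero limbs
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) limbs <- limbs[-length(limbs)]
  structure(list(limbs = limbs), class = "bigint")
}

big_carry <- function(limbs) {
  carry <- 0
  for (i in seq_along(limbs)) {
    v <- limbs[i] + carry
    limbs[i] <- v %% BIG_BASE
    carry <- floor(v / BIG_BASE)
  }
  while (carry > 0) {
    limbs <- c(limbs, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  limbs
}

big_add <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  n <- max(length(a$limbs), length(b$limbs))
  la <- c(a$limbs, numeric(n - length(a$limbs)))
  lb <- c(b$limbs, numeric(n - length(b$limbs)))
  new_bigint(big_carry(la + lb))
}

big_mul <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  la <- a$limbs; lb <- b$limbs
  out <- numeric(length(la) + length(lb))
  for (i in seq_along(la)) {
    if (la[i] == 0) next
    idx <- (i - 1L) + seq_along(lb)
    out[idx] <- out[idx] + la[i] * lb
    # keep partial sums well below 2^53
    out <- big_carry(out)
  }
  new_bigint(out)
}

big_pow <- function(a, k) {
  a <- bigint(a)
  k <- as.integer(k)
  if (k < 0) stop("negative exponent")
  result <- bigint(1)
  base <- a
  while (k > 0) {
    if (k %% 2L == 1L) result <- big_mul(result, base)
    base <- big_mul(base, base)
    k <- k %/% 2L
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

#' @export
as.double.bigint <- function(x, ...) {
  sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1))
}

#' @export
`==.bigint` <- function(e1, e2) identical(bigint(e1)$limbs, bigint(e2)$limbs)
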