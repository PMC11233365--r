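#' Exact rational vectors
#'
#' `rq()` creates a vector of exact rational numbers stored as reduced
#' numerator/denominator pairs. All index computations in pdindex are carried
#' out on these vectors, so identities such as completeness (index values
#' summing to the total weight of a system) hold exactly rather than to
#' floating-point tolerance. Numerators and denominators are kept as
#' double-precision integers; any intermediate that would leave the exactly
#' representable range (|.| > 2^53) raises an error instead of silently
#' losing precision.
#'
#' @param n integer-valued numerators.
#' @param d integer-valued denominators (recycled), non-zero.
#'
#' @return A vector of class `pdindex_rq`.
#' @examples
#' rq(1, 3) + rq(1, 6)
#' sum(rq(c(1, 1, 1), 3)) == rq(1)
#' @export
rq <- function(n = double(), d = 1) {
  vctrs::vec_assert(as.double(n))
  args <- vctrs::vec_recycle_common(n = as.double(n), d = as.double(d))
  if (any(args$d == 0)) stop("rational with zero denominator", call. = FALSE)
  if (any(args$n != round(args$n)) || any(args$d != round(args$d))) {
    stop("rq() expects integer-valued numerator and denominator; use as_rq() for decimals",
         call. = FALSE)
  }
  rq_canonical(args$n, args$d)
}

new_rq <- function(n = double(), d = double()) {
  vctrs::new_rcrd(list(n = n, d = d), class = "pdindex_rq")
}

rq_overflow_check <- function(...) {
  vals <- c(...)
  if (any(abs(vals) > 2^53, na.rm = TRUE)) {
    stop("exact rational arithmetic overflow (|value| > 2^53)", call. = FALSE)
  }
  if (any(is.na(vals))) stop("NA in exact rational arithmetic", call. = FALSE)
  invisible(NULL)
}

# vectorized Euclid on non-negative integer-valued doubles
rq_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    live <- b > 0
    r <- a
    r[live] <- a[live] %% b[live]
    a[live] <- b[live]
    b[live] <- r[live]
  }
  a[a == 0] <- 1
  a
}

rq_canonical <- function(n, d) {
  rq_overflow_check(n, d)
  s <- sign(d)
  n <- n * s
  d <- d * s
  g <- rq_gcd(n, d)
  new_rq(n / g, d / g)
}

#' @export
rq_num <- function(x) vctrs::field(x, "n")

#' @export
rq_den <- function(x) vctrs::field(x, "d")

#' Convert objects to exact rationals
#'
#' Accepts integer-valued numerics, strings of the form `"3/4"`, integer
#' strings, and decimal strings (scientific notation allowed), which are
#' converted exactly (e.g. `"0.15"` becomes 3/20). Doubles that are not
#' integer-valued are converted through their shortest decimal representation
#' (15 significant digits).
#'
#' @param x object to convert.
#' @return A `pdindex_rq` vector.
#' @examples
#' as_rq("31/6")
#' as_rq("0.125")
#' @export
as_rq <- function(x) UseMethod("as_rq")

#' @export
#' @method as_rq pdindex_rq
as_rq.pdindex_rq <- function(x) x

#' @export
#' @method as_rq numeric
as_rq.numeric <- function(x) {
  intish <- x == round(x) & abs(x) <= 2^53
  if (all(intish)) return(rq(x, 1))
  out <- character(length(x))
  out[intish] <- format(x[intish], scientific = FALSE)
  out[!intish] <- vapply(x[!intish], format, "", digits = 15, scientific = TRUE)
  as_rq(out)
}

#' @export
#' @method as_rq integer
as_rq.integer <- function(x) rq(x, 1)

#' @export
#' @method as_rq character
as_rq.character <- function(x) {
  parse1 <- function(s) {
    s <- trimws(s)
    if (grepl("^[+-]?[0-9]+$", s)) return(c(as.numeric(s), 1))
    if (grepl("^[+-]?[0-9]+[ ]*/[ ]*[0-9]+$", s)) {
      parts <- strsplit(s, "/")[[1]]
      return(c(as.numeric(parts[1]), as.numeric(parts[2])))
    }
    m <- regmatches(s, regexec("^([+-]?)([0-9]*)\\.?([0-9]*)[eE]?([+-]?[0-9]+)?$", s))[[1]]
    if (length(m) == 0 || (m[3] == "" && m[4] == "")) {
      stop("cannot parse '", s, "' as a rational number", call. = FALSE)
    }
    digits <- paste0(m[3], m[4])
    if (nchar(digits) > 15) stop("too many digits for exact conversion: '", s, "'", call. = FALSE)
    n <- as.numeric(digits)
    if (m[2] == "-") n <- -n
    d <- 10^nchar(m[4])
    e <- if (is.na(m[5]) || m[5] == "") 0 else as.numeric(m[5])
    if (e > 0) n <- n * 10^e else if (e < 0) d <- d * 10^(-e)
    c(n, d)
  }
  parts <- vapply(unname(x), parse1, numeric(2))
  rq_canonical(unname(parts[1, ]), unname(parts[2, ]))
}

#' @export
#' @method format pdindex_rq
format.pdindex_rq <- function(x, ...) {
  n <- rq_num(x)
  d <- rq_den(x)
  ifelse(d == 1, format(n, scientific = FALSE, trim = TRUE),
         paste0(format(n, scientific = FALSE, trim = TRUE), "/",
                format(d, scientific = FALSE, trim = TRUE)))
}

#' @export
#' @method as.character pdindex_rq
as.character.pdindex_rq <- function(x, ...) format(x)

#' @export
#' @method as.double pdindex_rq
as.double.pdindex_rq <- function(x, ...) rq_num(x) / rq_den(x)

#' @export
#' @method vec_ptype_abbr pdindex_rq
vec_ptype_abbr.pdindex_rq <- function(x, ...) "rq"

#' @export
#' @method vec_ptype2 pdindex_rq.pdindex_rq
vec_ptype2.pdindex_rq.pdindex_rq <- function(x, y, ...) new_rq()

#' @export
#' @method vec_ptype2 pdindex_rq.double
vec_ptype2.pdindex_rq.double <- function(x, y, ...) double()

#' @export
#' @method vec_ptype2 double.pdindex_rq
vec_ptype2.double.pdindex_rq <- function(x, y, ...) double()

#' @export
#' @method vec_cast pdindex_rq.pdindex_rq
vec_cast.pdindex_rq.pdindex_rq <- function(x, to, ...) x

#' @export
#' @method vec_cast double.pdindex_rq
vec_cast.double.pdindex_rq <- function(x, to, ...) as.double(x)

#' @export
#' @method vec_cast pdindex_rq.integer
vec_cast.pdindex_rq.integer <- function(x, to, ...) rq(x, 1)

#' @export
#' @method vec_cast pdindex_rq.double
vec_cast.pdindex_rq.double <- function(x, to, ...) as_rq(x)

#' @export
#' @method vec_cast character.pdindex_rq
vec_cast.character.pdindex_rq <- function(x, to, ...) format(x)

#' @export
#' @method vec_proxy_compare pdindex_rq
vec_proxy_compare.pdindex_rq <- function(x, ...) rq_num(x) / rq_den(x)

rq_add <- function(x, y) {
  args <- vctrs::vec_recycle_common(x, y)
  n1 <- rq_num(args[[1]]); d1 <- rq_den(args[[1]])
  n2 <- rq_num(args[[2]]); d2 <- rq_den(args[[2]])
  g <- rq_gcd(d1, d2)
  n <- n1 * (d2 / g) + n2 * (d1 / g)
  d <- (d1 / g) * d2
  rq_canonical(n, d)
}

rq_mul <- function(x, y) {
  args <- vctrs::vec_recycle_common(x, y)
  n1 <- rq_num(args[[1]]); d1 <- rq_den(args[[1]])
  n2 <- rq_num(args[[2]]); d2 <- rq_den(args[[2]])
  g1 <- rq_gcd(n1, d2)
  g2 <- rq_gcd(n2, d1)
  rq_canonical((n1 / g1) * (n2 / g2), (d1 / g2) * (d2 / g1))
}

rq_neg <- function(x) new_rq(-rq_num(x), rq_den(x))

rq_inv <- function(x) {
  if (any(rq_num(x) == 0)) stop("division by exact zero", call. = FALSE)
  rq_canonical(rq_den(x), rq_num(x))
}

#' @export
#' @method vec_arith pdindex_rq
vec_arith.pdindex_rq <- function(op, x, y, ...) {
  UseMethod("vec_arith.pdindex_rq", y)
}

#' @export
#' @method vec_arith.pdindex_rq default
vec_arith.pdindex_rq.default <- function(op, x, y, ...) {
  vctrs::stop_incompatible_op(op, x, y)
}

rq_arith <- function(op, x, y) {
  switch(op,
    "+" = rq_add(x, y),
    "-" = rq_add(x, rq_neg(y)),
    "*" = rq_mul(x, y),
    "/" = rq_mul(x, rq_inv(y)),
    stop("unsupported operation '", op, "' on rationals", call. = FALSE)
  )
}

#' @export
#' @method vec_arith.pdindex_rq pdindex_rq
vec_arith.pdindex_rq.pdindex_rq <- function(op, x, y, ...) rq_arith(op, x, y)

#' @export
#' @method vec_arith.pdindex_rq numeric
vec_arith.pdindex_rq.numeric <- function(op, x, y, ...) rq_arith(op, x, as_rq(y))

#' @export
#' @method vec_arith.numeric pdindex_rq
vec_arith.numeric.pdindex_rq <- function(op, x, y, ...) rq_arith(op, as_rq(x), y)

#' @export
#' @method vec_arith.pdindex_rq MISSING
vec_arith.pdindex_rq.MISSING <- function(op, x, y, ...) {
  switch(op,
    "-" = rq_neg(x),
    "+" = x,
    vctrs::stop_incompatible_op(op, x, y)
  )
}

#' @export
#' @method vec_math pdindex_rq
vec_math.pdindex_rq <- function(.fn, .x, ...) {
  switch(.fn,
    sum = rq_sum(.x),
    abs = new_rq(abs(rq_num(.x)), rq_den(.x)),
    mean = rq_mul(rq_sum(.x), rq(1, length(.x))),
    cumsum = {
      acc <- rq(0)
      out <- vctrs::vec_init(new_rq(), length(.x))
      for (i in seq_along(.x)) {
        acc <- rq_add(acc, .x[i])
        out[i] <- acc
      }
      out
    },
    vctrs::vec_math_base(.fn, .x, ...)
  )
}

#' Exact sum of a rational vector
#' @param x a `pdindex_rq` vector.
#' @return A length-one `pdindex_rq`.
#' @export
rq_sum <- function(x) {
  acc <- rq(0)
  for (i in seq_along(x)) acc <- rq_add(acc, x[i])
  acc
}

#' Exact inner product of two rational vectors
#' @param x,y `pdindex_rq` vectors of equal length.
#' @return A length-one `pdindex_rq`.
#' @export
rq_dot <- function(x, y) rq_sum(rq_mul(x, y))

rq_zero <- function(n = 1) rq(rep(0, n), 1)

rq_is_zero <- function(x) rq_num(x) == 0
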