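#' @useDynLib planarcrn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot runif setNames
NULL

# Minimal exact rational arithmetic on numerator/denominator pairs.
#
# Numerators and denominators are stored as doubles but kept integral, so
# arithmetic is exact as long as intermediates stay below 2^53 (far beyond
# anything the small exponent lattices here produce).  Exponents such as
# -1/4 or 1/2 must survive a round-trip through the JSON network format,
# and the chain geometry (h-values) must come out exactly, which is why
# plain floating point is not used for these quantities.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

rat_norm <- function(num, den) {
  stopifnot(all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- mapply(function(n, d) if (n == 0) d else rat_gcd(n, d), num, den)
  list(num = num / g, den = den / g)
}

#' Parse rational numbers written as "p/q" or decimal strings
#'
#' @param x character or numeric vector; entries like `"-1/4"`, `"3"`,
#'   `"0.5"` are accepted.  Decimals are converted exactly (they are finite
#'   binary/decimal fractions in all file formats used here).
#' @return list with integral `num` and `den` vectors
#' @keywords internal
rat_parse <- function(x) {
  x <- as.character(x)
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[[i]])
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed rational: ", s)
      num[i] <- as.numeric(parts[1]); den[i] <- as.numeric(parts[2])
    } else {
      v <- as.numeric(s)
      if (is.na(v)) stop("malformed rational: ", s)
      if (v == round(v)) { num[i] <- v; den[i] <- 1 } else {
        # decimal string: scale by a power of ten
        dec <- sub("^-?[0-9]*\\.", "", s)
        p <- 10^nchar(dec)
        num[i] <- round(v * p); den[i] <- p
      }
    }
  }
  rat_norm(num, den)
}

rat_format <- function(num, den) {
  ifelse(den == 1, formatC(num, format = "fg"),
         paste0(formatC(num, format = "fg"), "/", formatC(den, format = "fg")))
}

rat_add <- function(a, b) rat_norm(a$num * b$den + b$num * a$den, a$den * b$den)
rat_sub <- function(a, b) rat_norm(a$num * b$den - b$num * a$den, a$den * b$den)
rat_mul <- function(a, b) rat_norm(a$num * b$num, a$den * b$den)
rat_num <- function(a) a$num / a$den

rat_at <- function(a, i) list(num = a$num[i], den = a$den[i])
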