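# Exact rational helpers. Tier thresholds are "num/den" strings and every
# threshold comparison is done by integer cross-multiplication, so boundary
# cases (19 of 20 at a 95% floor) are decided exactly, never in floating point.

frac_parse <- function(x) {
  if (is.numeric(x) && length(x) == 2L) {
    num <- as.integer(x[1]); den <- as.integer(x[2])
  } else {
    parts <- strsplit(as.character(x), "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
      stop("malformed fraction: ", x, call. = FALSE)
    }
    num <- as.integer(parts[1]); den <- as.integer(parts[2])
  }
  if (den <= 0L || num < 0L) stop("fraction must be non-negative with positive denominator: ", x, call. = FALSE)
  c(num = num, den = den)
}

frac_str <- function(num, den) paste0(num, "/", den)

# a/b >= num/den for counts a out of b (b may be 0: vacuous, treated as pass)
frac_ge <- function(a, b, frac) {
  f <- frac_parse(frac)
  if (b == 0L) return(TRUE)
  as.double(a) * f[["den"]] >= as.double(f[["num"]]) * b
}

# a/b <= num/den
frac_le <- function(a, b, frac) {
  f <- frac_parse(frac)
  if (b == 0L) return(TRUE)
  as.double(a) * f[["den"]] <= as.double(f[["num"]]) * b
}

# smallest integer a with a/b >= num/den: ceil(num*b/den), pure integer
frac_ceil_count <- function(b, frac) {
  f <- frac_parse(frac)
  as.integer((f[["num"]] * as.integer(b) + f[["den"]] - 1L) %/% f[["den"]])
}

# largest integer a with a/b <= num/den: floor(num*b/den), pure integer
frac_floor_count <- function(b, frac) {
  f <- frac_parse(frac)
  as.integer((f[["num"]] * as.integer(b)) %/% f[["den"]])
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

frac_reduce <- function(num, den) {
  if (num == 0L) return(c(num = 0L, den = 1L))
  g <- gcd2(as.integer(num), as.integer(den))
  c(num = as.integer(num / g), den = as.integer(den / g))
}
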