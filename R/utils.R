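# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state;
# a NULL seed means "use the current RNG stream".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# round-half-up at `digits`, the convention of the printed report tables
# (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard error of the mean, NA-safe
se <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# draw one Dirichlet vector with parameter alpha
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

as_matrix_checked <- function(x, what = "matrix") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("%s must be numeric", what)
  if (any(!is.finite(x))) stopf("%s contains non-finite values", what)
  x
}
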