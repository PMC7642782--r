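## Small internal helpers.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed, staying below 2^31.
childSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1000003 * k) %% 2147483647
}

## Numeric formatting used by all text writers (round-trip precision).
num6 <- function(x) formatC(x, format = "g", digits = 6)

## Uniform random rotation matrices via unit quaternions.
randomRotations <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

rotationFromRow <- function(row) matrix(as.numeric(unlist(row)), 3, 3, byrow = TRUE)

## Pearson correlation that returns NA instead of erroring on degenerate
## input.
safeCor <- function(x, y, minN = 3L) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < minN) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}
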