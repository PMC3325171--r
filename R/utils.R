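# internal helpers

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Indices of strict local maxima and minima of a vector, robust to plateaus:
# runs of equal values are collapsed and the run-center index reported.
localExtrema <- function(x) {
  r <- rle(x)
  v <- r$values
  n <- length(v)
  if (n < 3L)
    return(list(maxima = integer(0), minima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- as.integer(floor((starts + ends) / 2))
  i <- 2:(n - 1L)
  isMax <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  isMin <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  list(maxima = centers[i][isMax], minima = centers[i][isMin])
}

# trapezoidal quadrature (pracma::trapz) restricted to a logical mask
trapzMasked <- function(x, y, mask) {
  if (sum(mask) < 2L) return(0)
  pracma::trapz(x[mask], y[mask])
}
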