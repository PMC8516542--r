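# Shared fixtures, built in code.

dice <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

diskImage <- function(n = 96, center = c(44.3, 51.1), r = 24,
                      hi = 200, lo = 20) {
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  y <- matrix(0:(n - 1), n, n)
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  list(img = ifelse(d <= r, hi, lo), mask = (d <= r) + 0, r = r,
       center = center)
}

gaussBlobImage <- function(n = 64, center = c(30.0, 34.0), s = 1.5,
                           peak = 200, bg = 10) {
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  y <- matrix(0:(n - 1), n, n)
  bg + peak * exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * s^2))
}

# horizontal bright bar with Gaussian cross-section of std `s`
gaussBarImage <- function(nr = 96, nc = 192, row = 47, s = 3,
                          peak = 120, bg = 30) {
  y <- matrix(0:(nr - 1), nr, nc)
  bg + peak * exp(-(y - row)^2 / (2 * s^2))
}

withinWindowMonotone <- function(total, reinit_every = 50L,
                                 burn_in = 10L, rel_tol = 1e-6) {
  ok <- TRUE
  for (i in seq_along(total)[-1]) {
    if (i <= burn_in) next
    if ((i - 1) %% reinit_every == 0) next  # w was reinitialized
    if ((total[i] - total[i - 1]) / abs(total[i - 1]) > rel_tol) ok <- FALSE
  }
  ok
}
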