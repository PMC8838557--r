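# Zero-phase IIR filtering.
#
# The forward-backward application removes the filter's phase lag so that
# detected activity/temperature transitions are not shifted in time. The
# recursion itself runs in compiled code; edges are handled by odd-reflection
# padding and a steady-state initial condition, so a constant input maps to a
# constant output without start-up transients.

# Steady-state initial conditions for the direct-form-II-transposed filter
# (the state a unit step has converged to), solved from the companion form.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1L]
  a <- a / a[1L]
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), B)
}

# Forward-backward filter with odd-reflection padding of length 3*(order).
filtfilt_zero_phase <- function(b, a, x) {
  n <- max(length(a), length(b))
  a0 <- a[1L]
  b <- c(b, rep(0, n - length(b))) / a0
  a <- c(a, rep(0, n - length(a))) / a0
  nfact <- 3L * (n - 1L)
  nx <- length(x)
  if (nx <= nfact) {
    stop_data(sprintf(
      "signal too short for zero-phase filtering (%d samples, need > %d)",
      nx, nfact
    ))
  }
  zi <- lfilter_zi(b, a)
  ext <- c(
    2 * x[1L] - x[(nfact + 1L):2L],
    x,
    2 * x[nx] - x[(nx - 1L):(nx - nfact)]
  )
  y <- filtfilt_cpp(b, a, ext, zi)
  y[(nfact + 1L):(nfact + nx)]
}
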