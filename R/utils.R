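# Trapezoid weights on a unit-spaced stage axis: integrating a piecewise
# linear curve through values v equals sum(w * v) with these weights.
.trapz_weights <- function(T) {
  if (T < 2L) stop("need at least two stages")
  c(0.5, rep(1, T - 2L), 0.5)
}

# Light smoothing of a stage profile with a [1,2,1]/4 kernel, ends repeated.
.smooth121 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  p <- c(v[1L], v, v[n])
  (p[1:n] + 2 * p[2:(n + 1L)] + p[3:(n + 2L)]) / 4
}

`%||%` <- function(a, b) if (is.null(a)) b else a
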