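# Independent literal transcriptions of the published update rules, kept
# separate from the package implementation so the two routes can disagree.

# One raw chaotic-map step, re-derived branch by branch from the tabulated
# recurrences (parameters passed explicitly).
oracle_chaos_raw <- function(name, x, k, p) {
  switch(name,
    tent = if (x < 0.7) x / 0.7 else (10 / 3) * (1 - x),
    logistic = p$a * x * (1 - x),
    sinusoidal = p$a * x^2 * sin(pi * x),
    singer = p$mu * (7.86 * x - 23.31 * x^2 + 28.75 * x^3 - 13.3 * x^4),
    sine = (p$a / 4) * sin(pi * x),
    chebyshev = cos(k * acos(x)),
    circle = (x + p$b - (p$a / (2 * pi)) * sin(2 * pi * x)) %% 1,
    iterative = sin(p$a * pi / x),
    gauss_mouse = if (x == 0) 0 else 1 / x - floor(1 / x),
    piecewise = {
      P <- p$P
      if (x >= 0 && x < P) {
        x / P
      } else if (x < 0.5) {
        (x - P) / (0.5 - P)
      } else if (x < 1 - P) {
        (1 - P - x) / (0.5 - P)
      } else {
        (1 - x) / P
      }
    }
  )
}

# Full n-step normalized sequence mirroring the declared normalization and
# boundary/fixed-point reseeding rule, evaluated step-by-step.
oracle_chaos_sequence <- function(name, x0, n, p) {
  x <- x0
  k <- 0L
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- oracle_chaos_raw(name, x, k, p)
    v <- switch(name,
      chebyshev = ,
      iterative = (v + 1) / 2,
      sinusoidal = ,
      sine = min(max(v, 0), 1),
      v
    )
    if (v == 0 || v == 1 || v == x) {
      v <- (x + 1e-6) %% 1
      if (v == 0) v <- 1e-6
    }
    x <- v
    k <- k + 1L
    out[i] <- x
  }
  out
}

default_map_params <- function(name) {
  switch(name,
    tent = list(),
    logistic = list(a = 4),
    sinusoidal = list(a = 2.3),
    singer = list(mu = 1.07),
    sine = list(a = 3.99),
    chebyshev = list(),
    circle = list(a = 0.5, b = 0.2),
    iterative = list(a = 0.7),
    gauss_mouse = list(),
    piecewise = list(P = 0.4)
  )
}

# Element-wise re-evaluations of the besiege rules.
oracle_soft_besiege <- function(x, xr, E, J) {
  dx <- xr - x
  dx - E * abs(J * xr - x)
}

oracle_hard_besiege <- function(x, xr, E) {
  xr - E * abs(xr - x)
}

# Independent numeric evaluation of the Levy scale.
oracle_levy_sigma <- function(beta) {
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  (num / den)^(1 / beta)
}

sphere <- function(x) sum(x^2)
rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
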