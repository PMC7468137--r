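#' Chaotic map specification
#'
#' Constructs the specification of one of the ten one-dimensional chaotic maps
#' used to drive population initialization and the escape-energy schedule of
#' the hybrid optimizer. Each map is a deterministic recurrence
#' \eqn{x_{k+1} = f(x_k)} whose iterates, after normalization, lie in
#' \eqn{[0,1]} and serve as a structured substitute for uniform random draws.
#'
#' Map parameters default to the canonical values of the chaotic-optimization
#' literature: logistic `a = 4`, sinusoidal `a = 2.3`, singer `mu = 1.07`,
#' sine `a = 3.99`, iterative `a = 0.7`, circle `a = 0.5, b = 0.2`, tent
#' branch point `0.7`, piecewise `P = 0.4`. The Chebyshev map
#' \eqn{x_{k+1} = \cos(k \cos^{-1} x_k)} uses the step index `k` as its
#' multiplier.
#'
#' @param name One of `"tent"`, `"logistic"`, `"sinusoidal"`, `"singer"`,
#'   `"sine"`, `"chebyshev"`, `"circle"`, `"iterative"`, `"gauss_mouse"`,
#'   `"piecewise"`.
#' @param x0 Initial value in (0, 1). `NULL` (default) draws it uniformly
#'   from the current RNG stream when the map state is first created, so a
#'   seeded run is reproducible.
#' @param ... Named parameter overrides (`a`, `mu`, `b`, `P` as applicable).
#'
#' @return An object of class `chaotic_map`: a list with `name`, `params`
#'   and `x0`.
#' @examples
#' m <- chaotic_map("piecewise", x0 = 0.7)
#' chaos_sequence(m, 5)
#' @export
chaotic_map <- function(name = c(
                          "tent", "logistic", "sinusoidal", "singer", "sine",
                          "chebyshev", "circle", "iterative", "gauss_mouse",
                          "piecewise"
                        ),
                        x0 = NULL, ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    tent        = list(),
    logistic    = list(a = 4),
    sinusoidal  = list(a = 2.3),
    singer      = list(mu = 1.07),
    sine        = list(a = 3.99),
    chebyshev   = list(),
    circle      = list(a = 0.5, b = 0.2),
    iterative   = list(a = 0.7),
    gauss_mouse = list(),
    piecewise   = list(P = 0.4)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) {
      stop("unknown parameter(s) for map '", name, "': ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    defaults[names(over)] <- over
  }
  if (!is.null(x0)) {
    stopifnot(is.numeric(x0), length(x0) == 1L, x0 > 0, x0 < 1)
  }
  structure(list(name = name, params = defaults, x0 = x0),
    class = "chaotic_map"
  )
}

#' @export
print.chaotic_map <- function(x, ...) {
  p <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  } else {
    "none"
  }
  cat("<chaotic_map> ", x$name, "  (", p, ")  x0 = ",
    if (is.null(x$x0)) "seeded random" else format(x$x0), "\n",
    sep = ""
  )
  invisible(x)
}

# Fresh state for a map: x0 from the spec or from the current RNG stream.
chaos_init <- function(map) {
  x0 <- map$x0
  if (is.null(x0)) x0 <- stats::runif(1)
  list(x = x0, k = 0L)
}

# Raw (un-normalized) recurrence, exactly as tabulated.
chaos_recurrence <- function(map, x, k) {
  p <- map$params
  switch(map$name,
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
      if (x < P) {
        x / P
      } else if (x < 0.5) {
        (x - P) / (0.5 - P)
      } else if (x < 1 - P) {
        (1 - P - x) / (0.5 - P)
      } else {
        (1 - x) / P
      }
    },
    stop("unknown chaotic map: ", map$name, call. = FALSE)
  )
}

#' Normalize a raw chaotic iterate into the unit interval
#'
#' Maps with range \eqn{[-1, 1]} (Chebyshev, iterative) are folded affinely
#' via \eqn{(v + 1)/2}; the sinusoidal and sine maps are clamped into
#' \eqn{[0, 1]}; all remaining maps already produce values in the unit
#' interval and pass through unchanged.
#'
#' @param v Raw recurrence output (finite scalar).
#' @param name Map name (see [chaotic_map()]).
#' @return A value in \eqn{[0, 1]}.
#' @export
chaos_normalize <- function(v, name) {
  if (!is.finite(v)) stop("non-finite chaotic iterate", call. = FALSE)
  out <- switch(name,
    chebyshev = ,
    iterative = (v + 1) / 2,
    sinusoidal = ,
    sine = min(max(v, 0), 1),
    v
  )
  if (out < 0 || out > 1) {
    stop("chaotic iterate escaped [0,1] for map '", name, "'", call. = FALSE)
  }
  out
}

#' Advance a chaotic map by one step
#'
#' Applies the map's recurrence to the current value, normalizes the result
#' into \eqn{[0, 1]} (see [chaos_normalize()]) and increments the step index.
#' If the normalized value lands exactly on 0 or 1, or exactly reproduces the
#' previous value (a fixed point — e.g. the logistic map collapses to 0
#' forever from \eqn{x = 0.5}), the state is reseeded to
#' \eqn{(x_k + 10^{-6}) \bmod 1} so the driver keeps producing variation.
#'
#' @param map A [chaotic_map()] specification.
#' @param state A list with elements `x` (current value) and `k` (step index),
#'   as returned by a previous `chaos_step()` call.
#' @return The next state: list with `x` and `k`.
#' @export
chaos_step <- function(map, state) {
  if (!is.finite(state$x)) stop("non-finite chaotic state", call. = FALSE)
  v <- chaos_recurrence(map, state$x, state$k)
  x_new <- chaos_normalize(v, map$name)
  if (x_new == 0 || x_new == 1 || x_new == state$x) {
    x_new <- (state$x + 1e-6) %% 1
    if (x_new == 0) x_new <- 1e-6
  }
  list(x = x_new, k = state$k + 1L)
}

#' Generate a chaotic sequence
#'
#' Iterates a chaotic map `n` times from its initial value, returning the `n`
#' normalized iterates. Deterministic given the map specification and `x0`;
#' when `x0` is `NULL` it is drawn once from the current RNG stream, so the
#' sequence is reproducible under `set.seed()`.
#'
#' @inheritParams chaos_step
#' @param n Number of iterates (>= 1).
#' @return Numeric vector of length `n`, all values in \eqn{[0, 1]}.
#' @examples
#' chaos_sequence(chaotic_map("logistic", x0 = 0.2), 3)
#' @export
chaos_sequence <- function(map, n) {
  stopifnot(n >= 1)
  st <- chaos_init(map)
  out <- numeric(n)
  for (i in seq_len(n)) {
    st <- chaos_step(map, st)
    out[i] <- st$x
  }
  out
}

#' @rdname chaotic_map
#' @format NULL
#' @export
chaotic_map_names <- c(
  "tent", "logistic", "sinusoidal", "singer", "sine",
  "chebyshev", "circle", "iterative", "gauss_mouse", "piecewise"
)
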