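# Deterministic validation systems: the 2D sine-ICMIC modulation map
# (2D-SIMM), a simplified Lorenz flow integrated with fixed-step RK4,
# subsampling, parameter sweeps and structural regime diagnostics.

#' Simulate the 2D-SIMM chaotic map
#'
#' Iterates the two-dimensional sine-ICMIC modulation map
#' \deqn{x_i = a \sin(\omega y_{i-1}) \sin(b / x_{i-1}), \quad
#'       y_i = a \sin(\omega x_i) \sin(b / y_{i-1}),}
#' where the second equation uses the freshly updated `x_i`. The `sin(b/x)`
#' factor is the infinite-collapse (ICMIC) nonlinearity; the map is bounded
#' by `a` in both variables and, at the reference setting `a = 1, b = 3,
#' omega = pi`, hyperchaotic. The map has a singularity at 0: if an iterate
#' reaches exactly zero (possible for parameter values where the orbit
#' collapses toward the origin) the simulation stops with an error naming
#' the step.
#'
#' @param n number of samples to emit (after discarding the transient).
#' @param a,b,omega positive map parameters.
#' @param x0,y0 initial condition (nonzero).
#' @param transient leading iterates to discard (default 1000; use 0 to
#'   start measuring at the given initial condition).
#' @return a 2 x n matrix with rows `x`, `y`.
#' @examples
#' X <- simulate_2dsimm(1000, transient = 0)
#' max(abs(X))  # bounded by a = 1
#' @export
simulate_2dsimm <- function(n, a = 1, b = 3, omega = pi,
                            x0 = 0.45, y0 = 0.95, transient = 1000) {
  stopifnot(n >= 1, transient >= 0, a > 0, b >= 0, omega >= 0,
            is.finite(x0), is.finite(y0), x0 != 0, y0 != 0)
  n <- as.integer(n); transient <- as.integer(transient)
  total <- n + transient
  x <- numeric(total); y <- numeric(total)
  xp <- x0; yp <- y0
  for (i in seq_len(total)) {
    if (abs(xp) < 1e-300)
      stop("2D-SIMM orbit hit the ICMIC singularity at step ", i,
           " (a = ", a, ")", call. = FALSE)
    xi <- a * sin(omega * yp) * sin(b / xp)
    if (abs(yp) < 1e-300)
      stop("2D-SIMM orbit hit the ICMIC singularity at step ", i,
           " (a = ", a, ")", call. = FALSE)
    yi <- a * sin(omega * xi) * sin(b / yp)
    if (!is.finite(xi) || !is.finite(yi))
      stop("2D-SIMM orbit hit the ICMIC singularity at step ", i,
           " (a = ", a, ")", call. = FALSE)
    x[i] <- xi; y[i] <- yi
    xp <- xi; yp <- yi
  }
  keep <- (transient + 1L):total
  rbind(x = x[keep], y = y[keep])
}

#' Simulate the simplified Lorenz flow
#'
#' Integrates
#' \deqn{\dot x = 10(y - x),\quad \dot y = -xz + (24 - 4c)x + cy,\quad
#'       \dot z = xy - 8z/3}
#' with a fixed-step fourth-order Runge-Kutta scheme (step `h`, default
#' 0.01). The single bifurcation parameter `c` leaves the system chaotic
#' over most of `(-1.59, 7.75)`, with periodic windows near the upper end.
#' After discarding `transient` integration steps, every `tau`-th sample is
#' kept until `n` samples have been emitted (so `n * tau` post-transient
#' steps are taken).
#'
#' @param n number of output samples (after transient removal and
#'   subsampling).
#' @param c_par bifurcation parameter c.
#' @param h integration step size.
#' @param transient integration steps discarded before sampling starts
#'   (default 10000 = 100 time units; attractor statistics are insensitive
#'   to the initial state once the transient is removed).
#' @param init initial state `(x, y, z)`. The origin is an equilibrium, so
#'   `c(0, 0, 0)` yields the zero trajectory.
#' @param tau integer sampling period (columns kept every `tau` steps).
#' @return a 3 x n matrix with rows `x`, `y`, `z`.
#' @export
simulate_simplified_lorenz <- function(n, c_par = 2, h = 0.01,
                                       transient = 10000,
                                       init = c(1, 1, 1), tau = 1L) {
  stopifnot(n >= 1, h > 0, transient >= 0, length(init) == 3,
            all(is.finite(init)))
  if (length(tau) != 1L || !is.finite(tau) || tau < 1 || tau != round(tau))
    stop("`tau` must be a positive integer", call. = FALSE)
  n <- as.integer(n); tau <- as.integer(tau); transient <- as.integer(transient)
  raw <- n * tau
  out <- matrix(0, 3L, n, dimnames = list(c("x", "y", "z"), NULL))
  x <- init[1]; y <- init[2]; z <- init[3]
  cc <- 24 - 4 * c_par
  b3 <- 8 / 3
  k <- 0L
  for (i in seq_len(transient + raw)) {
    k1x <- 10 * (y - x); k1y <- -x * z + cc * x + c_par * y; k1z <- x * y - b3 * z
    x2 <- x + 0.5 * h * k1x; y2 <- y + 0.5 * h * k1y; z2 <- z + 0.5 * h * k1z
    k2x <- 10 * (y2 - x2); k2y <- -x2 * z2 + cc * x2 + c_par * y2; k2z <- x2 * y2 - b3 * z2
    x3 <- x + 0.5 * h * k2x; y3 <- y + 0.5 * h * k2y; z3 <- z + 0.5 * h * k2z
    k3x <- 10 * (y3 - x3); k3y <- -x3 * z3 + cc * x3 + c_par * y3; k3z <- x3 * y3 - b3 * z3
    x4 <- x + h * k3x; y4 <- y + h * k3y; z4 <- z + h * k3z
    k4x <- 10 * (y4 - x4); k4y <- -x4 * z4 + cc * x4 + c_par * y4; k4z <- x4 * y4 - b3 * z4
    x <- x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    y <- y + h / 6 * (k1y + 2 * k2y + 2 * k3y + k4y)
    z <- z + h / 6 * (k1z + 2 * k2z + 2 * k3z + k4z)
    if (!is.finite(x) || !is.finite(y) || !is.finite(z) || abs(x) > 1e8)
      stop("trajectory diverged at integration step ", i, call. = FALSE)
    if (i > transient && (i - transient) %% tau == 0L) {
      k <- k + 1L
      out[1L, k] <- x; out[2L, k] <- y; out[3L, k] <- z
    }
  }
  out
}

#' Subsample a multichannel series
#'
#' Keeps columns `1, 1 + tau, 1 + 2*tau, ...`.
#'
#' @param x channels x samples matrix.
#' @param tau positive integer sampling period; `tau = 1` is the identity.
#' @return the subsampled matrix.
#' @export
subsample_series <- function(x, tau) {
  if (length(tau) != 1L || !is.numeric(tau) || !is.finite(tau) ||
      tau < 1 || tau != round(tau))
    stop("`tau` must be a positive integer", call. = FALSE)
  X <- .as_channel_matrix(x)
  X[, seq(1L, ncol(X), by = as.integer(tau)), drop = FALSE]
}

# Structural regime diagnostics, independent of the entropy estimators so
# that chaotic-vs-periodic comparisons are not circular.

# A periodic map orbit settles on finitely many points: count distinct
# values (10 significant digits) in the orbit tail.
.simm2d_regime <- function(X, tail_len = 1000L, max_period = 32L) {
  xt <- X[1L, max(1L, ncol(X) - tail_len + 1L):ncol(X)]
  if (length(unique(signif(xt, 10))) <= max_period) "periodic" else "chaotic"
}

# A periodic flow revisits the same local maxima: count distinct successive
# maxima of z (rounded to 2 decimals, well above RK4 noise).
.lorenz_regime <- function(X, max_distinct = 16L) {
  z <- X[3L, ]
  n <- length(z)
  pk <- which(z[2:(n - 1L)] > z[1:(n - 2L)] & z[2:(n - 1L)] > z[3:n]) + 1L
  if (length(pk) < 4L) return("periodic")
  if (length(unique(round(z[pk], 2))) <= max_distinct) "periodic" else "chaotic"
}

#' Complexity sweep of the 2D-SIMM map
#'
#' For each value of `a`, simulates the map, applies the min-max flip
#' normalization, and computes PE (on the x variable) and MMPE (on both
#' variables) for each requested embedding dimension. Each parameter value
#' is also labelled `chaotic` or `periodic` from the distinct-attractor-
#' point diagnostic; orbits that fall into the ICMIC singularity are
#' labelled `degenerate` with `NA` entropy.
#'
#' @param a_values numeric vector of map parameter values.
#' @param d embedding dimensions to evaluate (vector allowed).
#' @param n samples per parameter value (default 10000).
#' @param ... passed to [simulate_2dsimm()] (`b`, `omega`, `x0`, `y0`,
#'   `transient`).
#' @return a long data.frame with columns `a`, `regime`, `estimator`, `d`,
#'   `value`, `n_patterns`.
#' @export
sweep_simm2d <- function(a_values, d = 4, n = 10000, ...) {
  rows <- lapply(a_values, function(a) {
    X <- tryCatch(simulate_2dsimm(n, a = a, ...), error = function(e) NULL)
    if (is.null(X)) {
      return(data.frame(a = a, regime = "degenerate",
                        estimator = rep(c("PE", "MMPE"), each = length(d)),
                        d = rep(d, 2L), value = NA_real_,
                        n_patterns = NA_integer_))
    }
    # an orbit settled exactly on a fixed point is a constant channel;
    # its complexity is 0, so map it to zeros rather than fail
    Xn <- suppressWarnings(flip_minmax_normalize(X, const_action = "zero"))
    regime <- .simm2d_regime(X)
    do.call(rbind, lapply(d, function(dd) {
      pe <- permutation_entropy(Xn[1L, ], dd)
      mm <- mmpe(Xn, dd)
      data.frame(a = a, regime = regime, estimator = c("PE", "MMPE"), d = dd,
                 value = c(pe$value, mm$value),
                 n_patterns = c(n_observed_patterns(pe$distribution),
                                n_observed_patterns(mm$distribution)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Complexity sweep of the simplified Lorenz flow
#'
#' For each value of the bifurcation parameter, integrates the flow,
#' subsamples at period `tau`, normalizes, and computes PE (x variable),
#' MMPE (all three variables) and MPE (cross-channel, fixed d = 3).
#' Parameter values are labelled by the distinct-z-maxima diagnostic.
#'
#' @param c_values numeric vector of bifurcation parameter values.
#' @param d embedding dimensions for PE / MMPE (vector allowed; MPE ignores
#'   it, its dimension is the channel count).
#' @param n output samples per parameter value (default 20000).
#' @param tau integer sampling period applied inside the simulator.
#' @param ... passed to [simulate_simplified_lorenz()].
#' @return long data.frame with columns `c_par`, `regime`, `estimator`,
#'   `d`, `value`, `n_patterns`.
#' @export
sweep_lorenz <- function(c_values, d = 4, n = 20000, tau = 1L, ...) {
  rows <- lapply(c_values, function(cp) {
    X <- simulate_simplified_lorenz(n, c_par = cp, tau = tau, ...)
    Xn <- suppressWarnings(flip_minmax_normalize(X, const_action = "zero"))
    regime <- .lorenz_regime(X)
    ests <- do.call(rbind, lapply(d, function(dd) {
      pe <- permutation_entropy(Xn[1L, ], dd)
      mm <- mmpe(Xn, dd)
      data.frame(c_par = cp, regime = regime, estimator = c("PE", "MMPE"),
                 d = dd, value = c(pe$value, mm$value),
                 n_patterns = c(n_observed_patterns(pe$distribution),
                                n_observed_patterns(mm$distribution)))
    }))
    mp <- mpe(Xn)
    rbind(ests,
          data.frame(c_par = cp, regime = regime, estimator = "MPE",
                     d = mp$d, value = mp$value,
                     n_patterns = n_observed_patterns(mp$distribution)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
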