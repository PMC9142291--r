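#' Parameter set for the PLSQR smoking model
#'
#' Bundles and validates the six rates that govern the dynamics of the
#' five-compartment giving-up-smoking model.
#'
#' @param a natural death / renewal rate (1/time); must be > 0 for
#'   equilibrium analysis (the permanent-quitter steady state divides by
#'   `a`), >= 0 for pure simulation.
#' @param b contact rate moving potential smokers into the occasional
#'   class (1/time).
#' @param c contact rate moving occasional smokers into the heavy class
#'   (1/time).
#' @param d quitting rate of heavy smokers (1/time).
#' @param e fraction of quitters who quit permanently (dimensionless,
#'   in \[0, 1\]); the remaining fraction `1 - e` quits temporarily.
#' @param f relapse rate of temporary quitters back to heavy smoking
#'   (1/time).
#'
#' @return An object of class `smoking_params`: a named numeric vector
#'   with elements `a`, `b`, `c`, `d`, `e`, `f`.
#' @examples
#' smoking_params(a = 0.04, b = 0.23, c = 0.3, d = 0.2, e = 0.4, f = 0.25)
#' @export
smoking_params <- function(a, b, c, d, e, f) {
  p <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  if (!is.numeric(p) || length(p) != 6L || anyNA(p) || !all(is.finite(p)))
    stop("all six rates must be finite numbers", call. = FALSE)
  if (any(p < 0)) {
    bad <- names(p)[p < 0][1L]
    stop(sprintf("rate '%s' must be nonnegative (got %g)", bad, p[[bad]]),
         call. = FALSE)
  }
  if (p[["e"]] > 1)
    stop(sprintf("'e' is a fraction and must lie in [0, 1] (got %g)",
                 p[["e"]]), call. = FALSE)
  structure(p, class = "smoking_params")
}

#' @export
print.smoking_params <- function(x, ...) {
  cat("PLSQR smoking model parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' A single PLSQR population state
#'
#' The population is split into potential smokers `P`, occasional
#' (light) smokers `L`, heavy smokers `S`, temporary quitters `Q` and
#' permanent quitters `R`, each a fraction of a unit total.
#'
#' @param P,L,S,Q,R compartment fractions; must be finite, and
#'   nonnegative unless `check_nonneg = FALSE`.
#' @param check_nonneg validate nonnegativity (default `TRUE`).
#'   Transient solver iterates may legitimately dip below zero and are
#'   reported, not clamped, so internal callers disable the check.
#'
#' @return A named numeric vector of class `compartment_state`.
#' @examples
#' compartment_state(0.60301, 0.24, 0.10628, 0.0326, 0.01811)
#' @export
compartment_state <- function(P, L, S, Q, R, check_nonneg = TRUE) {
  x <- c(P = P, L = L, S = S, Q = Q, R = R)
  if (!is.numeric(x) || length(x) != 5L)
    stop("state must have five numeric components", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- names(x)[!is.finite(x)][1L]
    stop(sprintf("state component '%s' is not finite", bad), call. = FALSE)
  }
  if (check_nonneg && any(x < 0)) {
    bad <- names(x)[x < 0][1L]
    stop(sprintf("state component '%s' is negative (%g)", bad, x[[bad]]),
         call. = FALSE)
  }
  structure(x, class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat("PLSQR state (fractions, total =",
      format(sum(x), digits = 10), "):\n")
  print(unclass(x), ...)
  invisible(x)
}

.as_state_vec <- function(state) {
  x <- as.numeric(state)
  if (length(x) != 5L)
    stop("state must have five components (P, L, S, Q, R)", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) {
    nm <- c("P", "L", "S", "Q", "R")[!is.finite(x)][1L]
    stop(sprintf("state component '%s' is not finite", nm), call. = FALSE)
  }
  names(x) <- c("P", "L", "S", "Q", "R")
  x
}

.check_variant <- function(variant) {
  match.arg(variant, c("PS", "PL"))
}

#' Right-hand side of the PLSQR system
#'
#' Time derivative of the five compartments. The inflow into the
#' occasional-smoker class is the mass-action term `b*P*S` under the
#' default `"PS"` incidence; the `"PL"` variant uses `b*P*L` instead.
#' Only the `"PS"` form conserves the total population (the component
#' sum of the derivative is `a*(1 - T)`, so `T = 1` is invariant), which
#' is why it is the default; `"PL"` is retained as an explicit variant.
#'
#' @param state five-component state (a [compartment_state] or plain
#'   numeric vector ordered P, L, S, Q, R).
#' @param params a [smoking_params] object.
#' @param variant incidence variant, `"PS"` (default) or `"PL"`.
#'
#' @return Named numeric vector of the five time derivatives (1/time).
#' @examples
#' p <- baseline_params()
#' smoking_rhs(c(1, 0, 0, 0, 0), p)   # zero at the smoking-free state
#' @export
smoking_rhs <- function(state, params, variant = c("PS", "PL")) {
  variant <- .check_variant(variant)
  x <- .as_state_vec(state)
  p <- unclass(params)
  P <- x[["P"]]; L <- x[["L"]]; S <- x[["S"]]; Q <- x[["Q"]]; R <- x[["R"]]
  incidence <- if (variant == "PS") p[["b"]] * P * S else p[["b"]] * P * L
  c(P = p[["a"]] * (1 - P) - p[["b"]] * P * S,
    L = -p[["a"]] * L + incidence - p[["c"]] * L * S,
    S = -(p[["a"]] + p[["d"]]) * S + p[["c"]] * L * S + p[["f"]] * Q,
    Q = -(p[["a"]] + p[["f"]]) * Q + p[["d"]] * (1 - p[["e"]]) * S,
    R = -p[["a"]] * R + p[["e"]] * p[["d"]] * S)
}

#' Jacobian of the PLSQR system (PS incidence)
#'
#' Analytic 5x5 Jacobian of [smoking_rhs] with the `"PS"` incidence
#' (the only variant whose linearisation enters the stability analysis).
#'
#' @inheritParams smoking_rhs
#' @return 5x5 numeric matrix with rows/columns named P, L, S, Q, R.
#' @examples
#' smoking_jacobian(c(1, 0, 0, 0, 0), baseline_params())
#' @export
smoking_jacobian <- function(state, params) {
  x <- .as_state_vec(state)
  p <- unclass(params)
  P <- x[["P"]]; L <- x[["L"]]; S <- x[["S"]]
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  d <- p[["d"]]; e <- p[["e"]]; f <- p[["f"]]
  J <- rbind(
    c(-a - b * S, 0,          -b * P,             0,        0),
    c(b * S,      -a - cc * S, b * P - cc * L,    0,        0),
    c(0,          cc * S,     -(a + d) + cc * L,  f,        0),
    c(0,          0,           d * (1 - e),      -(a + f),  0),
    c(0,          0,           e * d,             0,       -a))
  dimnames(J) <- list(c("P", "L", "S", "Q", "R"),
                      c("P", "L", "S", "Q", "R"))
  J
}
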