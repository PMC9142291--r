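#' Disease-free (smoking-free) equilibrium
#'
#' The steady state with every smoking-related compartment empty. For
#' this model it is the parameter-free point (1, 0, 0, 0, 0): the whole
#' population sits in the potential-smoker class.
#'
#' @param params a [smoking_params] object (validated, otherwise unused:
#'   the closed form does not depend on the rates).
#' @return A [compartment_state] at which [smoking_rhs] vanishes exactly.
#' @export
disease_free_equilibrium <- function(params) {
  if (!inherits(params, "smoking_params"))
    params <- do.call(smoking_params, as.list(params))
  compartment_state(1, 0, 0, 0, 0)
}

#' Basic reproduction number
#'
#' Threshold quantity of the smoking-free state,
#' \deqn{R_0 = \frac{d\,f\,(1-e)}{(a+d)(a+f)},}
#' computed from the quitting rate `d`, the relapse rate `f`, the
#' permanent-quitting fraction `e` and the death rate `a`. `R_0 < 1`
#' indicates the smoking-free equilibrium is stable. Note the formula
#' contains neither contact rate (`b`, `c`) and is strictly below 1 for
#' every positive parameter set, since `d f (1-e) < (a+d)(a+f)`
#' termwise; the numeric endemic-root scan of [endemic_equilibrium] is
#' therefore the operational existence check for an endemic state.
#'
#' @param params a [smoking_params] object with `a + d > 0` and
#'   `a + f > 0`.
#' @return Dimensionless scalar `>= 0`.
#' @examples
#' reproductive_number(baseline_params())  # 0.431034...
#' @export
reproductive_number <- function(params) {
  p <- unclass(params)
  if (p[["a"]] + p[["d"]] <= 0)
    stop("denominator factor a + d vanishes", call. = FALSE)
  if (p[["a"]] + p[["f"]] <= 0)
    stop("denominator factor a + f vanishes", call. = FALSE)
  p[["d"]] * p[["f"]] * (1 - p[["e"]]) /
    ((p[["a"]] + p[["d"]]) * (p[["a"]] + p[["f"]]))
}

# Scalar residual whose roots are endemic heavy-smoker levels S*.
# Derived from the steady-state equations: P* = a/(a+bS*),
# L* = a b S*/((a+bS*)(a+cS*)), Q* = d(1-e)S*/(a+f), R* = e d S*/a,
# leaving one scalar equation in S*.
.endemic_residual <- function(S, p) {
  Lstar <- p[["a"]] * p[["b"]] * S /
    ((p[["a"]] + p[["b"]] * S) * (p[["a"]] + p[["c"]] * S))
  -(p[["a"]] + p[["d"]]) + p[["c"]] * Lstar +
    p[["f"]] * p[["d"]] * (1 - p[["e"]]) / (p[["a"]] + p[["f"]])
}

.endemic_state <- function(S, p) {
  Pstar <- p[["a"]] / (p[["a"]] + p[["b"]] * S)
  Lstar <- p[["a"]] * p[["b"]] * S /
    ((p[["a"]] + p[["b"]] * S) * (p[["a"]] + p[["c"]] * S))
  Qstar <- p[["d"]] * (1 - p[["e"]]) * S / (p[["a"]] + p[["f"]])
  Rstar <- p[["e"]] * p[["d"]] * S / p[["a"]]
  compartment_state(Pstar, Lstar, S, Qstar, Rstar)
}

#' Endemic equilibria by scalar root scan
#'
#' Searches (0, `s_max`] for heavy-smoker levels `S*` at which the full
#' five-dimensional system is stationary. The other four compartments
#' are expressed in closed form in terms of `S*`, reducing the search to
#' a scalar residual; sign changes on a uniform grid are bracketed and
#' refined by bisection. All roots found are returned, none privileged.
#'
#' @param params a [smoking_params] with `a > 0` (the permanent-quitter
#'   steady state divides by `a`).
#' @param s_max upper end of the scanned `S*` range (default 1, the
#'   population scale).
#' @param n_grid number of scan intervals (default 1e4).
#' @return List of [compartment_state] roots, each with maximum-absolute
#'   [smoking_rhs] residual below 1e-10 (PS incidence); empty list when
#'   the residual never changes sign.
#' @export
endemic_equilibrium <- function(params, s_max = 1, n_grid = 1e4) {
  p <- unclass(params)
  if (p[["a"]] <= 0)
    stop("endemic analysis requires a > 0 (R* divides by a)", call. = FALSE)
  if (s_max <= 0) stop("s_max must be positive", call. = FALSE)
  grid <- seq(0, s_max, length.out = n_grid + 1L)[-1L]
  g <- vapply(grid, .endemic_residual, numeric(1), p = p)
  roots <- list()
  # exact zeros on the grid
  hit <- which(g == 0)
  for (i in hit) roots[[length(roots) + 1L]] <- grid[i]
  sgn <- sign(g)
  flip <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  for (i in flip) {
    r <- stats::uniroot(.endemic_residual, c(grid[i], grid[i + 1L]), p = p,
                        tol = .Machine$double.eps)
    roots[[length(roots) + 1L]] <- r$root
  }
  out <- lapply(roots, .endemic_state, p = p)
  keep <- vapply(out, function(st)
    max(abs(smoking_rhs(st, params, "PS"))) < 1e-10, logical(1))
  out[keep]
}

#' Eigenvalues and local stability at the smoking-free equilibrium
#'
#' Evaluates both the closed-form eigenvalues of the linearisation at
#' the smoking-free state,
#' \deqn{\lambda_1 = -a,\quad
#'   \lambda_{2,3} = \tfrac12\bigl(-2a-d-f \mp
#'   \sqrt{d^2 + 2df - 4def + f^2}\bigr),}
#' and the full numeric spectrum of the 5x5 Jacobian there (which adds
#' `-a` twice). The verdict is `"locally_stable"` iff every numeric
#' eigenvalue has negative real part. A negative discriminant yields a
#' complex conjugate pair, returned as complex numbers, not an error.
#'
#' @param params a [smoking_params] object.
#' @return List with `closed_form` (3 values, complex if needed),
#'   `numeric` (5 eigenvalues of the Jacobian at the smoking-free
#'   state), and `verdict` (`"locally_stable"` or `"not_stable"`).
#' @examples
#' dfe_eigenvalues(baseline_params())
#' @export
dfe_eigenvalues <- function(params) {
  p <- unclass(params)
  a <- p[["a"]]; d <- p[["d"]]; e <- p[["e"]]; f <- p[["f"]]
  disc <- d^2 + 2 * d * f - 4 * d * e * f + f^2
  rt <- if (disc >= 0) sqrt(disc) else sqrt(as.complex(disc))
  lam <- c(-a,
           0.5 * (-2 * a - d - f - rt),
           0.5 * (-2 * a - d - f + rt))
  if (all(Im(lam) == 0)) lam <- Re(lam)
  J0 <- smoking_jacobian(disease_free_equilibrium(params), params)
  spec <- eigen(J0, only.values = TRUE)$values
  verdict <- if (all(Re(spec) < 0)) "locally_stable" else "not_stable"
  list(closed_form = lam, numeric = spec, verdict = verdict)
}

#' Volterra-type Lyapunov function
#'
#' \eqn{M = \sum_x (x - x^* - x^* \log(x/x^*))} over the five
#' compartments: nonnegative, and zero exactly at the reference
#' equilibrium.
#'
#' @param state,eq componentwise strictly positive five-component
#'   states (current state and reference equilibrium).
#' @return Scalar `>= 0`.
#' @export
lyapunov_value <- function(state, eq) {
  x <- .as_state_vec(state); xs <- .as_state_vec(eq)
  if (any(x <= 0) || any(xs <= 0))
    stop("Lyapunov function requires strictly positive components",
         call. = FALSE)
  sum(x - xs - xs * log(x / xs))
}

#' Time derivative of the Lyapunov function along the flow
#'
#' Chain rule applied to [lyapunov_value]:
#' \eqn{\dot M = \sum_x \frac{x - x^*}{x}\,\dot x} with \eqn{\dot x}
#' from [smoking_rhs] (PS incidence). A negative value at states near an
#' equilibrium is numerical evidence of its stability.
#'
#' @inheritParams lyapunov_value
#' @param params a [smoking_params] object.
#' @return Scalar (1/time).
#' @export
lyapunov_derivative <- function(state, eq, params) {
  x <- .as_state_vec(state); xs <- .as_state_vec(eq)
  if (any(x <= 0) || any(xs <= 0))
    stop("Lyapunov derivative requires strictly positive components",
         call. = FALSE)
  sum((x - xs) / x * smoking_rhs(x, params, "PS"))
}

#' Full stability report for one parameter set
#'
#' Bundles the smoking-free equilibrium, endemic roots from the numeric
#' scan, the reproduction number, both eigenvalue sets and the stability
#' verdict.
#'
#' @param params a [smoking_params] object.
#' @param s_max scan range for endemic roots (see
#'   [endemic_equilibrium]).
#' @return Object of class `stability_report`: a list with elements
#'   `dfe`, `endemic`, `R0`, `eigenvalues_closed_form`,
#'   `eigenvalues_numeric`, `verdict`.
#' @examples
#' stability_report(baseline_params())
#' @export
stability_report <- function(params, s_max = 1) {
  eig <- dfe_eigenvalues(params)
  structure(list(
    dfe = disease_free_equilibrium(params),
    endemic = endemic_equilibrium(params, s_max = s_max),
    R0 = reproductive_number(params),
    eigenvalues_closed_form = eig$closed_form,
    eigenvalues_numeric = eig$numeric,
    verdict = eig$verdict
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("PLSQR stability report\n")
  cat("  smoking-free equilibrium:",
      paste(format(unclass(x$dfe)), collapse = " "), "\n")
  cat("  R0:", format(x$R0, digits = 7), "\n")
  cat("  closed-form eigenvalues:",
      paste(format(x$eigenvalues_closed_form, digits = 7), collapse = " "),
      "\n")
  cat("  numeric spectrum:",
      paste(format(x$eigenvalues_numeric, digits = 7), collapse = " "), "\n")
  cat("  endemic roots found:", length(x$endemic), "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Serialize a stability report to flat JSON
#'
#' @param report a [stability_report] object.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  eig_num <- report$eigenvalues_numeric
  doc <- list(
    dfe = as.numeric(report$dfe),
    endemic = lapply(report$endemic, as.numeric),
    R0 = report$R0,
    eigenvalues_closed_form = Re(report$eigenvalues_closed_form),
    eigenvalues_numeric = Re(eig_num),
    verdict = report$verdict
  )
  if (is.complex(report$eigenvalues_closed_form))
    doc$eigenvalues_closed_form_imag <- Im(report$eigenvalues_closed_form)
  if (is.complex(eig_num)) doc$eigenvalues_numeric_imag <- Im(eig_num)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
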