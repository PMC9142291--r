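#' Built-in baseline parameter set
#'
#' The six rates of the baseline smoking scenario: a = 0.04, b = 0.23,
#' c = 0.3, d = 0.2, e = 0.4, f = 0.25.
#'
#' @return A [smoking_params] object.
#' @export
baseline_params <- function() {
  smoking_params(a = 0.04, b = 0.23, c = 0.3, d = 0.2, e = 0.4, f = 0.25)
}

#' Built-in baseline initial conditions
#'
#' P(0) = 0.60301, L(0) = 0.24000, S(0) = 0.10628, Q(0) = 0.03260,
#' R(0) = 0.01811; the five fractions sum to exactly 1.
#'
#' @return A [compartment_state] object.
#' @export
baseline_initial <- function() {
  compartment_state(0.60301, 0.24000, 0.10628, 0.03260, 0.01811)
}

.default_orders <- c(1.0, 0.95, 0.90, 0.85, 0.80)

#' Built-in baseline scenario
#'
#' Bundles [baseline_params], [baseline_initial], default solver settings
#' (sigma = 1, h = 0.01, t_end = 30, PS incidence) and the default order
#' sweep {1.0, 0.95, 0.90, 0.85, 0.80}.
#'
#' @return Object of class `fracsmoke_scenario`.
#' @export
baseline_scenario <- function() {
  structure(list(
    params = baseline_params(),
    initial = baseline_initial(),
    solver = solver_config(sigma = 1, h = 0.01, t_end = 30, variant = "PS"),
    orders = .default_orders,
    label = "baseline"
  ), class = "fracsmoke_scenario")
}

#' @export
print.fracsmoke_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$label))
  cat("  rates:", paste(sprintf("%s=%g", names(x$params),
                                unclass(x$params)), collapse = " "), "\n")
  cat("  initial:", paste(sprintf("%s=%g", names(x$initial),
                                  unclass(x$initial)), collapse = " "), "\n")
  cat(sprintf("  solver: sigma=%g h=%g t_end=%g variant=%s\n",
              x$solver$sigma, x$solver$h, x$solver$t_end,
              x$solver$variant))
  cat("  sweep orders:", paste(x$orders, collapse = ", "), "\n")
  invisible(x)
}

.scenario_keys <- c("a", "b", "c", "d", "e", "f",
                    "P0", "L0", "S0", "Q0", "R0",
                    "sigma", "h", "t_end", "variant", "orders")

#' Load a scenario by name or from a key-value file
#'
#' Accepts the built-in name `"paper"` or the path of a flat key = value
#' text file with any subset of the keys `a b c d e f P0 L0 S0 Q0 R0
#' sigma h t_end variant orders` (`orders` is comma-separated; `#`
#' starts a comment). Keys absent from the file fall back to the
#' baseline scenario value and each fallback is logged as a message.
#' Unknown keys, non-numeric values and invariant violations are
#' rejected with single-line diagnostics naming the offender.
#'
#' @param path_or_name `"paper"` or a readable file path.
#' @param quiet suppress fallback logging (default `FALSE`).
#' @return Object of class `fracsmoke_scenario`.
#' @export
load_scenario <- function(path_or_name = "paper", quiet = FALSE) {
  if (identical(path_or_name, "paper")) return(baseline_scenario())
  if (!file.exists(path_or_name))
    stop(sprintf("scenario '%s' is neither the built-in name 'paper' nor a readable file",
                 path_or_name), call. = FALSE)
  lines <- readLines(path_or_name, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed line in scenario file: '%s'", ln),
           call. = FALSE)
    key <- trimws(parts[1L]); val <- trimws(parts[2L])
    if (!key %in% .scenario_keys)
      stop(sprintf("unknown scenario key '%s'", key), call. = FALSE)
    kv[[key]] <- val
  }
  base <- baseline_scenario()
  num <- function(key, fallback) {
    if (is.null(kv[[key]])) {
      if (!quiet)
        message(sprintf("scenario key '%s' missing; using baseline %g",
                        key, fallback))
      return(fallback)
    }
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v))
      stop(sprintf("scenario key '%s' is not numeric: '%s'", key,
                   kv[[key]]), call. = FALSE)
    v
  }
  p0 <- unclass(base$params)
  params <- smoking_params(a = num("a", p0[["a"]]), b = num("b", p0[["b"]]),
                           c = num("c", p0[["c"]]), d = num("d", p0[["d"]]),
                           e = num("e", p0[["e"]]), f = num("f", p0[["f"]]))
  s0 <- unclass(base$initial)
  initial <- compartment_state(num("P0", s0[["P"]]), num("L0", s0[["L"]]),
                               num("S0", s0[["S"]]), num("Q0", s0[["Q"]]),
                               num("R0", s0[["R"]]))
  variant <- if (is.null(kv[["variant"]])) {
    if (!quiet) message("scenario key 'variant' missing; using baseline PS")
    base$solver$variant
  } else .check_variant(kv[["variant"]])
  solver <- solver_config(sigma = num("sigma", base$solver$sigma),
                          h = num("h", base$solver$h),
                          t_end = num("t_end", base$solver$t_end),
                          variant = variant)
  orders <- if (is.null(kv[["orders"]])) {
    if (!quiet) message("scenario key 'orders' missing; using baseline sweep")
    base$orders
  } else {
    o <- suppressWarnings(as.numeric(strsplit(kv[["orders"]], ",")[[1L]]))
    if (anyNA(o)) stop("scenario key 'orders' contains a non-numeric entry",
                       call. = FALSE)
    if (any(o <= 0 | o > 1))
      stop("every sweep order must lie in (0, 1]", call. = FALSE)
    o
  }
  structure(list(params = params, initial = initial, solver = solver,
                 orders = orders,
                 label = basename(path_or_name)),
            class = "fracsmoke_scenario")
}

#' Stability analysis of a scenario
#'
#' Computes the full [stability_report] for the scenario's parameter
#' set; optionally serializes it to JSON.
#'
#' @param scenario a `fracsmoke_scenario` (default the built-in
#'   baseline).
#' @param json_path optional path for the flat JSON report.
#' @return The [stability_report], invisibly when written to file.
#' @examples
#' run_analysis()
#' @export
run_analysis <- function(scenario = baseline_scenario(), json_path = NULL) {
  rep <- stability_report(scenario$params)
  if (!is.null(json_path)) {
    report_to_json(rep, json_path)
    return(invisible(rep))
  }
  rep
}

#' Fractional-order sweep of a scenario
#'
#' Integrates the scenario once per fractional order in
#' `scenario$orders` with the Atangana-Toufik scheme, writes one CSV
#' trajectory per order plus a JSON manifest recording sigma, h, t_end,
#' file name and the final-time value of each compartment. Partial
#' outputs are removed if any order fails. The run is fully
#' deterministic: repeated invocation reproduces byte-identical files.
#'
#' @param scenario a `fracsmoke_scenario`.
#' @param out_dir output directory (created if needed).
#' @param plot also render a base-graphics panel of the five
#'   compartments across orders to `sweep.pdf` (default `FALSE`).
#' @return Invisibly, a list with `manifest` (data frame) and
#'   `trajectories` (list keyed by order label).
#' @export
run_sweep <- function(scenario = baseline_scenario(), out_dir = ".",
                      plot = FALSE) {
  if (length(scenario$orders) == 0L)
    stop("scenario has no sweep orders", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  trajs <- list()
  rows <- list()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    for (sg in scenario$orders) {
      cfg <- solver_config(sigma = sg, h = scenario$solver$h,
                           t_end = scenario$solver$t_end,
                           variant = scenario$solver$variant)
      tr <- atm_solve(y0 = scenario$initial, params = scenario$params,
                      config = cfg)
      fname <- sprintf("trajectory_sigma_%s.csv", format(sg))
      fpath <- file.path(out_dir, fname)
      write_trajectory_csv(tr, fpath)
      written <- c(written, fpath)
      last <- tr[nrow(tr), ]
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sg, h = cfg$h, t_end = cfg$t_end, file = fname,
        P = last$P, L = last$L, S = last$S, Q = last$Q, R = last$R)
      trajs[[format(sg)]] <- tr
    }
  }, error = on_fail)
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.json")
  writeLines(.manifest_json(manifest), mpath)
  if (plot) {
    grDevices::pdf(file.path(out_dir, "sweep.pdf"), width = 7, height = 9)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2, 1))
    for (comp in c("P", "L", "S", "Q", "R")) {
      rng <- range(vapply(trajs, function(tr) range(tr[[comp]]),
                          numeric(2)))
      graphics::plot(NULL, xlim = c(0, scenario$solver$t_end), ylim = rng,
                     xlab = "t", ylab = comp,
                     main = sprintf("%s(t) across orders", comp))
      for (i in seq_along(trajs))
        graphics::lines(trajs[[i]]$t, trajs[[i]][[comp]], col = i)
      graphics::legend("topright", legend = names(trajs),
                       col = seq_along(trajs), lty = 1, cex = 0.7)
    }
  }
  message(sprintf(
    "sweep '%s': orders {%s}, h=%g, t_end=%g -> %d CSV files + manifest in %s",
    scenario$label, paste(scenario$orders, collapse = ", "),
    scenario$solver$h, scenario$solver$t_end, length(written), out_dir))
  invisible(list(manifest = manifest, trajectories = trajs))
}

# manifest serializer: numbers are printed with %.17g so the JSON
# round-trips the doubles bit-exactly, matching the CSV writer
.manifest_json <- function(df) {
  row_json <- vapply(seq_len(nrow(df)), function(i) {
    fields <- vapply(names(df), function(nm) {
      v <- df[[nm]][i]
      val <- if (is.character(v)) sprintf("\"%s\"", v) else
        sprintf("%.17g", v)
      sprintf("\"%s\":%s", nm, val)
    }, character(1))
    paste0("{", paste(fields, collapse = ","), "}")
  }, character(1))
  paste0("[", paste(row_json, collapse = ","), "]")
}

#' Reproducible random scenario for property tests
#'
#' Draws the six rates log-uniformly in \[1e-3, 1\] (with `e` uniform in
#' \[0, 1\]) and a strictly positive initial state rescaled so its
#' components sum to exactly 1. The same seed always reproduces the
#' same scenario; the global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @return Object of class `fracsmoke_scenario`.
#' @export
random_fixture <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  lu <- function(n) 10^stats::runif(n, -3, 0)
  r <- lu(5)
  params <- smoking_params(a = r[1], b = r[2], c = r[3], d = r[4],
                           e = stats::runif(1), f = r[5])
  x <- stats::runif(5, 0.05, 1)
  x <- x / sum(x)
  initial <- compartment_state(x[1], x[2], x[3], x[4], x[5])
  structure(list(params = params, initial = initial,
                 solver = solver_config(sigma = 1, h = 0.01, t_end = 30,
                                        variant = "PS"),
                 orders = .default_orders,
                 label = sprintf("random-%d", seed)),
            class = "fracsmoke_scenario")
}
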