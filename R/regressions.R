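# Response-surface regressions: the four published fits of plexus-mean
# concentration against plexus size, plexus depth, blood velocity and pore
# density, plus least-squares refitting of the same functional forms to
# simulator sweeps.

#' Published response-surface equations
#'
#' The four reference fits of `C_plex` (mean plexus concentration, in the
#' source's internal units) against a single predictor, as published:
#' quadratic in plexus size `p_size` (m), quadratic in plexus depth `h_plex`
#' (m), exponential decay in blood velocity `v_b` (m/s), and linear in pore
#' density `p_d` (fraction). Quadratics are `a x^2 + b x + c`, the
#' exponential is `a exp(b x)`, the linear form is `a x + b`. Predictor
#' units are inferred: metres for the lengths and m/s for velocity place the
#' quadratic vertices at the reported standard plexus size (~50 um) and
#' depth (~450 um).
#'
#' @return Data frame with columns `name`, `form`, `a`, `b`, `c`,
#'   `r_squared`, `variable`, `unit`.
#' @export
printed_regressions <- function() {
  data.frame(
    name = c("size", "depth", "velocity", "density"),
    form = c("quadratic", "quadratic", "exponential", "linear"),
    a = c(2e7, -199723, 0.008, 0.0056),
    b = c(-1990.4, 182.39, -2038, 0.002),
    c = c(0.0454, -0.0387, NA, NA),
    r_squared = c(0.94, 0.95, 0.97, NA),
    variable = c("p_size", "h_plex", "v_b", "p_d"),
    unit = c("m", "m", "m/s", "fraction")
  )
}

new_regression_fit <- function(form, coefficients, r_squared,
                               variable = NA_character_) {
  ncoef <- c(quadratic = 3L, exponential = 2L, linear = 2L)[[form]]
  stopifnot(length(coefficients) == ncoef)
  names(coefficients) <- letters[seq_len(ncoef)]
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1 + 1e-12)
  structure(list(form = form, coefficients = coefficients,
                 r_squared = r_squared, variable = variable),
            class = "regression_fit")
}

#' A published equation as a `regression_fit`
#'
#' @param name One of `"size"`, `"depth"`, `"velocity"`, `"density"`.
#' @return A `regression_fit` object.
#' @export
printed_fit <- function(name = c("size", "depth", "velocity", "density")) {
  name <- match.arg(name)
  tab <- printed_regressions()
  row <- tab[tab$name == name, ]
  co <- switch(row$form, quadratic = c(row$a, row$b, row$c),
               exponential = c(row$a, row$b), linear = c(row$a, row$b))
  new_regression_fit(row$form, co, row$r_squared, row$variable)
}

#' Evaluate a regression fit
#'
#' @param fit A `regression_fit`.
#' @param x Predictor values (SI units of the fit's variable).
#' @return Predicted `C_plex` values.
#' @export
eval_fit <- function(fit, x) {
  stopifnot(inherits(fit, "regression_fit"))
  co <- fit$coefficients
  switch(fit$form,
    quadratic = co[["a"]] * x^2 + co[["b"]] * x + co[["c"]],
    exponential = co[["a"]] * exp(co[["b"]] * x),
    linear = co[["a"]] * x + co[["b"]]
  )
}

#' Evaluate a published equation
#'
#' Exact arithmetic evaluation of one of the published response surfaces at
#' SI predictor values (e.g. `eval_printed("velocity", 0)` returns the
#' zero-velocity limit 0.008 of the exponential fit).
#'
#' @param name One of `"size"`, `"depth"`, `"velocity"`, `"density"`.
#' @param x Predictor values (m, m, m/s or fraction respectively).
#' @return Predicted `C_plex` values.
#' @export
eval_printed <- function(name, x) {
  eval_fit(printed_fit(name), x)
}

#' Extremum of a quadratic fit
#'
#' Vertex `x* = -b / (2a)`, classified as a minimum (`a > 0`) or maximum
#' (`a < 0`).
#'
#' @param fit A `regression_fit` with `form == "quadratic"`.
#' @return List with `x_star`, `value` and `kind` (`"minimum"` or
#'   `"maximum"`).
#' @export
quadratic_extremum <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$form != "quadratic") {
    stop("quadratic_extremum: fit form is '", fit$form,
         "', not 'quadratic'", call. = FALSE)
  }
  a <- fit$coefficients[["a"]]; b <- fit$coefficients[["b"]]
  if (a == 0) {
    stop("quadratic_extremum: degenerate quadratic (a = 0)", call. = FALSE)
  }
  x_star <- -b / (2 * a)
  list(x_star = x_star, value = eval_fit(fit, x_star),
       kind = if (a > 0) "minimum" else "maximum")
}

#' Fit a response surface to sweep data
#'
#' Least squares in the published functional forms: quadratic and linear via
#' `lm`, exponential via nonlinear least squares initialised from the
#' log-linear fit. `R^2 = 1 - SS_res / SS_tot`; for constant responses
#' `R^2 = 0` by convention and the constant fit is returned.
#'
#' @param xs Predictor values.
#' @param ys Observed responses.
#' @param form `"quadratic"`, `"exponential"` or `"linear"`.
#' @param variable Optional predictor name stored on the fit.
#' @return A `regression_fit`.
#' @export
fit_surface <- function(xs, ys, form = c("quadratic", "exponential",
                                         "linear"),
                        variable = NA_character_) {
  form <- match.arg(form)
  stopifnot(length(xs) == length(ys), all(is.finite(xs)), all(is.finite(ys)))
  ncoef <- c(quadratic = 3L, exponential = 2L, linear = 2L)[[form]]
  if (length(unique(xs)) < ncoef) {
    stop("fit_surface: need at least ", ncoef, " distinct predictor values ",
         "for a ", form, " fit", call. = FALSE)
  }
  ss_tot <- sum((ys - mean(ys))^2)
  if (ss_tot == 0) {
    co <- switch(form, quadratic = c(0, 0, ys[1]),
                 exponential = c(ys[1], 0), linear = c(0, ys[1]))
    return(new_regression_fit(form, co, 0, variable))
  }
  if (form == "quadratic") {
    m <- stats::lm(ys ~ xs + I(xs^2))
    co <- c(stats::coef(m)[["I(xs^2)"]], stats::coef(m)[["xs"]],
            stats::coef(m)[["(Intercept)"]])
    pred <- stats::fitted(m)
  } else if (form == "linear") {
    m <- stats::lm(ys ~ xs)
    co <- c(stats::coef(m)[["xs"]], stats::coef(m)[["(Intercept)"]])
    pred <- stats::fitted(m)
  } else {
    if (any(ys <= 0)) {
      stop("fit_surface: exponential form needs positive responses",
           call. = FALSE)
    }
    lin <- stats::lm(log(ys) ~ xs)
    start <- list(a = exp(stats::coef(lin)[["(Intercept)"]]),
                  b = stats::coef(lin)[["xs"]])
    m <- tryCatch(
      stats::nls(ys ~ a * exp(b * xs), start = start,
                 control = stats::nls.control(maxiter = 500,
                                              minFactor = 1e-12)),
      error = function(e) NULL)
    if (is.null(m)) {
      co <- c(start$a, start$b)
      pred <- co[1] * exp(co[2] * xs)
    } else {
      co <- c(stats::coef(m)[["a"]], stats::coef(m)[["b"]])
      pred <- stats::fitted(m)
    }
  }
  r2 <- max(0, min(1, 1 - sum((ys - pred)^2) / ss_tot))
  new_regression_fit(form, unname(co), r2, variable)
}

#' @export
print.regression_fit <- function(x, ...) {
  co <- paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
              collapse = ", ")
  cat(sprintf("<regression_fit> %s in %s: %s (R^2 = %s)\n", x$form,
              x$variable, co,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f",
                                                        x$r_squared)))
  invisible(x)
}
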