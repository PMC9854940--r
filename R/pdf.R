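#' Probability density function specifications for uncertainty sources
#'
#' In metrological uncertainty evaluation each input quantity is assigned a
#' probability density function (PDF) characterising its random behaviour.
#' Three families cover the sources considered here:
#'
#' * `pdf_normal(mu, sigma)` — Gaussian, for quantities characterised by a
#'   mean and standard deviation (electrode voltages, baseline, noise);
#' * `pdf_rectangular(a, b)` — uniform on `(a, b)`, the standard assignment
#'   for a component known only to lie within a tolerance interval
#'   (precision resistors);
#' * `pdf_ushaped(a, b)` — arcsine distribution on `(a, b)`, the standard
#'   assignment for components whose value drifts periodically between
#'   bounds (capacitors subject to, e.g., thermal cycling).
#'
#' @param mu Mean, in the quantity's native units.
#' @param sigma Standard deviation, strictly positive.
#' @param a,b Lower and upper interval bounds, `a < b`.
#'
#' @return An object of class `pdf_spec`.
#' @examples
#' pdf_normal(0.30, 0.04)
#' pdf_rectangular(21.78, 22.22)
#' pdf_ushaped(0.99, 1.01)
#' @export
pdf_normal <- function(mu, sigma) {
  new_pdf_spec("normal", mu = mu, sigma = sigma)
}

#' @rdname pdf_normal
#' @export
pdf_rectangular <- function(a, b) {
  new_pdf_spec("rectangular", a = a, b = b)
}

#' @rdname pdf_normal
#' @export
pdf_ushaped <- function(a, b) {
  new_pdf_spec("u_shaped", a = a, b = b)
}

pdf_families <- c("normal", "rectangular", "u_shaped")

new_pdf_spec <- function(family, mu = NULL, sigma = NULL, a = NULL, b = NULL) {
  family <- match.arg(family, pdf_families)
  spec <- switch(family,
    normal      = list(family = family, mu = mu, sigma = sigma),
    rectangular = ,
    u_shaped    = list(family = family, a = a, b = b)
  )
  validate_pdf_spec(structure(spec, class = "pdf_spec"))
}

validate_pdf_spec <- function(spec) {
  if (!inherits(spec, "pdf_spec")) {
    stop("`spec` must be a pdf_spec object", call. = FALSE)
  }
  fam <- spec$family
  if (!is.character(fam) || length(fam) != 1L || !fam %in% pdf_families) {
    stop("unknown PDF family: ", format(fam), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (fam == "normal") {
    if (!num1(spec$mu)) stop("normal PDF requires a finite scalar `mu`", call. = FALSE)
    if (!num1(spec$sigma) || spec$sigma <= 0) {
      stop("normal PDF requires `sigma` > 0", call. = FALSE)
    }
  } else {
    if (!num1(spec$a) || !num1(spec$b)) {
      stop(fam, " PDF requires finite scalar bounds `a` and `b`", call. = FALSE)
    }
    if (spec$a >= spec$b) stop(fam, " PDF requires a < b", call. = FALSE)
  }
  spec
}

#' @export
print.pdf_spec <- function(x, ...) {
  desc <- switch(x$family,
    normal      = sprintf("N(mu = %g, sigma = %g)", x$mu, x$sigma),
    rectangular = sprintf("R(a = %g, b = %g)", x$a, x$b),
    u_shaped    = sprintf("U(a = %g, b = %g)", x$a, x$b)
  )
  cat("<pdf_spec> ", desc, "\n", sep = "")
  invisible(x)
}

#' Draw random samples from a PDF specification
#'
#' Normal draws use [stats::rnorm()], rectangular draws [stats::runif()].
#' U-shaped draws follow the arcsine law on `(a, b)` via the inverse CDF
#' `x = a + (b - a) * sin(pi * u / 2)^2` with `u` uniform on (0, 1).
#'
#' @param spec A [pdf_normal()]/[pdf_rectangular()]/[pdf_ushaped()] spec.
#' @param m Number of draws, a positive integer.
#' @param seed Optional integer; when given, draws come from a local RNG
#'   stream seeded with `seed` and the caller's RNG state is untouched, so
#'   identical `(spec, m, seed)` always yield identical vectors.
#' @return Numeric vector of length `m`.
#' @examples
#' pdf_sample(pdf_ushaped(0.99, 1.01), 5, seed = 1)
#' @export
pdf_sample <- function(spec, m, seed = NULL) {
  validate_pdf_spec(spec)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  m <- as.integer(m)
  draw <- function() {
    switch(spec$family,
      normal      = stats::rnorm(m, spec$mu, spec$sigma),
      rectangular = stats::runif(m, spec$a, spec$b),
      u_shaped    = spec$a + (spec$b - spec$a) *
        sin(pi * stats::runif(m) / 2)^2
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Analytic mean and standard deviation of a PDF specification
#'
#' These closed-form moments are what the analytic (GUM-style) propagation
#' engine uses as standard uncertainties `u(Xi)`: for a rectangular PDF the
#' half-width divided by `sqrt(3)` (equivalently `(b - a)/sqrt(12)`), for the
#' arcsine U-shape the half-width divided by `sqrt(2)`.
#'
#' @inheritParams pdf_sample
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @examples
#' pdf_moments(pdf_rectangular(0, 1))   # c(0.5, 0.2886751)
#' @export
pdf_moments <- function(spec) {
  validate_pdf_spec(spec)
  switch(spec$family,
    normal      = c(mean = spec$mu, sd = spec$sigma),
    rectangular = c(mean = (spec$a + spec$b) / 2,
                    sd   = (spec$b - spec$a) / sqrt(12)),
    u_shaped    = c(mean = (spec$a + spec$b) / 2,
                    sd   = (spec$b - spec$a) / (2 * sqrt(2)))
  )
}

#' Build a bounded PDF from a component tolerance
#'
#' A component marked, e.g., "22 kOhm, 1 %" is assigned a bounded PDF on
#' `nominal * (1 - tol_fraction)` to `nominal * (1 + tol_fraction)`; the
#' tolerance is multiplicative on the nominal value, as on component
#' datasheets.
#'
#' @param nominal Nominal component value (non-zero).
#' @param tol_fraction Tolerance as a fraction (0.01 for 1 %).
#' @param family `"rectangular"` (default) or `"u_shaped"`. A tolerance
#'   interval has no meaningful normal assignment.
#' @return A `pdf_spec`.
#' @examples
#' pdf_from_tolerance(22, 0.01)             # R(21.78, 22.22)
#' pdf_from_tolerance(10, 0.01, "u_shaped") # U(9.9, 10.1)
#' @export
pdf_from_tolerance <- function(nominal, tol_fraction,
                               family = c("rectangular", "u_shaped")) {
  family <- match.arg(family)
  if (!is.numeric(nominal) || length(nominal) != 1L || nominal == 0) {
    stop("`nominal` must be a non-zero scalar", call. = FALSE)
  }
  if (!is.numeric(tol_fraction) || length(tol_fraction) != 1L ||
      tol_fraction <= 0) {
    stop("`tol_fraction` must be > 0", call. = FALSE)
  }
  bounds <- sort(nominal * c(1 - tol_fraction, 1 + tol_fraction))
  if (family == "rectangular") {
    pdf_rectangular(bounds[1], bounds[2])
  } else {
    pdf_ushaped(bounds[1], bounds[2])
  }
}

# serialize / deserialize for the configuration dialect --------------------

pdf_to_list <- function(spec) {
  validate_pdf_spec(spec)
  unclass(spec)
}

pdf_from_list <- function(x) {
  if (is.null(x$family)) stop("PDF definition needs a `family` field", call. = FALSE)
  fam <- as.character(x$family)
  if (!fam %in% pdf_families) {
    stop("unknown PDF family in configuration: ", fam, call. = FALSE)
  }
  if (fam == "normal") {
    pdf_normal(as.numeric(x$mu), as.numeric(x$sigma))
  } else {
    new_pdf_spec(fam, a = as.numeric(x$a), b = as.numeric(x$b))
  }
}
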