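#' Minimum Monte Carlo sample count for a coverage probability
#'
#' The recommended minimum number of Monte Carlo trials grows with the
#' desired coverage probability `p` as `M = ceiling(1e4 / (1 - p))`: at 95 %
#' coverage, 2e5 trials.
#'
#' @param p Coverage probability, strictly between 0 and 1.
#' @return Positive integer sample count.
#' @examples
#' required_samples(0.95)  # 200000
#' @export
required_samples <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  # guard the ceiling against floating-point dust in 1e4/(1-p)
  as.integer(ceiling(1e4 / (1 - p) - 1e-6))
}

coverage_factor <- function(p) {
  if (abs(p - 0.95) < 1e-12) 1.96 else stats::qnorm((1 + p) / 2)
}

#' Expanded uncertainty from a standard deviation
#'
#' Multiplies a standard uncertainty by the coverage factor `k(p)`; at
#' `p = 0.95` the conventional `k = 1.96` is used, other probabilities take
#' the normal quantile.
#'
#' @param sd Standard uncertainty (non-negative).
#' @param p Coverage probability (default 0.95).
#' @return Expanded uncertainty in the units of `sd`.
#' @examples
#' expanded_uncertainty(57.0)  # 111.7
#' @export
expanded_uncertainty <- function(sd, p = 0.95) {
  if (!is.numeric(sd) || any(sd < 0)) {
    stop("`sd` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  coverage_factor(p) * sd
}

# Draw the m x n sample matrix for all quantities entering the static
# output equation. Columns are drawn sequentially in declaration order from
# a single seeded stream, so any run (full or per-source) that shares the
# seed shares the draws.
mcm_draws <- function(system, m, seed) {
  qs <- active_quantities(system)
  draw_all <- function() {
    A <- vapply(qs, function(q) pdf_sample(q$pdf, m), numeric(m))
    colnames(A) <- names(qs)
    A
  }
  withr::with_seed(seed, draw_all())
}

new_mcm_result <- function(samples, p, m, seed, label, keep_samples = TRUE) {
  mu <- mean(samples)
  s <- stats::sd(samples)
  u95 <- expanded_uncertainty(s, p)
  ci <- unname(stats::quantile(samples, c((1 - p) / 2, (1 + p) / 2)))
  structure(
    list(samples = if (keep_samples) samples else NULL,
         mean = mu, sd = s, U95 = u95,
         U95_percent = 100 * u95 / mu,
         coverage_interval = ci,
         p = p, k = coverage_factor(p), m = m, seed = seed, label = label),
    class = "mcm_result"
  )
}

#' @export
print.mcm_result <- function(x, digits = 4, ...) {
  cat(sprintf("<mcm_result> %s (m = %d, seed = %d, p = %g)\n", x$label, x$m,
              x$seed, x$p))
  cat(sprintf("  mean  %s mV\n", format(x$mean, digits = digits + 2)))
  cat(sprintf("  sd    %s mV\n", format(x$sd, digits = digits)))
  cat(sprintf("  U95   %s mV  (%s %% of mean, k = %g)\n",
              format(x$U95, digits = digits),
              format(x$U95_percent, digits = digits), x$k))
  cat(sprintf("  %g %% coverage interval: [%s, %s] mV\n", 100 * x$p,
              format(x$coverage_interval[1], digits = digits + 2),
              format(x$coverage_interval[2], digits = digits + 2)))
  invisible(x)
}

validate_mcm_args <- function(system, m, seed) {
  stopifnot(inherits(system, "mcm_system"))
  if (!is.numeric(m) || length(m) != 1L || m < 1e3 || m != round(m)) {
    stop("`m` must be an integer >= 1000", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  for (q in active_quantities(system)) validate_pdf_spec(q$pdf)
  invisible(TRUE)
}

#' Full Monte Carlo propagation through a measurement system
#'
#' Draws `m` values for every quantity entering the output equation, from
#' its assigned PDF, evaluates the measurement equation row-wise and
#' summarises the resulting output-value distribution (mean, standard
#' deviation, expanded uncertainty `k * sd`, symmetric percentile coverage
#' interval). Deterministic given `seed`.
#'
#' @param system An [mcm_system()].
#' @param m Number of Monte Carlo trials (default [required_samples()] at
#'   `p`).
#' @param seed Integer RNG seed; recorded in the result.
#' @param p Coverage probability (default 0.95).
#' @param keep_samples Keep the raw output samples in the result (default
#'   TRUE; set FALSE to save memory in batch runs).
#' @return An `mcm_result`.
#' @examples
#' mcm_run(ecg_system(), m = 10000, seed = 1)
#' @export
mcm_run <- function(system, m = required_samples(p), seed = 20230113L,
                    p = 0.95, keep_samples = TRUE) {
  validate_mcm_args(system, m, seed)
  A <- mcm_draws(system, m, seed)
  y <- eval_model(system, as.data.frame(A))
  new_mcm_result(y, p, as.integer(m), as.integer(seed), "all sources",
                 keep_samples)
}

#' One-at-a-time / per-block Monte Carlo propagation
#'
#' Varies only the named quantities according to their PDFs while holding
#' every other quantity constant at its nominal value, isolating the output
#' dispersion attributable to that source (or block of sources). The varied
#' columns reuse the exact draws of the full run at the same seed, so
#' per-source rows and the all-sources total are consistent by construction.
#'
#' @inheritParams mcm_run
#' @param sources Non-empty character vector of quantity names to vary.
#' @return An `mcm_result` labelled with the varied sources.
#' @examples
#' mcm_run_sources(ecg_system(), c("vin_plus", "vin_minus"),
#'                 m = 10000, seed = 1)
#' @export
mcm_run_sources <- function(system, sources, m = required_samples(p),
                            seed = 20230113L, p = 0.95, keep_samples = TRUE) {
  validate_mcm_args(system, m, seed)
  qs <- active_quantities(system)
  if (!length(sources)) stop("`sources` must be non-empty", call. = FALSE)
  unknown <- setdiff(sources, names(qs))
  if (length(unknown)) {
    stop("unknown source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  A <- mcm_draws(system, m, seed)
  B <- matrix(rep(nominal_values(system), each = m), nrow = m,
              dimnames = list(NULL, names(qs)))
  B[, sources] <- A[, sources]
  y <- eval_model(system, as.data.frame(B))
  new_mcm_result(y, p, as.integer(m), as.integer(seed),
                 paste(sources, collapse = "+"), keep_samples)
}

#' Per-source / per-block uncertainty budget
#'
#' Runs one per-source propagation for every named subset in `grouping` plus
#' the all-sources total, all from a single draw matrix at one seed, and
#' tabulates mean, standard deviation, expanded uncertainty and its
#' percentage of the row mean. Each row's `group` label is taken from the
#' group tags of its quantities (or `"mixed"`).
#'
#' @inheritParams mcm_run
#' @param grouping Named list of character vectors (subsets of quantity
#'   names). Defaults to the system's declared grouping. Overlapping subsets
#'   are allowed but flagged with a warning. An empty list yields a budget
#'   with only the total row.
#' @return An object of class `uncertainty_budget` with a `rows` data frame,
#'   a `total` row and the per-row `mcm_result`s in `results`.
#' @examples
#' mcm_budget(ecg_system(), m = 10000, seed = 1)
#' @export
mcm_budget <- function(system, grouping = system$groupings,
                       m = required_samples(p), seed = 20230113L, p = 0.95) {
  validate_mcm_args(system, m, seed)
  qs <- active_quantities(system)
  if (is.null(grouping)) grouping <- list()
  validate_grouping(grouping, names(qs))
  all_named <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_named)) {
    warning("overlapping budget subsets: ",
            paste(unique(all_named[duplicated(all_named)]), collapse = ", "),
            call. = FALSE)
  }

  A <- mcm_draws(system, m, seed)
  nominals <- nominal_values(system)
  results <- list()

  for (lbl in names(grouping)) {
    B <- matrix(rep(nominals, each = m), nrow = m,
                dimnames = list(NULL, names(qs)))
    B[, grouping[[lbl]]] <- A[, grouping[[lbl]]]
    y <- eval_model(system, as.data.frame(B))
    results[[lbl]] <- new_mcm_result(y, p, as.integer(m), as.integer(seed),
                                     lbl)
  }
  y_all <- eval_model(system, as.data.frame(A))
  total <- new_mcm_result(y_all, p, as.integer(m), as.integer(seed),
                          "All sources")

  row_group <- vapply(grouping, function(subset) {
    g <- unique(vapply(system$quantities[subset], `[[`, "", "group"))
    if (length(g) == 1L) g else "mixed"
  }, "")

  as_row <- function(res, source, group) {
    data.frame(source = source, group = group, mean_mV = res$mean,
               sd_mV = res$sd, U95_mV = res$U95, U95_pct = res$U95_percent,
               ci_lo_mV = res$coverage_interval[1],
               ci_hi_mV = res$coverage_interval[2],
               stringsAsFactors = FALSE)
  }
  rows <- if (length(grouping)) {
    do.call(rbind, c(
      lapply(names(grouping),
             function(lbl) as_row(results[[lbl]], lbl, row_group[[lbl]])),
      list(make.row.names = FALSE)
    ))
  } else {
    as_row(total, "All sources", "total")[0, ]
  }

  structure(
    list(rows = rows, total = as_row(total, "All sources", "total"),
         results = results, total_result = total,
         m = as.integer(m), p = p, seed = as.integer(seed),
         system_name = system$name),
    class = "uncertainty_budget"
  )
}

# report rounding convention: integer mV, two-decimal percents, always from
# unrounded intermediates
round_budget_rows <- function(rows) {
  data.frame(
    source  = rows$source,
    group   = rows$group,
    mean_mV = round(rows$mean_mV),
    sd_mV   = round(rows$sd_mV),
    U95_mV  = round(rows$U95_mV),
    U95_pct = round(rows$U95_pct, 2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> %s (m = %d, p = %g, seed = %d)\n",
              x$system_name, x$m, x$p, x$seed))
  tab <- round_budget_rows(rbind(x$rows, x$total))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo uncertainty of the amplifier cut-off frequencies
#'
#' The components shaping the frequency response (`R9`, `C1` for the first
#' stage; `R11`, `C2` for the second) do not enter the static output
#' equation, so their uncertainty is budgeted separately: this propagates
#' their PDFs through `f = 1 / (2 pi R C)` and summarises both cut-offs.
#'
#' @param system An [mcm_system()] declaring quantities `R9`, `C1`, `R11`,
#'   `C2` in native units (MOhm, uF, kOhm, nF).
#' @inheritParams mcm_run
#' @return List with `mcm_result`s `f1` and `f2` (Hz).
#' @examples
#' cutoff_uncertainty(ecg_system(), m = 10000, seed = 1)
#' @export
cutoff_uncertainty <- function(system, m = required_samples(p),
                               seed = 20230113L, p = 0.95) {
  stopifnot(inherits(system, "mcm_system"))
  need <- c("R9", "C1", "R11", "C2")
  unknown <- setdiff(need, names(system$quantities))
  if (length(unknown)) {
    stop("system lacks quantity(ies): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- as.integer(m)
  draws <- withr::with_seed(seed, {
    out <- lapply(system$quantities[need], function(q) pdf_sample(q$pdf, m))
    names(out) <- need
    out
  })
  f1 <- 1 / (2 * pi * draws$C1 * 1e-6 * draws$R9 * 1e6)
  f2 <- 1 / (2 * pi * draws$C2 * 1e-9 * draws$R11 * 1e3)
  list(f1 = new_mcm_result(f1, p, m, as.integer(seed), "f1 (first stage)"),
       f2 = new_mcm_result(f2, p, m, as.integer(seed), "f2 (final stage)"))
}
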