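#' Declare an uncertain input quantity of a measurement system
#'
#' A quantity couples a name, a nominal value (in its native unit), a PDF
#' characterising its uncertainty, and two tags used by the budget machinery:
#' `group` locates the source among the three classic budget blocks
#' (measurand / measuring system / environment) and `block` locates it in the
#' circuit. Quantities tagged `block = "frequency_only"` shape the amplifier's
#' frequency response (cut-off frequencies) but never enter the static output
#' equation, so they are excluded from output-voltage propagation.
#'
#' The nominal value must equal the PDF's analytic mean to within 1 part in
#' 1e3: budget rows are reported relative to the nominal output, so a
#' mismatch would silently bias every row.
#'
#' @param name Unique identifier (a syntactic name).
#' @param nominal Nominal value in `unit`.
#' @param pdf A [pdf_normal()]/[pdf_rectangular()]/[pdf_ushaped()] spec.
#' @param group One of `"measurand"`, `"measuring_system"`, `"environment"`.
#' @param block One of `"input"`, `"preamplifier"`, `"final_stage"`,
#'   `"frequency_only"`.
#' @param unit Unit label (string, informational).
#' @return An object of class `uncertain_quantity`.
#' @export
uncertain_quantity <- function(name, nominal, pdf,
                               group = c("measurand", "measuring_system",
                                         "environment"),
                               block = c("input", "preamplifier",
                                         "final_stage", "frequency_only"),
                               unit = "") {
  group <- match.arg(group)
  block <- match.arg(block)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(nominal) || length(nominal) != 1L || !is.finite(nominal)) {
    stop("`nominal` must be a finite scalar", call. = FALSE)
  }
  validate_pdf_spec(pdf)
  mu <- unname(pdf_moments(pdf)["mean"])
  tol <- max(1e-3, 1e-3 * abs(nominal))
  if (abs(mu - nominal) > tol) {
    stop(sprintf(
      "quantity '%s': nominal %g disagrees with the PDF mean %g", name,
      nominal, mu), call. = FALSE)
  }
  structure(
    list(name = name, nominal = nominal, pdf = pdf, group = group,
         block = block, unit = unit),
    class = "uncertain_quantity"
  )
}

#' @export
print.uncertain_quantity <- function(x, ...) {
  cat(sprintf("<uncertain_quantity> %s = %g %s  [%s/%s]\n", x$name, x$nominal,
              x$unit, x$group, x$block))
  print(x$pdf)
  invisible(x)
}

# ---- measurement models ---------------------------------------------------

#' Gain of the three-op-amp instrumentation preamplifier
#'
#' `G1 = (1 + 2 R1 / R2) * (R5 / R4)`. All resistances must share one unit
#' (the bundled model uses kilo-ohms); the gain is dimensionless. Vectorised
#' over its arguments.
#'
#' @param R1,R2,R4,R5 Resistances; `R2 > 0`, `R4 > 0`.
#' @return Dimensionless gain.
#' @examples
#' preamp_gain(22, 10, 10, 47)  # 25.38
#' @export
preamp_gain <- function(R1, R2, R4, R5) {
  if (any(R2 <= 0) || any(R4 <= 0)) {
    stop("preamp_gain requires R2 > 0 and R4 > 0", call. = FALSE)
  }
  (1 + 2 * R1 / R2) * (R5 / R4)
}

#' Gain of the final amplification stage
#'
#' `G2 = 1 + R11 / R8`, the non-inverting gain of the output stage.
#' Vectorised.
#'
#' @param R8,R11 Resistances in a common unit; `R8 > 0`.
#' @return Dimensionless gain.
#' @examples
#' final_gain(5, 150)  # 31
#' @export
final_gain <- function(R8, R11) {
  if (any(R8 <= 0)) stop("final_gain requires R8 > 0", call. = FALSE)
  1 + R11 / R8
}

#' Nominal component values of the two-stage ECG amplifier
#'
#' Container for the circuit's component values and input voltages in their
#' native units: resistances in kilo-ohms except `R9` (mega-ohms), `C1` in
#' microfarads, `C2` in nanofarads, voltages in millivolts. Defaults are the
#' bundled amplifier's nominals. Duplicate components of the symmetric
#' instrumentation topology are eliminated (`R3 = R1`, `R6 = R4`, `R7 = R5`,
#' `R10 = R9`).
#'
#' @param R1,R2,R4,R5,R8,R11 Resistances (kOhm).
#' @param R9 Resistance (MOhm), first-stage high-pass path.
#' @param C1 Capacitance (uF), first-stage coupling.
#' @param C2 Capacitance (nF), final-stage feedback.
#' @param vin_plus,vin_minus Differential electrode voltages (mV).
#' @param baseline Input-referred baseline offset (mV).
#' @param noise Input-referred environmental noise (mV).
#' @return An object of class `ecg_circuit`.
#' @export
ecg_circuit <- function(R1 = 22, R2 = 10, R4 = 10, R5 = 47, R8 = 5,
                        R9 = 3.3, R11 = 150, C1 = 1, C2 = 10,
                        vin_plus = 0.30, vin_minus = 0.00,
                        baseline = 3.00, noise = 0.00) {
  vals <- list(R1 = R1, R2 = R2, R4 = R4, R5 = R5, R8 = R8, R9 = R9,
               R11 = R11, C1 = C1, C2 = C2, vin_plus = vin_plus,
               vin_minus = vin_minus, baseline = baseline, noise = noise)
  pos <- c("R1", "R2", "R4", "R5", "R8", "R9", "R11", "C1", "C2")
  for (nm in pos) {
    if (!is.numeric(vals[[nm]]) || any(vals[[nm]] <= 0)) {
      stop("circuit component ", nm, " must be strictly positive",
           call. = FALSE)
    }
  }
  structure(vals, class = "ecg_circuit")
}

#' Static output voltage of the two-stage amplifier
#'
#' The measurement equation: the baseline offset and environmental noise are
#' input-referred, i.e. added to the differential signal before the
#' preamplifier, and the two gains act in cascade:
#' `vout = G2 * G1 * (vin_plus - vin_minus + baseline + noise)`.
#' The static gain model is used throughout; frequency-dependent attenuation
#' near the cut-offs is not applied (the budgets are static).
#'
#' @param circuit An [ecg_circuit()].
#' @return Output voltage in mV.
#' @examples
#' system_output(ecg_circuit())  # 2596.36 at the bundled nominals
#' @export
system_output <- function(circuit) {
  if (!inherits(circuit, "ecg_circuit")) {
    stop("`circuit` must be an ecg_circuit", call. = FALSE)
  }
  g1 <- preamp_gain(circuit$R1, circuit$R2, circuit$R4, circuit$R5)
  g2 <- final_gain(circuit$R8, circuit$R11)
  g2 * g1 * (circuit$vin_plus - circuit$vin_minus +
               circuit$baseline + circuit$noise)
}

#' First- and second-stage cut-off frequencies
#'
#' `f1 = 1 / (2 pi C1 R9)` and `f2 = 1 / (2 pi C2 R11)`. With
#' `units = "native"` the arguments carry the circuit's native units
#' (R9 in MOhm, C1 in uF, R11 in kOhm, C2 in nF) and are converted to SI
#' internally; with `units = "si"` they are ohms and farads.
#'
#' @param R9,C1,R11,C2 Component values, all strictly positive.
#' @param units `"native"` (default) or `"si"`.
#' @return Named numeric vector `c(f1 = ..., f2 = ...)` in Hz.
#' @examples
#' cutoff_frequencies(3.3, 1, 150, 10)  # c(f1 = 0.0482, f2 = 106.1)
#' @export
cutoff_frequencies <- function(R9, C1, R11, C2, units = c("native", "si")) {
  units <- match.arg(units)
  if (any(c(R9, C1, R11, C2) <= 0)) {
    stop("all components must be strictly positive", call. = FALSE)
  }
  if (units == "native") {
    R9 <- R9 * 1e6    # MOhm -> Ohm
    C1 <- C1 * 1e-6   # uF  -> F
    R11 <- R11 * 1e3  # kOhm -> Ohm
    C2 <- C2 * 1e-9   # nF  -> F
  }
  c(f1 = 1 / (2 * pi * C1 * R9), f2 = 1 / (2 * pi * C2 * R11))
}

# ---- systems of uncertain quantities --------------------------------------

# builtin measurement equations, evaluated column-wise over a data.frame of
# quantity samples
builtin_models <- list(
  ecg_two_stage = function(x) {
    preamp_gain(x$R1, x$R2, x$R4, x$R5) * final_gain(x$R8, x$R11) *
      (x$vin_plus - x$vin_minus + x$baseline + x$noise)
  }
)

# arithmetic-expression models: parsed once, evaluated over quantity columns
# in a restricted environment (operators, parentheses and unary math only)
model_from_expression <- function(text, quantity_names) {
  expr <- tryCatch(parse(text = text)[[1]],
                   error = function(e) stop("cannot parse model expression: ",
                                            conditionMessage(e), call. = FALSE))
  allowed_funs <- c("+", "-", "*", "/", "^", "(", "exp", "log", "log10",
                    "sqrt", "sin", "cos", "tan", "abs")
  vars <- all.vars(expr)
  funs <- setdiff(all.names(expr), vars)
  bad_fun <- setdiff(funs, allowed_funs)
  if (length(bad_fun)) {
    stop("model expression uses unsupported function(s): ",
         paste(bad_fun, collapse = ", "), call. = FALSE)
  }
  bad_var <- setdiff(vars, quantity_names)
  if (length(bad_var)) {
    stop("model expression references undeclared quantity(ies): ",
         paste(bad_var, collapse = ", "), call. = FALSE)
  }
  base_env <- new.env(parent = baseenv())
  function(x) eval(expr, envir = as.list(x), enclos = base_env)
}

#' Assemble a measurement system for uncertainty propagation
#'
#' A system bundles named [uncertain_quantity()] declarations with a
#' deterministic measurement equation mapping quantity values to the output.
#' The model may be the name of a built-in equation (`"ecg_two_stage"`), an
#' arithmetic expression string over the quantity names (e.g.
#' `"x1 + 2 * x2"`), or an R function taking a data frame with one column
#' per quantity.
#'
#' @param quantities List of [uncertain_quantity()] objects with unique names.
#' @param model Model selector (see Details).
#' @param name Label for reports.
#' @param groupings Optional named list of character vectors defining the
#'   default budget rows (each vector a set of quantity names).
#' @return An object of class `mcm_system`.
#' @seealso [ecg_system()] for the bundled amplifier model.
#' @export
mcm_system <- function(quantities, model = "ecg_two_stage",
                       name = "measurement system", groupings = NULL) {
  if (!length(quantities)) stop("`quantities` must be non-empty", call. = FALSE)
  for (q in quantities) {
    if (!inherits(q, "uncertain_quantity")) {
      stop("all elements of `quantities` must be uncertain_quantity objects",
           call. = FALSE)
    }
  }
  nms <- vapply(quantities, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate quantity names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(quantities) <- nms

  model_name <- NULL
  if (is.function(model)) {
    model_fun <- model
    model_name <- "user function"
  } else if (is.character(model) && length(model) == 1L) {
    if (model %in% names(builtin_models)) {
      model_fun <- builtin_models[[model]]
      model_name <- model
      missing_q <- setdiff(c("R1", "R2", "R4", "R5", "R8", "R11", "vin_plus",
                             "vin_minus", "baseline", "noise"), nms)
      if (model == "ecg_two_stage" && length(missing_q)) {
        stop("ecg_two_stage model needs quantities: ",
             paste(missing_q, collapse = ", "), call. = FALSE)
      }
    } else {
      model_fun <- model_from_expression(model, nms)
      model_name <- model
    }
  } else {
    stop("`model` must be a function or a single string", call. = FALSE)
  }

  if (!is.null(groupings)) validate_grouping(groupings, nms)

  sys <- structure(
    list(quantities = quantities, model = model_fun, model_name = model_name,
         name = name, groupings = groupings),
    class = "mcm_system"
  )
  # fail fast if the model cannot evaluate at nominals
  out0 <- nominal_output(sys)
  if (!is.finite(out0)) {
    stop("model does not evaluate to a finite value at the nominals",
         call. = FALSE)
  }
  sys
}

validate_grouping <- function(grouping, quantity_names) {
  if (!is.list(grouping) || (length(grouping) && is.null(names(grouping)))) {
    stop("`grouping` must be a named list of quantity-name vectors",
         call. = FALSE)
  }
  for (lbl in names(grouping)) {
    unknown <- setdiff(grouping[[lbl]], quantity_names)
    if (length(unknown)) {
      stop(sprintf("grouping '%s' references unknown quantity(ies): %s", lbl,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(grouping)
}

# quantities entering the static output equation
active_quantities <- function(system) {
  Filter(function(q) q$block != "frequency_only", system$quantities)
}

nominal_values <- function(system, active_only = TRUE) {
  qs <- if (active_only) active_quantities(system) else system$quantities
  vapply(qs, `[[`, 0, "nominal")
}

eval_model <- function(system, values) {
  # values: named list / data.frame of equal-length vectors
  y <- system$model(as.data.frame(values))
  if (!is.numeric(y)) stop("model did not return a numeric vector", call. = FALSE)
  y
}

#' Nominal (noise-free) model output of a system
#'
#' Evaluates the measurement equation with every quantity at its nominal
#' value.
#'
#' @param system An [mcm_system()].
#' @return Scalar model output.
#' @export
nominal_output <- function(system) {
  vals <- as.list(nominal_values(system))
  as.numeric(eval_model(system, vals))
}

#' @export
print.mcm_system <- function(x, ...) {
  cat(sprintf("<mcm_system> %s\n", x$name))
  cat(sprintf("  model: %s\n", x$model_name))
  qs <- x$quantities
  cat(sprintf("  quantities (%d):\n", length(qs)))
  for (q in qs) {
    cat(sprintf("    %-10s %10g %-4s %-16s %s\n", q$name, q$nominal, q$unit,
                paste0("[", q$block, "]"), format(q$pdf)))
  }
  cat(sprintf("  nominal output: %g\n", nominal_output(x)))
  invisible(x)
}

#' @export
format.pdf_spec <- function(x, ...) {
  switch(x$family,
    normal      = sprintf("N(%g, %g)", x$mu, x$sigma),
    rectangular = sprintf("R(%g, %g)", x$a, x$b),
    u_shaped    = sprintf("U(%g, %g)", x$a, x$b)
  )
}

#' The bundled two-stage ECG amplifier as a measurement system
#'
#' Builds the amplifier's thirteen uncertainty sources with their standard
#' PDF assignment: electrode voltages, baseline and noise are normal;
#' resistors are rectangular on their tolerance interval (1 % by default);
#' capacitors are U-shaped (arcsine) on a 1 % interval. `R9`, `C1` and `C2`
#' shape only the cut-off frequencies (`block = "frequency_only"`) and do not
#' enter the output-voltage equation. The default budget grouping has five
#' rows: vin (both electrode voltages), Baseline, Preamplifier (R1 R2 R4 R5),
#' Final stage (R8 R11), and Noise.
#'
#' @param resistor_tol Fractional tolerance applied to all resistors
#'   (default 0.01, i.e. 1 %).
#' @param capacitor_tol Fractional tolerance for the capacitors (default 0.01).
#' @return An [mcm_system()].
#' @examples
#' sys <- ecg_system()
#' nominal_output(sys)   # 2596.36 mV
#' @export
ecg_system <- function(resistor_tol = 0.01, capacitor_tol = 0.01) {
  rq <- function(name, nominal, block, unit = "kOhm") {
    uncertain_quantity(name, nominal,
                       pdf_from_tolerance(nominal, resistor_tol),
                       group = "measuring_system", block = block, unit = unit)
  }
  cq <- function(name, nominal, unit) {
    uncertain_quantity(name, nominal,
                       pdf_from_tolerance(nominal, capacitor_tol, "u_shaped"),
                       group = "measuring_system", block = "frequency_only",
                       unit = unit)
  }
  quantities <- list(
    uncertain_quantity("vin_plus", 0.30, pdf_normal(0.30, 0.04),
                       group = "measurand", block = "input", unit = "mV"),
    uncertain_quantity("vin_minus", 0.00, pdf_normal(0.00, 0.04),
                       group = "measurand", block = "input", unit = "mV"),
    uncertain_quantity("baseline", 3.00, pdf_normal(3.00, 0.01),
                       group = "measurand", block = "input", unit = "mV"),
    rq("R1", 22, "preamplifier"),
    rq("R2", 10, "preamplifier"),
    rq("R4", 10, "preamplifier"),
    rq("R5", 47, "preamplifier"),
    rq("R8", 5, "final_stage"),
    rq("R9", 3.3, "frequency_only", unit = "MOhm"),
    rq("R11", 150, "final_stage"),
    cq("C1", 1, "uF"),
    cq("C2", 10, "nF"),
    uncertain_quantity("noise", 0.00, pdf_normal(0.00, 0.01),
                       group = "environment", block = "input", unit = "mV")
  )
  mcm_system(
    quantities,
    model = "ecg_two_stage",
    name = "two-stage ECG amplifier",
    groupings = list(
      vin            = c("vin_plus", "vin_minus"),
      Baseline       = "baseline",
      Preamplifier   = c("R1", "R2", "R4", "R5"),
      `Final stage`  = c("R8", "R11"),
      Noise          = "noise"
    )
  )
}

#' Tighten component tolerances of a system (design variant)
#'
#' Rebuilds the bounded PDFs of the named quantities from their nominal
#' values at a new fractional tolerance, e.g. substituting 0.1 % precision
#' resistors for 1 % ones. The PDF family of each quantity is preserved.
#'
#' @param system An [mcm_system()].
#' @param quantities Character vector of quantity names to retolerance.
#' @param tol_fraction New fractional tolerance (0.001 for 0.1 %).
#' @return A modified copy of `system`.
#' @examples
#' sys01 <- apply_tolerance(ecg_system(), c("R1", "R2", "R4", "R5"), 0.001)
#' @export
apply_tolerance <- function(system, quantities, tol_fraction) {
  stopifnot(inherits(system, "mcm_system"))
  unknown <- setdiff(quantities, names(system$quantities))
  if (length(unknown)) {
    stop("unknown quantity(ies): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in quantities) {
    q <- system$quantities[[nm]]
    if (q$pdf$family == "normal") {
      stop(sprintf(
        "quantity '%s' has a normal PDF; tolerances apply to bounded PDFs",
        nm), call. = FALSE)
    }
    fam <- if (q$pdf$family == "u_shaped") "u_shaped" else "rectangular"
    system$quantities[[nm]]$pdf <- pdf_from_tolerance(q$nominal, tol_fraction,
                                                      fam)
  }
  system
}
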