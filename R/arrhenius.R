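#' Calibrate an Arrhenius law to a reported value
#'
#' Given a kinetic parameter's reported value x_ref at reference temperature
#' T_ref and an activation enthalpy deltaH, solves
#' x_ref = exp(c - deltaH/(R * T_ref)) for the constant c:
#' c = ln(x_ref) + deltaH / (R * T_ref), with R = 0.008314 kJ/mol/K.
#' By construction the law reproduces x_ref at T_ref exactly.
#'
#' @param x_ref reported parameter value at the reference temperature (> 0)
#' @param temp_ref_k reference temperature, kelvin (> 0)
#' @param delta_h activation enthalpy, kJ/mol
#' @return an [ArrheniusLaw-class]
#' @examples
#' law <- calibrateArrhenius(2.98, temp_ref_k = 303.15, delta_h = 47.2)
#' arrheniusValue(law, 303.15)  # 2.98
#' @export
calibrateArrhenius <- function(x_ref, temp_ref_k, delta_h) {
  if (!is.finite(x_ref) || x_ref <= 0)
    stop("x_ref must be strictly positive")
  if (!is.finite(temp_ref_k) || temp_ref_k <= 0)
    stop("temp_ref_k must be positive kelvin")
  new("ArrheniusLaw", delta_h = as.numeric(delta_h),
      c = log(x_ref) + delta_h / (GAS_CONSTANT * temp_ref_k))
}

#' Evaluate an Arrhenius law
#'
#' @param law an [ArrheniusLaw-class]
#' @param temp_k temperature(s) in kelvin (> 0)
#' @return x(temp_k) = exp(c - deltaH/(R * temp_k))
#' @export
arrheniusValue <- function(law, temp_k) {
  stopifnot(is(law, "ArrheniusLaw"))
  if (any(temp_k <= 0)) stop("temperatures must be positive kelvin")
  exp(law@c - law@delta_h / (GAS_CONSTANT * temp_k))
}

#' Build a temperature model from kinetic parameters and enthalpies
#'
#' Calibrates one Arrhenius law per kinetic parameter (kcat_C, K_C, K_O and
#' the derived kcat_O), each anchored at its own reference temperature.
#' kcat_O is never a user input: its reference value is computed from the
#' specificity identity kcat_O = kcat_C * K_O / (S_C/O * K_C) using the
#' reported values, and is anchored at the kcat_C reference temperature. Its
#' enthalpy must be supplied explicitly.
#'
#' @param params a [KineticParams-class]
#' @param delta_h named numeric with entries kcat_C, K_C, K_O, kcat_O
#'   (kJ/mol)
#' @return a [TemperatureModel-class]
#' @export
buildTemperatureModel <- function(params, delta_h) {
  stopifnot(is(params, "KineticParams"))
  need <- c("kcat_C", "K_C", "K_O", "kcat_O")
  if (!all(need %in% names(delta_h)))
    stop("delta_h must be named for ", paste(need, collapse = ", "),
         " (no default enthalpy for kcat_O)")
  refk <- params@ref_temp_k
  laws <- list(
    kcat_C = calibrateArrhenius(params@kcat_C, refk[["kcat_C"]],
                                delta_h[["kcat_C"]]),
    K_C = calibrateArrhenius(params@K_C, refk[["K_C"]], delta_h[["K_C"]]),
    K_O = calibrateArrhenius(params@K_O, refk[["K_O"]], delta_h[["K_O"]]),
    kcat_O = calibrateArrhenius(kcatOFromSpecificity(params),
                                refk[["kcat_C"]], delta_h[["kcat_O"]]))
  new("TemperatureModel", form_id = params@form_id, laws = laws)
}

#' Kinetic parameters at a target temperature
#'
#' Evaluates each Arrhenius law at T = temp_c + 273.15 and re-derives the
#' specificity factor from the scaled values,
#' S_C/O = kcat_C(T) * K_O(T) / (kcat_O(T) * K_C(T)).
#'
#' @param model a [TemperatureModel-class]
#' @param temp_c target temperature, Celsius
#' @return a [KineticParams-class] whose reference temperature is temp_c
#' @export
paramsAtTemperature <- function(model, temp_c) {
  stopifnot(is(model, "TemperatureModel"))
  validObject(model)
  tk <- temp_c + 273.15
  if (tk <= 0) stop("temperature below absolute zero")
  kcat_C <- arrheniusValue(model@laws$kcat_C, tk)
  K_C <- arrheniusValue(model@laws$K_C, tk)
  K_O <- arrheniusValue(model@laws$K_O, tk)
  kcat_O <- arrheniusValue(model@laws$kcat_O, tk)
  kineticParams(model@form_id, kcat_C = kcat_C, K_C = K_C, K_O = K_O,
                S_CO = kcat_C * K_O / (kcat_O * K_C), ref_temp_c = temp_c)
}
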