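#' Construct a KineticParams object
#'
#' @param form_id enzyme form label (e.g. "II", "IAc", "IAq")
#' @param kcat_C carboxylation turnover rate, 1/s, > 0
#' @param K_C CO2 half-saturation, uM, > 0
#' @param K_O O2 half-saturation, uM, > 0
#' @param S_CO specificity factor, dimensionless, > 0
#' @param ref_temp_c reference temperature(s) in Celsius: a single value for
#'   all parameters, or a named vector with entries for kcat_C, K_C, K_O and
#'   S_CO when the published values were assayed at different temperatures
#' @return a validated [KineticParams-class]
#' @examples
#' kineticParams("IAc", kcat_C = 2.98, K_C = 42, K_O = 610, S_CO = 47,
#'               ref_temp_c = c(kcat_C = 30, K_C = 25, K_O = 25, S_CO = 25))
#' @export
kineticParams <- function(form_id, kcat_C, K_C, K_O, S_CO, ref_temp_c = 25) {
  need <- c("kcat_C", "K_C", "K_O", "S_CO")
  if (length(ref_temp_c) == 1L && is.null(names(ref_temp_c)))
    ref_temp_c <- stats::setNames(rep(ref_temp_c, 4L), need)
  if (!all(need %in% names(ref_temp_c)))
    stop("ref_temp_c must be a single value or named for ",
         paste(need, collapse = ", "))
  new("KineticParams", form_id = as.character(form_id),
      kcat_C = as.numeric(kcat_C), K_C = as.numeric(K_C),
      K_O = as.numeric(K_O), S_CO = as.numeric(S_CO),
      ref_temp_k = ref_temp_c[need] + 273.15)
}

#' Construct gas/temperature conditions
#'
#' @param co2 CO2 concentration(s), uM, >= 0
#' @param o2 O2 concentration(s), uM, >= 0 (recycled against co2)
#' @param temp_c temperature in Celsius (single value)
#' @return a validated [GasConditions-class]
#' @export
gasConditions <- function(co2, o2, temp_c = 25) {
  n <- max(length(co2), length(o2))
  new("GasConditions", co2 = rep_len(as.numeric(co2), n),
      o2 = rep_len(as.numeric(o2), n), temp_c = as.numeric(temp_c))
}

#' Construct a phosphoglycolate-salvage model
#'
#' @param pathway_name salvage pathway label; "C2" (the default) is the C2
#'   photorespiratory cycle, which releases one CO2 per two 2-phosphoglycolate
#'   molecules salvaged
#' @param co2_loss_per_oxygenation CO2 lost per oxygenation event; 0.5 for the
#'   C2 cycle, 0 disables salvage accounting entirely
#' @return a validated [PGSModel-class]
#' @export
pgsModel <- function(pathway_name = "C2", co2_loss_per_oxygenation = 0.5) {
  new("PGSModel", pathway_name = as.character(pathway_name),
      co2_loss_per_oxygenation = as.numeric(co2_loss_per_oxygenation))
}

#' Oxygenation turnover rate from the specificity factor
#'
#' kcat_O is rarely measured directly; it is recovered from the commonly
#' measured specificity factor via kcat_O = kcat_C * K_O / (S_C/O * K_C).
#'
#' @param params a [KineticParams-class]
#' @return kcat_O in 1/s
#' @export
kcatOFromSpecificity <- function(params) {
  stopifnot(is(params, "KineticParams"))
  params@kcat_C * params@K_O / (params@S_CO * params@K_C)
}

#' Gross carboxylation rate
#'
#' Michaelis-Menten kinetics with O2 as a competitive inhibitor:
#' R_C = kcat_C * \[CO2\] / (\[CO2\] + K_C + K_C * \[O2\] / K_O).
#'
#' @param params a [KineticParams-class]
#' @param cond a [GasConditions-class]
#' @return gross carboxylation rate(s), C/s per active site
#' @examples
#' p <- kineticParams("toy", 2, 10, 100, 10)
#' grossCarboxylation(p, gasConditions(co2 = 10, o2 = 100))  # 2/3
#' @export
grossCarboxylation <- function(params, cond) {
  stopifnot(is(params, "KineticParams"), is(cond, "GasConditions"))
  validObject(params); validObject(cond)
  params@kcat_C * cond@co2 /
    (cond@co2 + params@K_C + params@K_C * cond@o2 / params@K_O)
}

#' Oxygenation rate
#'
#' R_O = kcat_O * \[O2\] / (\[O2\] + K_O + K_O * \[CO2\] / K_C), with CO2 as
#' the competitive inhibitor and kcat_O derived from the specificity factor.
#'
#' @inheritParams grossCarboxylation
#' @return oxygenation rate(s), O/s per active site
#' @export
oxygenationRate <- function(params, cond) {
  stopifnot(is(params, "KineticParams"), is(cond, "GasConditions"))
  validObject(params); validObject(cond)
  kcat_O <- kcatOFromSpecificity(params)
  kcat_O * cond@o2 /
    (cond@o2 + params@K_O + params@K_O * cond@co2 / params@K_C)
}

#' Net carboxylation under phosphoglycolate salvage
#'
#' The net carbon fixation rate f = R_C - loss_ratio * R_O, where loss_ratio
#' is the stoichiometric CO2 cost of salvaging the 2-phosphoglycolate made by
#' each oxygenation (0.5 for the C2 cycle). The difference form is used
#' directly, so \[CO2\] = 0 is well defined (both rates 0, or f <= 0 when
#' only oxygenation proceeds). A net rate of 0 or less marks conditions where
#' autotrophy cannot occur, so `viable` is strictly f_net > 0.
#'
#' @inheritParams grossCarboxylation
#' @param pgs a [PGSModel-class]
#' @return a [RateResult-class] with gross, oxygenation and net rates plus
#'   viability flags, parallel to the conditions
#' @export
netCarboxylation <- function(params, cond, pgs = pgsModel()) {
  stopifnot(is(pgs, "PGSModel"))
  r_c <- grossCarboxylation(params, cond)
  r_o <- oxygenationRate(params, cond)
  f <- r_c - pgs@co2_loss_per_oxygenation * r_o
  new("RateResult", r_c = r_c, r_o = r_o, f_net = f, viable = f > 0)
}
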