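#' @import methods
NULL

## Universal gas constant, kJ/mol/K. All enthalpies in this package are kJ/mol.
GAS_CONSTANT <- 0.008314

#' Arrhenius temperature law for a kinetic parameter
#'
#' Represents x(T) = exp(c - deltaH / (R * T)) with R = 0.008314 kJ/mol/K.
#' A law is usually built by [calibrateArrhenius()] from a reported value at a
#' reference temperature and an activation enthalpy.
#'
#' @slot delta_h activation enthalpy (kJ/mol)
#' @slot c dimensionless pre-exponential constant
#' @export
setClass("ArrheniusLaw", representation(delta_h = "numeric", c = "numeric"),
         validity = function(object) {
           if (length(object@delta_h) != 1L || !is.finite(object@delta_h))
             return("delta_h must be a single finite number")
           if (length(object@c) != 1L || !is.finite(object@c))
             return("c must be a single finite number")
           TRUE
         })

#' Kinetic parameters of one Rubisco form
#'
#' Holds the measured kinetics of a single enzyme form: the carboxylation
#' turnover rate kcat_C (1/s per active site), the CO2 and O2 half-saturation
#' concentrations K_C and K_O (micromolar), and the dimensionless CO2/O2
#' specificity factor S_C/O. Each value may carry its own reference
#' temperature (kelvin), because published parameters of the same enzyme are
#' often reported at different assay temperatures. The oxygenation turnover
#' kcat_O is never stored: it is derived from the specificity identity
#' S_C/O = (kcat_C * K_O) / (kcat_O * K_C) via [kcatOFromSpecificity()].
#'
#' @slot form_id enzyme form label, e.g. "II", "IAc", "IAq"
#' @slot kcat_C carboxylation turnover (1/s)
#' @slot K_C CO2 half-saturation (uM)
#' @slot K_O O2 half-saturation (uM)
#' @slot S_CO specificity factor (dimensionless)
#' @slot ref_temp_k named numeric: reference temperature (K) for each of
#'   kcat_C, K_C, K_O, S_CO
#' @export
setClass("KineticParams",
         representation(form_id = "character", kcat_C = "numeric",
                        K_C = "numeric", K_O = "numeric", S_CO = "numeric",
                        ref_temp_k = "numeric"),
         validity = function(object) {
           v <- c(kcat_C = object@kcat_C, K_C = object@K_C,
                  K_O = object@K_O, S_CO = object@S_CO)
           if (any(!is.finite(v)) || any(v <= 0))
             return("kcat_C, K_C, K_O and S_CO must all be strictly positive")
           need <- c("kcat_C", "K_C", "K_O", "S_CO")
           if (!all(need %in% names(object@ref_temp_k)))
             return("ref_temp_k must be named for kcat_C, K_C, K_O, S_CO")
           if (any(object@ref_temp_k[need] <= 0))
             return("reference temperatures must be positive kelvin")
           TRUE
         })

#' Gas and temperature conditions
#'
#' CO2 and O2 concentrations (micromolar, the same unit convention as K_C and
#' K_O) and a temperature in degrees Celsius. Concentration slots are parallel
#' vectors so a set of conditions can be evaluated at once.
#'
#' @slot co2 CO2 concentration(s), uM, >= 0
#' @slot o2 O2 concentration(s), uM, >= 0
#' @slot temp_c temperature, degrees Celsius
#' @export
setClass("GasConditions",
         representation(co2 = "numeric", o2 = "numeric", temp_c = "numeric"),
         validity = function(object) {
           if (length(object@co2) != length(object@o2))
             return("co2 and o2 must have equal length")
           if (any(!is.finite(object@co2)) || any(object@co2 < 0))
             return("co2 concentrations must be finite and non-negative")
           if (any(!is.finite(object@o2)) || any(object@o2 < 0))
             return("o2 concentrations must be finite and non-negative")
           if (length(object@temp_c) != 1L || object@temp_c + 273.15 <= 0)
             return("temp_c must be a single Celsius value above absolute zero")
           TRUE
         })

#' Temperature model for one Rubisco form
#'
#' One [ArrheniusLaw-class] per kinetic parameter (kcat_C, K_C, K_O, kcat_O),
#' calibrated so each law reproduces its reported value at its reference
#' temperature. The specificity factor is not modeled directly: at any
#' temperature it is re-derived from the four scaled parameters.
#'
#' @slot form_id enzyme form label
#' @slot laws named list of ArrheniusLaw, names kcat_C, K_C, K_O, kcat_O
#' @export
setClass("TemperatureModel",
         representation(form_id = "character", laws = "list"),
         validity = function(object) {
           need <- c("kcat_C", "K_C", "K_O", "kcat_O")
           if (!all(need %in% names(object@laws)))
             return(paste("laws must contain:", paste(need, collapse = ", ")))
           ok <- vapply(object@laws[need], function(l) is(l, "ArrheniusLaw"),
                        logical(1))
           if (!all(ok)) return("every law must be an ArrheniusLaw")
           TRUE
         })

#' Phosphoglycolate salvage model
#'
#' The stoichiometric carbon cost of recycling 2-phosphoglycolate produced by
#' the oxygenation reaction. The C2 cycle loses one CO2 for every two 2-PG
#' molecules salvaged, i.e. 0.5 CO2 per oxygenation, which is the default.
#'
#' @slot pathway_name salvage pathway label (default "C2")
#' @slot co2_loss_per_oxygenation CO2 lost per oxygenation event (>= 0)
#' @export
setClass("PGSModel",
         representation(pathway_name = "character",
                        co2_loss_per_oxygenation = "numeric"),
         validity = function(object) {
           r <- object@co2_loss_per_oxygenation
           if (length(r) != 1L || !is.finite(r) || r < 0)
             return("co2_loss_per_oxygenation must be a single number >= 0")
           TRUE
         })

#' Rates at one set of conditions
#'
#' Gross carboxylation rate r_c, oxygenation rate r_o, net carboxylation
#' f_net = r_c - loss_ratio * r_o, and a viability flag (f_net > 0). A net
#' rate of 0 or less means autotrophy cannot occur under those conditions.
#' Slots are parallel vectors matching the conditions evaluated.
#'
#' @slot r_c gross carboxylation rate (C/s)
#' @slot r_o oxygenation rate (O/s)
#' @slot f_net net carboxylation rate (C/s)
#' @slot viable logical, f_net > 0
#' @export
setClass("RateResult",
         representation(r_c = "numeric", r_o = "numeric", f_net = "numeric",
                        viable = "logical"),
         validity = function(object) {
           n <- length(object@r_c)
           if (length(object@r_o) != n || length(object@f_net) != n ||
               length(object@viable) != n)
             return("all slots must have equal length")
           if (any(object@r_c < 0) || any(object@r_o < 0))
             return("gross rates must be non-negative")
           TRUE
         })

#' CO2 x O2 x temperature grid specification
#'
#' @slot co2_values strictly increasing CO2 axis (uM, > 0)
#' @slot o2_values strictly increasing O2 axis (uM, >= 0)
#' @slot temps_c temperatures to evaluate (Celsius)
#' @slot spacing named character, spacing label ("linear"/"log") per axis;
#'   informational, recorded in serialized output
#' @export
setClass("GridSpec",
         representation(co2_values = "numeric", o2_values = "numeric",
                        temps_c = "numeric", spacing = "character"),
         validity = function(object) {
           if (length(object@co2_values) < 1L || length(object@o2_values) < 1L)
             return("grid axes must be non-empty")
           if (any(object@co2_values <= 0))
             return("co2_values must be strictly positive")
           if (any(object@o2_values < 0))
             return("o2_values must be non-negative")
           if (is.unsorted(object@co2_values, strictly = TRUE) ||
               is.unsorted(object@o2_values, strictly = TRUE))
             return("grid axes must be strictly increasing")
           if (length(object@temps_c) < 1L)
             return("at least one temperature is required")
           TRUE
         })

#' Per-cell comparison of two Rubisco forms over a CO2 x O2 grid
#'
#' Matrices are CO2 (rows) by O2 (columns). `diff` is f(form A) - f(form B),
#' positive where form A fixes carbon faster. Viability flags come from the
#' net rate (f_net > 0) regardless of the comparison mode, so the non-viable
#' (gray) region is available even for gross-rate comparisons.
#'
#' @slot spec the [GridSpec-class] used
#' @slot temp_c evaluation temperature (Celsius)
#' @slot form_a,form_b form labels
#' @slot mode "gross" or "net"
#' @slot f_a,f_b compared rate per cell for each form (C/s)
#' @slot diff f_a - f_b per cell
#' @slot viable_a,viable_b logical matrices, net rate > 0
#' @export
setClass("ComparisonGrid",
         representation(spec = "GridSpec", temp_c = "numeric",
                        form_a = "character", form_b = "character",
                        mode = "character", f_a = "matrix", f_b = "matrix",
                        diff = "matrix", viable_a = "matrix",
                        viable_b = "matrix"),
         validity = function(object) {
           d <- c(length(object@spec@co2_values), length(object@spec@o2_values))
           for (nm in c("f_a", "f_b", "diff", "viable_a", "viable_b"))
             if (!identical(dim(slot(object, nm)), as.integer(d)))
               return(sprintf("%s must be a %d x %d matrix", nm, d[1], d[2]))
           if (!object@mode %in% c("gross", "net"))
             return("mode must be 'gross' or 'net'")
           TRUE
         })

#' Mesophilic reference statistics for one Rubisco form
#'
#' Per-index mean, standard error (sample sd / sqrt(n)) and n over the
#' designated mesophilic reference sequences of one form. SE = 0 is allowed
#' and triggers the any-change-is-significant rule in [testIndex()].
#'
#' @slot form_id enzyme form label
#' @slot stats numeric matrix, rows = the ten indices, columns mean/se/n
#' @export
setClass("ReferenceStats",
         representation(form_id = "character", stats = "matrix"),
         validity = function(object) {
           if (!all(c("mean", "se", "n") %in% colnames(object@stats)))
             return("stats needs columns mean, se, n")
           if (!all(thermalIndexNames() %in% rownames(object@stats)))
             return("stats must cover all ten thermal indices")
           if (any(object@stats[, "n"] < 1))
             return("n must be >= 1")
           if (any(object@stats[, "se"] < 0))
             return("standard errors must be >= 0")
           TRUE
         })

#' A protein record ready for thermal-adaptation analysis
#'
#' Form I Rubiscos carry a small subunit; the analysis sequence is the
#' concatenation large-then-small. Form II records are large subunit only.
#'
#' @slot seq_id sequence identifier of the large subunit
#' @slot form enzyme form label
#' @slot genome_label source genome
#' @slot large_seq amino-acid string of the large subunit
#' @slot small_seq amino-acid string of the small subunit ("" if absent)
#' @slot is_reference member of the mesophilic reference set?
#' @export
setClass("ProteinRecord",
         representation(seq_id = "character", form = "character",
                        genome_label = "character", large_seq = "character",
                        small_seq = "character", is_reference = "logical"),
         validity = function(object) {
           if (!nzchar(object@large_seq))
             return("large_seq must be non-empty")
           TRUE
         })

#' Composition profile for the synthetic-sequence generator
#'
#' Twenty amino-acid frequencies (summing to one) plus the per-index shifts
#' already folded in, a sequence length and the shift bookkeeping used for
#' reporting.
#'
#' @slot freqs named numeric(20), sampling frequencies, sum to 1
#' @slot length sequence length in residues (>= 50)
#' @slot shifted_indices names of the indices whose composition was shifted
#' @slot effect_size fractional composition delta applied per index group
#' @export
setClass("CompositionProfile",
         representation(freqs = "numeric", length = "numeric",
                        shifted_indices = "character", effect_size = "numeric"),
         validity = function(object) {
           if (!identical(sort(names(object@freqs)), sort(AA_ALPHABET20)))
             return("freqs must be named with the 20 standard amino acids")
           if (any(object@freqs < 0))
             return("frequencies must be non-negative")
           if (abs(sum(object@freqs) - 1) > 1e-9)
             return("frequencies must sum to 1 (within 1e-9)")
           if (object@length < 50)
             return("length must be >= 50 residues")
           TRUE
         })

setMethod("show", "ArrheniusLaw", function(object) {
  cat(sprintf("ArrheniusLaw: x(T) = exp(%.4f - %.2f/(R*T)), R = %.6f kJ/mol/K\n",
              object@c, object@delta_h, GAS_CONSTANT))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams for form %s\n", object@form_id))
  cat(sprintf("  kcat_C = %.4g 1/s (ref %.2f K)\n",
              object@kcat_C, object@ref_temp_k[["kcat_C"]]))
  cat(sprintf("  K_C = %.4g uM, K_O = %.4g uM, S_C/O = %.4g\n",
              object@K_C, object@K_O, object@S_CO))
  cat(sprintf("  derived kcat_O = %.4g 1/s\n", kcatOFromSpecificity(object)))
})

setMethod("show", "TemperatureModel", function(object) {
  cat(sprintf("TemperatureModel for form %s (laws: %s)\n", object@form_id,
              paste(names(object@laws), collapse = ", ")))
})

setMethod("show", "ComparisonGrid", function(object) {
  cat(sprintf(
    "ComparisonGrid %s - %s (%s rates) at %.1f degC: %d x %d cells\n",
    object@form_a, object@form_b, object@mode, object@temp_c,
    nrow(object@diff), ncol(object@diff)))
  cat(sprintf("  diff range [%.4g, %.4g] C/s; both non-viable in %d cells\n",
              min(object@diff), max(object@diff),
              sum(!object@viable_a & !object@viable_b)))
})

setMethod("show", "ReferenceStats", function(object) {
  cat(sprintf("ReferenceStats for form %s (n = %d)\n", object@form_id,
              as.integer(object@stats[1, "n"])))
  print(round(object@stats, 4))
})

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord %s (form %s, genome %s): large %d aa%s%s\n",
              object@seq_id, object@form, object@genome_label,
              nchar(object@large_seq),
              if (nzchar(object@small_seq))
                sprintf(" + small %d aa", nchar(object@small_seq)) else "",
              if (object@is_reference) " [reference]" else ""))
})
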