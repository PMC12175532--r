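#' Read a kinetic parameter table
#'
#' TSV with columns form_id, parameter, value, unit, ref_temp_c,
#' delta_h_kj_mol and source. Parameters kcat_C, K_C, K_O and S_CO carry
#' measured values; a kcat_O row carries only the activation enthalpy (its
#' value is always derived from the specificity identity, never read).
#' Units: 1/s (or s-1, per_s) for turnovers; uM or mM for half-saturations
#' (mM is converted to uM); dimensionless for S_CO. Forms IAc and IAq fall
#' back to enthalpies configured under form_id "IA" when their own rows have
#' no delta_h, mirroring literature enthalpies reported only at the form-IA
#' level.
#'
#' @param path TSV path
#' @return named list, one entry per form, each with elements `params`
#'   ([KineticParams-class]) and `model` ([TemperatureModel-class])
#' @export
readKineticTable <- function(path) {
  if (!file.exists(path)) stop("kinetic parameter file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("form_id", "parameter", "value", "unit", "ref_temp_c",
            "delta_h_kj_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("kinetic table is missing column(s): ", paste(miss, collapse = ", "))
  tab$value <- convertUnits(tab$value, tab$unit, tab$parameter)
  forms <- setdiff(unique(tab$form_id), "IA")
  ia <- tab[tab$form_id == "IA", , drop = FALSE]
  out <- list()
  for (f in forms) {
    rows <- tab[tab$form_id == f, , drop = FALSE]
    getRow <- function(p) {
      r <- rows[rows$parameter == p, , drop = FALSE]
      if (nrow(r) > 1L) stop("duplicate ", p, " rows for form ", f)
      r
    }
    vals <- temps <- stats::setNames(numeric(4), c("kcat_C", "K_C", "K_O", "S_CO"))
    for (p in names(vals)) {
      r <- getRow(p)
      if (nrow(r) == 0L || is.na(r$value))
        stop("form ", f, " is missing a value for ", p)
      vals[[p]] <- r$value; temps[[p]] <- r$ref_temp_c
    }
    dh <- stats::setNames(numeric(4), c("kcat_C", "K_C", "K_O", "kcat_O"))
    for (p in names(dh)) {
      r <- getRow(p)
      v <- if (nrow(r)) r$delta_h_kj_mol else NA_real_
      if (is.na(v) && f %in% c("IAc", "IAq")) {
        r_ia <- ia[ia$parameter == p, , drop = FALSE]
        if (nrow(r_ia)) v <- r_ia$delta_h_kj_mol[1]
      }
      if (is.na(v))
        stop("no activation enthalpy for ", p, " of form ", f,
             " (and no form-IA fallback row)")
      dh[[p]] <- v
    }
    params <- kineticParams(f, kcat_C = vals[["kcat_C"]], K_C = vals[["K_C"]],
                            K_O = vals[["K_O"]], S_CO = vals[["S_CO"]],
                            ref_temp_c = temps)
    out[[f]] <- list(params = params,
                     model = buildTemperatureModel(params, dh))
  }
  out
}

convertUnits <- function(value, unit, parameter) {
  out <- value
  for (i in seq_along(value)) {
    if (is.na(value[i])) next
    u <- tolower(unit[i])
    if (u %in% c("mm")) out[i] <- value[i] * 1000
    else if (u %in% c("um", "µm", "1/s", "s-1", "per_s",
                      "dimensionless", "")) out[i] <- value[i]
    else stop("unrecognized unit '", unit[i], "' for ", parameter[i])
  }
  out
}

#' Read a phosphoglycolate-salvage config
#'
#' YAML with keys `pathway` (label) and `co2_loss_per_oxygenation` (ratio);
#' either may be omitted, defaulting to the C2 cycle (ratio 0.5).
#'
#' @param path YAML path
#' @return a [PGSModel-class]
#' @export
readPGSConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pgsModel(pathway_name = cfg$pathway %||% "C2",
           co2_loss_per_oxygenation = cfg$co2_loss_per_oxygenation %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
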