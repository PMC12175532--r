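#' Construct a CO2 x O2 x temperature grid specification
#'
#' @param co2_values strictly increasing CO2 axis (uM, > 0)
#' @param o2_values strictly increasing O2 axis (uM, >= 0)
#' @param temps_c temperatures, Celsius (default 0 and 25)
#' @param spacing character of length 2, spacing labels for the CO2 and O2
#'   axes (recorded in serialized output)
#' @export
gridSpec <- function(co2_values, o2_values, temps_c = c(0, 25),
                     spacing = c(co2 = "log", o2 = "linear")) {
  new("GridSpec", co2_values = as.numeric(co2_values),
      o2_values = as.numeric(o2_values), temps_c = as.numeric(temps_c),
      spacing = spacing)
}

#' Default comparison grid
#'
#' CO2 log-spaced from 0.1 to 10000 uM (64 points) to span the low-CO2
#' break-even region up to the millimolar concentrations reported for the
#' habitats of interest; O2 linear from 0 to 500 uM (64 points), covering the
#' 0-0.6 mM habitat range.
#'
#' @inheritParams gridSpec
#' @param n points per axis
#' @export
defaultGridSpec <- function(temps_c = c(0, 25), n = 64) {
  gridSpec(co2_values = 10^seq(log10(0.1), log10(10000), length.out = n),
           o2_values = seq(0, 500, length.out = n), temps_c = temps_c)
}

#' Compare two Rubisco forms over a CO2 x O2 grid
#'
#' Evaluates both temperature models at `temp_c`, computes per-cell rates
#' (gross carboxylation R_C, or net carboxylation f under phosphoglycolate
#' salvage) and their difference form A minus form B. Viability flags always
#' come from the net rate, so the region where both forms lose carbon is
#' available in either mode.
#'
#' @param model_a,model_b [TemperatureModel-class] objects for the two forms
#' @param spec a [GridSpec-class]
#' @param temp_c evaluation temperature, Celsius
#' @param pgs a [PGSModel-class]
#' @param mode "net" (default) or "gross"
#' @return a [ComparisonGrid-class] with CO2 as rows and O2 as columns
#' @export
compareForms <- function(model_a, model_b, spec, temp_c,
                         pgs = pgsModel(), mode = c("net", "gross")) {
  mode <- match.arg(mode)
  stopifnot(is(model_a, "TemperatureModel"), is(model_b, "TemperatureModel"),
            is(spec, "GridSpec"))
  validObject(spec)
  pa <- paramsAtTemperature(model_a, temp_c)
  pb <- paramsAtTemperature(model_b, temp_c)
  cells <- expand.grid(co2 = spec@co2_values, o2 = spec@o2_values)
  cond <- gasConditions(cells$co2, cells$o2, temp_c)
  ra <- netCarboxylation(pa, cond, pgs)
  rb <- netCarboxylation(pb, cond, pgs)
  dims <- c(length(spec@co2_values), length(spec@o2_values))
  shape <- function(x) matrix(x, nrow = dims[1], ncol = dims[2])
  f_a <- shape(if (mode == "gross") ra@r_c else ra@f_net)
  f_b <- shape(if (mode == "gross") rb@r_c else rb@f_net)
  new("ComparisonGrid", spec = spec, temp_c = as.numeric(temp_c),
      form_a = model_a@form_id, form_b = model_b@form_id, mode = mode,
      f_a = f_a, f_b = f_b, diff = f_a - f_b,
      viable_a = shape(ra@viable), viable_b = shape(rb@viable))
}

#' Largest absolute rate difference on a grid
#'
#' Returns the maximum of |f_A - f_B| over all cells and one cell attaining
#' it; ties go to the lowest CO2, then the lowest O2.
#'
#' @param grid a [ComparisonGrid-class]
#' @return list with `value` (C/s), `co2`, `o2` (uM) and the cell indices
#' @export
maxAbsDifference <- function(grid) {
  stopifnot(is(grid, "ComparisonGrid"))
  a <- abs(grid@diff)
  m <- max(a)
  hits <- which(a == m, arr.ind = TRUE)
  # row index = CO2, column = O2; order() on (co2, o2) gives the tie-break
  pick <- hits[order(hits[, 1], hits[, 2])[1], , drop = TRUE]
  list(value = m,
       co2 = grid@spec@co2_values[pick[["row"]]],
       o2 = grid@spec@o2_values[pick[["col"]]],
       i_co2 = unname(pick[["row"]]), i_o2 = unname(pick[["col"]]))
}

#' Region where neither form can sustain autotrophy
#'
#' Cell mask that is TRUE exactly where the net carboxylation rate is <= 0
#' for both forms (the gray region of the comparison plots). Only defined for
#' grids computed in net mode.
#'
#' @param grid a [ComparisonGrid-class] with mode "net"
#' @return logical matrix, CO2 rows x O2 columns
#' @export
nonviableRegion <- function(grid) {
  stopifnot(is(grid, "ComparisonGrid"))
  if (grid@mode != "net")
    stop("nonviableRegion requires a grid computed with mode = 'net'")
  !grid@viable_a & !grid@viable_b
}

#' Write a comparison grid as long-format TSV plus a JSON sidecar
#'
#' One row per cell (co2_um, o2_um, temp_c, f_a, f_b, diff, viable_a,
#' viable_b) and `<path>.json` holding the grid metadata. Serialization is
#' deterministic: re-reading with [readComparisonGrid()] reproduces the grid.
#'
#' @param grid a [ComparisonGrid-class]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeComparisonGrid <- function(grid, path) {
  stopifnot(is(grid, "ComparisonGrid"))
  cells <- expand.grid(co2_um = grid@spec@co2_values,
                       o2_um = grid@spec@o2_values)
  df <- data.frame(co2_um = sprintf("%.10g", cells$co2_um),
                   o2_um = sprintf("%.10g", cells$o2_um),
                   temp_c = sprintf("%.10g", grid@temp_c),
                   f_a = sprintf("%.10g", as.vector(grid@f_a)),
                   f_b = sprintf("%.10g", as.vector(grid@f_b)),
                   diff = sprintf("%.10g", as.vector(grid@diff)),
                   viable_a = as.integer(grid@viable_a),
                   viable_b = as.integer(grid@viable_b))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(form_a = grid@form_a, form_b = grid@form_b, mode = grid@mode,
               temp_c = grid@temp_c, spacing = as.list(grid@spec@spacing),
               n_co2 = length(grid@spec@co2_values),
               n_o2 = length(grid@spec@o2_values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a comparison grid written by [writeComparisonGrid()]
#'
#' @param path TSV path (expects `<path>.json` alongside)
#' @return a [ComparisonGrid-class]
#' @export
readComparisonGrid <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  co2 <- unique(df$co2_um); o2 <- unique(df$o2_um)
  spec <- gridSpec(co2, o2, temps_c = meta$temp_c,
                   spacing = unlist(meta$spacing))
  shape <- function(x) matrix(x, nrow = length(co2), ncol = length(o2))
  new("ComparisonGrid", spec = spec, temp_c = meta$temp_c,
      form_a = meta$form_a, form_b = meta$form_b, mode = meta$mode,
      f_a = shape(df$f_a), f_b = shape(df$f_b), diff = shape(df$diff),
      viable_a = shape(df$viable_a == 1L), viable_b = shape(df$viable_b == 1L))
}
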