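## Residue groups through which each index's composition shift is realized,
## and the direction (sign of the frequency delta) that makes a sequence
## colder under the default direction table.
INDEX_SHIFT_GROUPS <- list(
  n_gly = list(residues = "G", cold_sign = +1),
  n_pro = list(residues = "P", cold_sign = -1),
  n_ser = list(residues = "S", cold_sign = +1),
  n_acidic = list(residues = c("D", "E"), cold_sign = +1),
  n_charged = list(residues = c("K", "R", "H"), cold_sign = -1),
  n_polar_uncharged = list(residues = c("N", "Q", "T"), cold_sign = +1),
  aliphatic_index = list(residues = c("V", "I", "L"), cold_sign = -1),
  aromaticity = list(residues = c("F", "W"), cold_sign = -1),
  gravy = list(residues = c("A", "M"), cold_sign = -1),
  isoelectric_point = list(residues = c("K", "R"), cold_sign = -1))

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Baseline amino-acid composition
#'
#' Frequencies computed from the bundled synthetic mesophilic form II
#' Rubisco-like fixture (a fixed 460-residue sequence with a typical
#' bacterial Rubisco composition). Pass any protein FASTA to use a different
#' baseline.
#'
#' @param path protein FASTA; defaults to the bundled fixture
#' @return named numeric(20), frequencies summing to 1
#' @export
baselineComposition <- function(path = system.file(
    "extdata", "synthetic_form2_baseline.faa", package = "RubiscoTherm")) {
  seqs <- readProteinFasta(path)
  chars <- strsplit(paste(as.character(seqs), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET20))
  stats::setNames(as.numeric(counts) / sum(counts), AA_ALPHABET20)
}

#' Build a composition profile with controlled index shifts
#'
#' Starting from the baseline frequencies, shifts total probability mass
#' `effect_size` into or out of each shifted index's defining residue group
#' (into, for indices whose cold direction is "higher"; out, for "lower"
#' when `direction = "cold"`, and the reverse for "hot"). Within a group the
#' delta is split proportionally to the baseline frequencies; the result is
#' renormalized to sum to one.
#'
#' @param baseline named numeric(20) of frequencies (see
#'   [baselineComposition()])
#' @param shift_indices indices to shift (subset of [thermalIndexNames()]);
#'   default none
#' @param effect_size absolute composition mass moved per index group
#' @param direction "cold" or "hot"
#' @param length sequence length in residues
#' @return a [CompositionProfile-class]
#' @export
compositionProfile <- function(baseline = baselineComposition(),
                               shift_indices = character(),
                               effect_size = 0, direction = c("cold", "hot"),
                               length = 460) {
  direction <- match.arg(direction)
  bad <- setdiff(shift_indices, names(INDEX_SHIFT_GROUPS))
  if (length(bad))
    stop("unknown index name(s): ", paste(bad, collapse = ", "))
  freqs <- baseline[AA_ALPHABET20]
  for (idx in shift_indices) {
    grp <- INDEX_SHIFT_GROUPS[[idx]]
    sign <- grp$cold_sign * if (direction == "cold") 1 else -1
    w <- freqs[grp$residues] / sum(freqs[grp$residues])
    freqs[grp$residues] <- freqs[grp$residues] + sign * effect_size * w
  }
  if (any(freqs < 0))
    stop("shift drives a residue frequency negative; reduce effect_size")
  freqs <- freqs / sum(freqs)
  new("CompositionProfile", freqs = freqs, length = as.numeric(length),
      shifted_indices = as.character(shift_indices),
      effect_size = as.numeric(effect_size))
}

#' Draw a protein sequence from a composition profile
#'
#' Residues are drawn independently (multinomial sampling) from the profile
#' frequencies; the same seed always yields the same sequence.
#'
#' @param profile a [CompositionProfile-class]
#' @param seed integer seed
#' @return amino-acid string of the profile's length
#' @export
generateSequence <- function(profile, seed) {
  stopifnot(is(profile, "CompositionProfile"))
  validObject(profile)
  withSeed(seed, paste(sample(AA_ALPHABET20, profile@length, replace = TRUE,
                              prob = profile@freqs), collapse = ""))
}

#' Generate a synthetic scoring cohort
#'
#' Draws a mesophilic reference set and neutral test sequences from the
#' baseline composition, and cold-shifted test sequences from a profile with
#' all ten index groups shifted in the cold direction at `effect_size`.
#' Returns (and optionally writes) FASTA, a metadata table consumable by the
#' scoring pipeline unchanged, and the expected labels for recovery testing.
#'
#' @param n_cold,n_neutral numbers of cold-shifted and baseline test
#'   sequences
#' @param ref_n reference-set size (>= 2)
#' @param effect_size composition mass moved per index group for the cold
#'   sequences (default 0.03, i.e. 3% of residues per group at the default
#'   length)
#' @param length sequence length (residues)
#' @param seed integer seed; every sequence derives its own stream from it
#' @param baseline baseline frequencies
#' @param shift_indices indices shifted in the cold sequences (default all
#'   ten)
#' @param out_dir if non-NULL, writes cohort.faa, metadata.tsv and
#'   expected_labels.tsv there
#' @return list with `fasta` (named character), `metadata` (data.frame),
#'   `expected` (data.frame seq_id, expected_class)
#' @export
generateCohort <- function(n_cold = 10, n_neutral = 10, ref_n = 5,
                           effect_size = 0.03, length = 460, seed = 1,
                           baseline = baselineComposition(),
                           shift_indices = thermalIndexNames(),
                           out_dir = NULL) {
  if (ref_n < 2) stop("ref_n must be >= 2")
  base_prof <- compositionProfile(baseline, length = length)
  cold_prof <- compositionProfile(baseline, shift_indices = shift_indices,
                                  effect_size = effect_size,
                                  direction = "cold", length = length)
  ids <- c(sprintf("ref_%02d", seq_len(ref_n)),
           sprintf("neutral_%02d", seq_len(n_neutral)),
           sprintf("cold_%02d", seq_len(n_cold)))
  profs <- c(rep(list(base_prof), ref_n + n_neutral),
             rep(list(cold_prof), n_cold))
  seqs <- stats::setNames(vapply(seq_along(ids), function(i)
    generateSequence(profs[[i]], seed = seed * 10000L + i), character(1)), ids)
  metadata <- data.frame(
    seq_id = ids, form = "II", subunit = "large",
    is_reference = as.integer(grepl("^ref_", ids)),
    genome_label = ids, stringsAsFactors = FALSE)
  expected <- data.frame(
    seq_id = ids[!grepl("^ref_", ids)],
    expected_class = ifelse(grepl("^cold_", ids[!grepl("^ref_", ids)]) &
                              effect_size > 0, "cold", "neutral"),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeProteinFasta(seqs, file.path(out_dir, "cohort.faa"))
    utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expected, file.path(out_dir, "expected_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fasta = seqs, metadata = metadata, expected = expected)
}

#' Generate a random valid kinetic parameter set and temperature model
#'
#' Parameters are drawn log-uniformly from field-plausible ranges:
#' kcat_C in \[0.5, 15\] 1/s, K_C in \[5, 300\] uM, K_O in \[100, 2000\] uM,
#' S_C/O in \[5, 100\], activation enthalpies in \[10, 90\] kJ/mol. The
#' draws always satisfy the kinetic parameter invariants.
#'
#' @param seed integer seed
#' @param form_id label for the generated form
#' @return list with `params` ([KineticParams-class]) and `model`
#'   ([TemperatureModel-class])
#' @export
generateKinetics <- function(seed, form_id = "synthetic") {
  withSeed(seed, {
    logu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
    params <- kineticParams(form_id,
                            kcat_C = logu(0.5, 15), K_C = logu(5, 300),
                            K_O = logu(100, 2000), S_CO = logu(5, 100),
                            ref_temp_c = 25)
    dh <- stats::setNames(exp(stats::runif(4, log(10), log(90))),
                          c("kcat_C", "K_C", "K_O", "kcat_O"))
    list(params = params, model = buildTemperatureModel(params, dh))
  })
}
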