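#' Default cold/hot direction table
#'
#' For each index, which side of the mesophilic mean counts as cold-adapted
#' ("higher" or "lower"). The defaults are the conventional psychrophile
#' signatures: more glycine, serine, acidic and polar uncharged residues;
#' fewer prolines, charged residues and aromatics; lower aliphatic index,
#' hydropathy and isoelectric point. The table is a package default and can
#' be replaced via a YAML config ([readDirectionTable()]).
#'
#' @return named character vector over [thermalIndexNames()], values
#'   "higher"/"lower"
#' @export
defaultDirections <- function() {
  c(n_gly = "higher", n_pro = "lower", n_ser = "higher",
    n_acidic = "higher", n_charged = "lower",
    n_polar_uncharged = "higher", aliphatic_index = "lower",
    aromaticity = "lower", gravy = "lower", isoelectric_point = "lower")
}

#' Read a direction table from a YAML file
#'
#' The file maps each of the ten index names to "higher" or "lower" (the
#' deviation direction that scores cold, +1).
#'
#' @param path YAML file path
#' @return named character vector as in [defaultDirections()]
#' @export
readDirectionTable <- function(path) {
  d <- unlist(yaml::read_yaml(path))
  validateDirections(d)
  d[thermalIndexNames()]
}

validateDirections <- function(directions) {
  miss <- setdiff(thermalIndexNames(), names(directions))
  if (length(miss))
    stop("direction table is missing indices: ", paste(miss, collapse = ", "))
  if (!all(directions[thermalIndexNames()] %in% c("higher", "lower")))
    stop("directions must be 'higher' or 'lower'")
  invisible(TRUE)
}

#' Build mesophilic reference statistics from index vectors
#'
#' Per index: arithmetic mean, standard error (sample standard deviation with
#' n-1 denominator divided by sqrt(n)) and n. With a single vector the SE is
#' 0 by convention and a warning is raised, because the t-test is undefined
#' and the SE = 0 any-change-is-significant rule will apply.
#'
#' @param vectors list of index vectors from [computeIndices()]
#' @param form_id enzyme form the reference describes
#' @return a [ReferenceStats-class]
#' @export
buildReference <- function(vectors, form_id) {
  if (length(vectors) < 1L) stop("at least one index vector is required")
  m <- do.call(rbind, vectors)
  if (!all(thermalIndexNames() %in% colnames(m)))
    stop("index vectors must cover all ten indices")
  m <- m[, thermalIndexNames(), drop = FALSE]
  n <- nrow(m)
  if (n == 1L) {
    warning("reference built from a single sequence: SE = 0, the ",
            "any-change-is-significant rule will apply to every index")
    se <- rep(0, ncol(m))
  } else {
    se <- apply(m, 2, stats::sd) / sqrt(n)
  }
  stats <- cbind(mean = colMeans(m), se = se, n = n)
  rownames(stats) <- thermalIndexNames()
  new("ReferenceStats", form_id = as.character(form_id), stats = stats)
}

#' One-sample t-test of an index value against a reference
#'
#' t = (ref mean - value) / SE with df = n - 1 and a two-sided p-value;
#' significant when p < alpha, with the direction given by the sign of
#' (value - mean). When SE = 0 the p-value is undefined and any deviation
#' from the mean is treated as significant; an exact match is not.
#'
#' @param value observed index value of the test sequence
#' @param ref_mean,ref_se,ref_n per-index reference statistics
#' @param alpha significance level in (0, 1)
#' @return one of "significant_higher", "significant_lower",
#'   "not_significant"
#' @export
testIndex <- function(value, ref_mean, ref_se, ref_n, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (ref_se < 0) stop("standard error must be >= 0")
  if (ref_se == 0) {
    if (value == ref_mean) return("not_significant")
    return(if (value > ref_mean) "significant_higher" else "significant_lower")
  }
  if (ref_n < 2) stop("n >= 2 required for a t-test with SE > 0")
  tstat <- (ref_mean - value) / ref_se
  p <- 2 * stats::pt(-abs(tstat), df = ref_n - 1)
  if (p >= alpha) return("not_significant")
  if (value > ref_mean) "significant_higher" else "significant_lower"
}

#' Score one sequence's indices against a mesophilic reference
#'
#' Each index significantly deviating in its cold direction scores +1, in the
#' hot direction -1, otherwise 0. The total over the ten indices classifies
#' the sequence: >= 3 cold, <= -3 hot, between -2 and 2 neutral.
#'
#' @param vector index vector from [computeIndices()]
#' @param ref a [ReferenceStats-class]
#' @param directions direction table, see [defaultDirections()]
#' @param alpha significance level
#' @return list with `scores` (named -1/0/+1 per index), `total` and
#'   `classification` ("cold"/"hot"/"neutral")
#' @export
scoreSequence <- function(vector, ref, directions = defaultDirections(),
                          alpha = 0.05) {
  stopifnot(is(ref, "ReferenceStats"))
  validateDirections(directions)
  idx <- thermalIndexNames()
  if (!all(idx %in% names(vector)))
    stop("index vector must cover all ten indices")
  scores <- stats::setNames(integer(length(idx)), idx)
  for (i in idx) {
    res <- testIndex(vector[[i]], ref@stats[i, "mean"], ref@stats[i, "se"],
                     ref@stats[i, "n"], alpha)
    if (res == "not_significant") next
    observed <- if (res == "significant_higher") "higher" else "lower"
    scores[[i]] <- if (observed == directions[[i]]) 1L else -1L
  }
  total <- sum(scores)
  list(scores = scores, total = total,
       classification = classifyTotal(total))
}

#' Classify a total adaptation score
#'
#' @param total integer in \[-10, 10\]
#' @return "cold" (total >= 3), "hot" (total <= -3) or "neutral"
#' @export
classifyTotal <- function(total) {
  ifelse(total >= 3, "cold", ifelse(total <= -3, "hot", "neutral"))
}

#' Score a cohort of protein records
#'
#' Computes indices for every record's analysis sequence (large subunit plus
#' small subunit for form I), scores each against the per-form reference and
#' summarises the cohort. Records flagged as reference-set members are
#' excluded unless `include_reference = TRUE`. Records whose form has no
#' reference are skipped with a warning.
#'
#' @param records list of [ProteinRecord-class] (see [assembleRecords()])
#' @param refs named list of [ReferenceStats-class], one per form
#' @param directions direction table
#' @param alpha significance level
#' @param include_reference score the reference-set members too?
#' @return list with `scores` (data.frame: seq_id, form, the ten index
#'   values, ten per-index scores, total, classification), `summary` (counts
#'   per class, n_skipped, and the median total among cold-inferred
#'   sequences, where the median of an even count is the mean of the middle
#'   two)
#' @export
scoreCohort <- function(records, refs, directions = defaultDirections(),
                        alpha = 0.05, include_reference = FALSE) {
  validateDirections(directions)
  rows <- list(); n_skipped <- 0L
  for (rec in records) {
    if (rec@is_reference && !include_reference) next
    if (is.null(refs[[rec@form]])) {
      warning("no reference for form '", rec@form, "'; skipping ",
              rec@seq_id)
      n_skipped <- n_skipped + 1L
      next
    }
    vec <- computeIndices(analysisSequence(rec))
    sc <- scoreSequence(vec, refs[[rec@form]], directions, alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = rec@seq_id, form = rec@form, t(vec),
      t(stats::setNames(sc$scores, paste0("score_", names(sc$scores)))),
      total = sc$total, classification = sc$classification,
      stringsAsFactors = FALSE)
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), form = character(),
               total = integer(), classification = character())
  counts <- c(cold = sum(scores$classification == "cold"),
              hot = sum(scores$classification == "hot"),
              neutral = sum(scores$classification == "neutral"))
  cold_totals <- scores$total[scores$classification == "cold"]
  list(scores = scores,
       summary = list(n_scored = nrow(scores), counts = as.list(counts),
                      n_skipped = n_skipped,
                      median_cold_total = if (length(cold_totals))
                        stats::median(cold_totals) else NA_real_))
}

#' Write cohort scores as TSV plus a JSON summary
#'
#' @param result output of [scoreCohort()]
#' @param path per-sequence TSV path; the summary goes to `<path>.json`
#' @return `path`, invisibly
#' @export
writeScores <- function(result, path) {
  utils::write.table(result$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(result$summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
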