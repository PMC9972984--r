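# Somatic variant prioritization: quality -> population allele frequency ->
# functional consequence -> germline subtraction -> novelty classification,
# with a per-stage survivor trace. All numeric thresholds are strict
# ("above Q30", "more than 5%"): boundary values survive.

#' Prioritization filter configuration
#'
#' @param min_quality Phred-scaled call quality; calls with quality strictly
#'   greater survive. Default 30.
#' @param max_pop_af maximum tolerated population allele frequency across the
#'   configured databases; strictly greater is removed. Default 0.05.
#' @param af_databases allele-frequency columns consulted; a call absent
#'   from all of them is retained. Default the three population databases.
#' @param keep_regions genomic regions retained. Default exonic + splicing.
#' @param drop_effects consequence classes removed. Default synonymous and
#'   unclassified ("other") calls, i.e. changes without an amino-acid
#'   consequence.
#' @param novel_min_normal_depth,novel_max_normal_alt matched-normal
#'   coverage required before an uncatalogued variant may be called novel:
#'   at least this many reads with at most this many variant reads.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_quality = 30, max_pop_af = 0.05,
                          af_databases = AF_COLUMNS,
                          keep_regions = c("exonic", "splicing"),
                          drop_effects = c("synonymous", "other"),
                          novel_min_normal_depth = 10L,
                          novel_max_normal_alt = 0L) {
  stopifnot(is.numeric(min_quality), length(min_quality) == 1L,
            is.numeric(max_pop_af), max_pop_af >= 0, max_pop_af <= 1,
            all(keep_regions %in% VARIANT_REGIONS),
            all(drop_effects %in% VARIANT_EFFECTS),
            novel_min_normal_depth >= 0L, novel_max_normal_alt >= 0L)
  structure(list(min_quality = min_quality, max_pop_af = max_pop_af,
                 af_databases = af_databases, keep_regions = keep_regions,
                 drop_effects = drop_effects,
                 novel_min_normal_depth = as.integer(novel_min_normal_depth),
                 novel_max_normal_alt = as.integer(novel_max_normal_alt)),
            class = "filter_config")
}

#' Quality filter
#'
#' Retains calls whose Phred-scaled quality is strictly above
#' `config$min_quality`.
#'
#' @param calls a [variant_calls()] data.frame.
#' @param config a [filter_config()].
#' @return the surviving calls.
#' @export
filter_quality <- function(calls, config = filter_config()) {
  if (any(is.na(calls$quality))) {
    stop("validation error: quality is absent on ", sum(is.na(calls$quality)),
         " call(s); the quality filter requires it on every call")
  }
  calls[calls$quality > config$min_quality, , drop = FALSE]
}

#' Population allele-frequency filter
#'
#' Removes a call iff its maximum allele frequency over the configured
#' population databases (ignoring databases where it is absent) is strictly
#' above `config$max_pop_af`. Calls absent from every database are retained:
#' the filter removes known-common variants, and absence is not evidence of
#' commonness.
#'
#' @inheritParams filter_quality
#' @return the surviving calls.
#' @export
filter_population_af <- function(calls, config = filter_config()) {
  for (db in config$af_databases) {
    v <- calls[[db]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("validation error: ", db, " outside [0, 1]")
    }
  }
  af <- max_pop_af(calls, config$af_databases)
  calls[is.na(af) | af <= config$max_pop_af, , drop = FALSE]
}

#' Functional-consequence filter
#'
#' Retains calls in a kept region (`keep_regions`), annotated to a gene, and
#' whose consequence class is not in `drop_effects` — i.e. removes
#' non-exonic/non-splicing calls, calls in unannotated genes, and changes
#' without an amino-acid consequence.
#'
#' @inheritParams filter_quality
#' @return the surviving calls.
#' @export
filter_functional <- function(calls, config = filter_config()) {
  keep <- calls$region %in% config$keep_regions &
    !is.na(calls$gene) & calls$gene != "" &
    !calls$effect %in% config$drop_effects
  calls[keep, , drop = FALSE]
}

#' Germline subtraction
#'
#' Removes tumour calls whose genomic change (chrom, pos, ref, alt) is also
#' present in the matched normal call set. For a single tumour/normal pair
#' (no shared sample identifiers between the two tables) matching is on the
#' genomic change alone; when the tables share sample identifiers — as in
#' a multi-sample cohort keyed by patient — matching is per sample, so one
#' patient's germline variant never subtracts another patient's somatic
#' call.
#'
#' @param tumour_calls,normal_calls [variant_calls()] belonging to the same
#'   patient pair (or the same per-sample-keyed cohort). Pairing is checked
#'   via an optional `patient_id` column when both sides carry one.
#' @return the surviving tumour calls.
#' @export
subtract_germline <- function(tumour_calls, normal_calls) {
  if ("patient_id" %in% names(tumour_calls) &&
      "patient_id" %in% names(normal_calls)) {
    tp <- unique(tumour_calls$patient_id); np <- unique(normal_calls$patient_id)
    if (length(tp) && length(np) && !setequal(tp, np)) {
      stop("validation error: tumour and normal call sets belong to ",
           "different patients: ", paste(tp, collapse = ","), " vs ",
           paste(np, collapse = ","))
    }
  }
  if (nrow(tumour_calls) == 0L || nrow(normal_calls) == 0L) {
    return(tumour_calls)
  }
  per_sample <- length(intersect(unique(tumour_calls$sample_id),
                                 unique(normal_calls$sample_id))) > 0L
  tkey <- variant_key(tumour_calls)
  nkey <- variant_key(normal_calls)
  if (per_sample) {
    tkey <- paste(tumour_calls$sample_id, tkey, sep = "|")
    nkey <- paste(normal_calls$sample_id, nkey, sep = "|")
  }
  tumour_calls[!tkey %in% unique(nkey), , drop = FALSE]
}

#' Novelty classification
#'
#' Flags a call `novel` iff it is absent from both known-variant catalogs
#' (no dbSNP and no COSMIC identifier) and the matched normal provides
#' confident wild-type evidence: at least `novel_min_normal_depth` reads
#' covering the position with at most `novel_max_normal_alt` variant reads.
#' All other calls are flagged `known`. This is a flag, not a removal.
#'
#' @inheritParams filter_quality
#' @return `calls` with an added logical column `novel`.
#' @export
classify_novel <- function(calls, config = filter_config()) {
  uncatalogued <- is.na(calls$dbsnp_id) & is.na(calls$cosmic_id)
  covered <- !is.na(calls$normal_depth) & !is.na(calls$normal_alt) &
    calls$normal_depth >= config$novel_min_normal_depth &
    calls$normal_alt <= config$novel_max_normal_alt
  calls$novel <- uncatalogued & covered
  calls
}

#' Run the full prioritization chain
#'
#' Applies quality, population allele frequency, functional-consequence and
#' germline-subtraction filtering in that fixed order, then flags novelty,
#' recording input and survivor counts per stage. The four removal stages
#' are pure predicates on independent fields, so the surviving set is
#' invariant under their ordering; the trace reflects the order run.
#'
#' @param tumour_calls,normal_calls [variant_calls()] (multi-sample tables
#'   are fine; germline subtraction is keyed per sample).
#' @param config a [filter_config()].
#' @return list with `calls` (survivors, novelty-flagged, sorted by sample,
#'   chrom, pos, alt) and `trace` (data.frame stage/in/out/removed).
#' @export
run_prioritization <- function(tumour_calls, normal_calls = NULL,
                               config = filter_config()) {
  if (is.null(normal_calls)) {
    normal_calls <- tumour_calls[0, , drop = FALSE]
  }
  stages <- list(
    quality = function(x) filter_quality(x, config),
    population_af = function(x) filter_population_af(x, config),
    functional = function(x) filter_functional(x, config),
    germline_subtraction = function(x) subtract_germline(x, normal_calls),
    novelty = function(x) classify_novel(x, config))
  trace <- data.frame(stage = names(stages),
                      `in` = NA_integer_, out = NA_integer_,
                      removed = NA_integer_, check.names = FALSE)
  calls <- tumour_calls
  for (i in seq_along(stages)) {
    n_in <- nrow(calls)
    calls <- stages[[i]](calls)
    trace$`in`[i] <- n_in
    trace$out[i] <- nrow(calls)
    trace$removed[i] <- n_in - nrow(calls)
  }
  ord <- order(calls$sample_id, calls$chrom, calls$pos, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, trace = trace)
}
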