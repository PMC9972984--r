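# Cohort landscape summaries: per-sample mutational burden and
# hypermutation status, MSI-group statistics, consequence-class
# distributions, recurrence, gene frequencies and pathogenic accounting.

#' Somatic mutation rate per megabase
#'
#' @param somatic_count number of somatic variants.
#' @param callable_mb callable genome size in megabases (the rate
#'   denominator; positive).
#' @return mutations per Mb.
#' @export
#' @examples
#' mutation_rate(120, 10)  # 12
mutation_rate <- function(somatic_count, callable_mb) {
  if (any(!is.finite(callable_mb)) || any(callable_mb <= 0)) {
    stop("callable_mb must be positive")
  }
  somatic_count / callable_mb
}

#' Hypermutation classification
#'
#' A sample is hypermutated iff its mutation rate is strictly above the
#' threshold (default 12 mutations/Mb); a rate exactly at the threshold is
#' not hypermutated.
#'
#' @param rate mutations per Mb (non-negative).
#' @param threshold rate threshold, default 12.
#' @return logical.
#' @export
classify_hypermutated <- function(rate, threshold = 12) {
  stopifnot(all(rate >= 0, na.rm = TRUE))
  rate > threshold
}

#' Per-sample mutational burden table
#'
#' @param calls prioritized somatic [variant_calls()].
#' @param meta [sample_meta()]; every metadata sample appears in the output,
#'   with zero counts when it has no surviving calls.
#' @param threshold hypermutation threshold in mutations/Mb.
#' @return data.frame with columns `sample_id`, `msi_status`,
#'   `somatic_count`, `callable_mb`, `rate_per_mb`, `hypermutated`.
#' @export
burden_table <- function(calls, meta, threshold = 12) {
  counts <- table(factor(calls$sample_id, levels = meta$sample_id))
  out <- data.frame(
    sample_id = meta$sample_id,
    msi_status = meta$msi_status,
    somatic_count = as.integer(counts),
    callable_mb = meta$callable_mb,
    stringsAsFactors = FALSE)
  out$rate_per_mb <- mutation_rate(out$somatic_count, out$callable_mb)
  out$hypermutated <- classify_hypermutated(out$rate_per_mb, threshold)
  out
}

#' MSI-group mutation-rate statistics
#'
#' Computes the median mutation rate per MSI group, a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test of MSI-H versus MSI-L rates (exact
#' null for small tie-free groups, normal approximation with continuity
#' correction otherwise), and a two-sided Fisher exact test on the 2x2
#' table of MSI-H membership against hypermutation status.
#'
#' @param burdens a [burden_table()] data.frame.
#' @return list with `medians` (named numeric over MSI groups),
#'   `rank_p` (MSI-H vs MSI-L Mann-Whitney p, `NA` with a warning when a
#'   group is empty), `fisher_p` (MSI-H x hypermutated exact p), and
#'   `fisher_table` (the 2x2 table tested).
#' @export
msi_group_stats <- function(burdens) {
  groups <- split(burdens$rate_per_mb, factor(burdens$msi_status,
                                              levels = MSI_LEVELS))
  medians <- vapply(groups, function(x) {
    if (length(x)) median(x) else NA_real_
  }, numeric(1))

  rank_p <- NA_real_
  if (length(groups[["MSI-H"]]) && length(groups[["MSI-L"]])) {
    rank_p <- suppressWarnings(
      wilcox.test(groups[["MSI-H"]], groups[["MSI-L"]],
                  alternative = "two.sided"))$p.value
  } else {
    warning("rank test skipped: MSI-H or MSI-L group is empty")
  }

  is_h <- burdens$msi_status == "MSI-H"
  tab <- table(factor(is_h, levels = c(TRUE, FALSE)),
               factor(burdens$hypermutated, levels = c(TRUE, FALSE)),
               dnn = c("msi_h", "hypermutated"))
  fisher_p <- if (sum(tab) > 0) fisher.test(tab)$p.value else NA_real_

  list(medians = medians, rank_p = rank_p, fisher_p = fisher_p,
       fisher_table = tab)
}

#' Variant-class distribution
#'
#' Exhaustive counts of calls by consequence class and by genomic region.
#'
#' @param calls a [variant_calls()] data.frame.
#' @return list of two data.frames, `effect` and `region`, each with a
#'   `count` column summing to `nrow(calls)`.
#' @export
variant_class_distribution <- function(calls) {
  eff <- table(factor(calls$effect, levels = VARIANT_EFFECTS))
  reg <- table(factor(calls$region, levels = VARIANT_REGIONS))
  list(effect = data.frame(effect = names(eff), count = as.integer(eff),
                           stringsAsFactors = FALSE),
       region = data.frame(region = names(reg), count = as.integer(reg),
                           stringsAsFactors = FALSE))
}

#' Recurrent variants
#'
#' Groups calls by genomic change (chrom, pos, ref, alt) — not by
#' amino-acid label, which can differ across transcripts — and reports
#' changes carried by at least `min_carriers` distinct samples, sorted by
#' carrier count (descending), then chromosome and position. A variant is
#' flagged novel when every carrier call is novel under [classify_novel()]
#' criteria (uncatalogued in both dbSNP and COSMIC with confident normal
#' coverage).
#'
#' @param calls a [variant_calls()] data.frame.
#' @param min_carriers minimum number of distinct carrier samples
#'   (default 2).
#' @param config [filter_config()] supplying the novelty coverage
#'   thresholds.
#' @return data.frame with one row per recurrent variant: `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `aa_change`, `carriers` (comma-separated),
#'   `carrier_count`, `novel`, `clinsig`.
#' @export
recurrent_variants <- function(calls, min_carriers = 2L,
                               config = filter_config()) {
  if (nrow(calls) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      aa_change = character(), carriers = character(),
                      carrier_count = integer(), novel = logical(),
                      clinsig = character(), stringsAsFactors = FALSE))
  }
  calls <- classify_novel(calls, config)
  key <- variant_key(calls)
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(idx) {
    g <- calls[idx, , drop = FALSE]
    carriers <- sort(unique(g$sample_id))
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], gene = g$gene[1], aa_change = g$aa_change[1],
               carriers = paste(carriers, collapse = ","),
               carrier_count = length(carriers),
               novel = all(g$novel),
               clinsig = if (any(!is.na(g$clinsig))) g$clinsig[!is.na(g$clinsig)][1]
                         else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$carrier_count >= min_carriers, , drop = FALSE]
  out <- out[order(-out$carrier_count, out$chrom, out$pos, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene mutation frequency
#'
#' Fraction of samples carrying at least one call in each gene; multiple
#' hits in the same gene and sample count once.
#'
#' @param calls a [variant_calls()] data.frame.
#' @param n_samples cohort size (>= 1) used as the denominator.
#' @return data.frame with `gene`, `carriers`, `frequency`, sorted by
#'   frequency (descending).
#' @export
gene_mutation_frequency <- function(calls, n_samples) {
  stopifnot(n_samples >= 1L)
  df <- unique(data.frame(gene = calls$gene, sample_id = calls$sample_id,
                          stringsAsFactors = FALSE))
  df <- df[!is.na(df$gene), , drop = FALSE]
  carriers <- table(df$gene)
  out <- data.frame(gene = names(carriers),
                    carriers = as.integer(carriers),
                    frequency = as.integer(carriers) / n_samples,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathogenic variant accounting
#'
#' Counts distinct genomic changes annotated pathogenic, and the distinct
#' genes they fall in. A pathogenic variant shared by several samples
#' counts once.
#'
#' @param calls a [variant_calls()] data.frame.
#' @return named integer vector `c(variants = , genes = )`.
#' @export
count_pathogenic <- function(calls) {
  p <- calls[!is.na(calls$clinsig) & calls$clinsig == "pathogenic", ,
             drop = FALSE]
  keys <- unique(variant_key(p))
  genes <- unique(p$gene[!duplicated(variant_key(p))])
  c(variants = length(keys), genes = length(genes[!is.na(genes)]))
}
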