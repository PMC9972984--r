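# Simplified driver-gene tests. These are deliberately transparent
# alternatives to covariate-based significance callers: a uniform-background
# binomial burden test and a permutation-based hotspot clustering test. The
# uniform background ignores per-gene covariates (replication timing,
# expression, chromatin), which full-scale tools model; results are
# comparable within a cohort, not across studies.

#' Significantly mutated genes under a uniform binomial background
#'
#' For each panel gene, tests whether its observed variant count exceeds
#' what a uniform per-base-pair, per-sample background mutation rate
#' predicts: `p = P(X >= observed)` with
#' `X ~ Binomial(n_samples * gene_length, background_rate)`, followed by
#' Benjamini-Hochberg adjustment across tested genes.
#'
#' @param calls prioritized somatic [variant_calls()].
#' @param panel data.frame with `gene` and `length_bp` (positive) columns,
#'   e.g. [fixture_gene_panel()]. Calls in genes absent from the panel are
#'   skipped with a warning.
#' @param n_samples cohort size.
#' @param background_rate expected mutations per base pair per sample
#'   (> 0).
#' @return data.frame sorted by p-value: `gene`, `carriers`,
#'   `variant_count`, `length_bp`, `p_value`, `q_value`.
#' @export
smg_binomial <- function(calls, panel, n_samples, background_rate) {
  stopifnot(background_rate > 0, n_samples >= 1L,
            all(c("gene", "length_bp") %in% names(panel)))
  if (any(panel$length_bp <= 0)) stop("every panel gene needs a positive length")
  outside <- setdiff(unique(calls$gene[!is.na(calls$gene)]), panel$gene)
  if (length(outside)) {
    warning("skipping calls in gene(s) absent from the panel: ",
            paste(outside, collapse = ", "))
  }
  counts <- table(factor(calls$gene, levels = panel$gene))
  carriers <- vapply(panel$gene, function(g) {
    length(unique(calls$sample_id[!is.na(calls$gene) & calls$gene == g]))
  }, integer(1))
  n_trials <- n_samples * panel$length_bp
  obs <- as.integer(counts)
  p <- pbinom(obs - 1L, n_trials, background_rate, lower.tail = FALSE)
  out <- data.frame(gene = panel$gene, carriers = unname(carriers),
                    variant_count = obs, length_bp = panel$length_bp,
                    p_value = p, q_value = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# null distribution of the maximum per-position carrier count when v
# variants are scattered uniformly over length_bp positions. Exact
# enumeration when length_bp^v <= max_states, else seeded Monte Carlo.
hotspot_null_p <- function(observed_max, v, length_bp, n_perm, max_states = 1e5) {
  if (length_bp^v <= max_states) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(length_bp)), v)))
    maxima <- apply(grid, 1L, function(pos) max(tabulate(pos, length_bp)))
    mean(maxima >= observed_max)
  } else {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pos <- sample.int(length_bp, v, replace = TRUE)
      if (max(tabulate(pos, length_bp)) >= observed_max) hits <- hits + 1L
    }
    (hits + 1L) / (n_perm + 1L)
  }
}

#' Hotspot-clustering driver score
#'
#' Scores each gene (with at least two variants) by how concentrated its
#' variants are at its single most-recurrent genomic position, and tests
#' the observed maximum per-position count against a null that scatters the
#' same number of variants uniformly over the gene length. The null is
#' enumerated exactly when the position-assignment space has at most `1e5`
#' states, and otherwise estimated by seeded Monte Carlo permutation.
#' P-values are Benjamini-Hochberg adjusted across scored genes.
#'
#' @param calls prioritized somatic [variant_calls()].
#' @param panel data.frame with `gene` and `length_bp`.
#' @param n_samples cohort size (reported, not used by the null).
#' @param fdr_threshold adjusted-significance threshold reported in the
#'   `significant` column (default 0.1).
#' @param n_perm Monte Carlo permutations when exact enumeration is
#'   infeasible (default 2000).
#' @param seed integer seed for the Monte Carlo branch.
#' @return data.frame sorted by p-value: `gene`, `carriers`,
#'   `variant_count`, `max_position_count`, `clustering_fraction`,
#'   `p_value`, `q_value`, `significant`.
#' @export
hotspot_driver_score <- function(calls, panel, n_samples,
                                 fdr_threshold = 0.1, n_perm = 2000L,
                                 seed = 1L) {
  set.seed(seed)
  genes <- intersect(panel$gene, unique(calls$gene[!is.na(calls$gene)]))
  rows <- lapply(genes, function(g) {
    gcalls <- calls[!is.na(calls$gene) & calls$gene == g, , drop = FALSE]
    v <- nrow(gcalls)
    if (v < 2L) return(NULL)  # clustering undefined for singletons
    pos_counts <- table(variant_key(gcalls))
    max_count <- max(as.integer(pos_counts))
    length_bp <- panel$length_bp[panel$gene == g][1]
    data.frame(gene = g,
               carriers = length(unique(gcalls$sample_id)),
               variant_count = v,
               max_position_count = max_count,
               clustering_fraction = max_count / v,
               p_value = hotspot_null_p(max_count, v, length_bp, n_perm),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene = character(), carriers = integer(),
                      variant_count = integer(),
                      max_position_count = integer(),
                      clustering_fraction = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < fdr_threshold
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
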