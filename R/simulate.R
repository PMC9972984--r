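# Seeded synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes — MSI-group-specific mutation rates,
# signature-mixture trinucleotide catalogs, recurrent hotspots, common
# germline variants leaking into tumour calls, and catalog membership —
# with full ground-truth labels, so every stage is testable without
# sequencing data.

default_signature_weights <- function() {
  w <- rbind(`MSI-H` = c(Sig1 = 0.15, Sig6 = 0.75, Sig10 = 0.10),
             `MSI-L` = c(Sig1 = 0.60, Sig6 = 0.30, Sig10 = 0.10),
             MSS     = c(Sig1 = 0.75, Sig6 = 0.15, Sig10 = 0.10))
  w
}

default_hotspots <- function() {
  data.frame(
    gene = c("KRAS", "ACVR2A", "TP53"),
    chrom = c("12", "2", "17"),
    pos = c(25398284L, 148683686L, 7578406L),
    ref = c("C", "TA", "C"),
    alt = c("T", "T", "T"),
    aa_change = c("G12D", "K435fs", "R175H"),
    effect = c("missense", "frameshift_del", "missense"),
    context3 = c("ACA", NA, "ACG"),
    cosmic_id = c("COSM521", "COSM252949", "COSM3355994"),
    target_carrier_count = c(6L, 4L, 4L),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions of the cohort being emulated: 50
#' patients split 10%/10%/80% into MSI-H/MSI-L/MSS, group median mutation
#' rates of 57.7, 4.1 and 3.8 mutations/Mb, one hypermutated MSS outlier at
#' 244/Mb, and recurrent hotspots (KRAS G12D in 6 samples, ACVR2A K435fs
#' and TP53 R175H in 4 each). Per-sample rates are log-normal around the
#' group median (only medians are known for the emulated cohort; sigma 0.6
#' reproduces a qualitatively wide range).
#'
#' @param n_samples cohort size.
#' @param msi_proportions named proportions over MSI-H/MSI-L/MSS, summing
#'   to 1.
#' @param rate_median named group medians, mutations/Mb.
#' @param rate_dispersion log-normal sigma of per-sample rates.
#' @param callable_mb callable genome size per sample, Mb.
#' @param signature_weights groups-by-signatures exposure matrix (rows sum
#'   to 1).
#' @param hotspots data.frame of planted recurrent variants (see
#'   `default_hotspots()`); `target_carrier_count` must not exceed
#'   `n_samples`.
#' @param germline_common_rate expected number of population-common
#'   germline variants leaking into each tumour call set (present in the
#'   matched normal too, population AF > 0.05).
#' @param novel_fraction probability that a somatic variant is absent from
#'   both known-variant catalogs.
#' @param mss_outlier_rate mutation rate (per Mb) of one planted
#'   hypermutated MSS sample, or `NULL` for none.
#' @param mss_outlier_weights signature mixture of the outlier
#'   (POLE-like, Sig10-heavy).
#' @param snv_fraction fraction of somatic variants that are single-base
#'   substitutions (the rest are small indels).
#' @param seed integer seed; mandatory.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 50L,
                          msi_proportions = c(`MSI-H` = 0.1, `MSI-L` = 0.1,
                                              MSS = 0.8),
                          rate_median = c(`MSI-H` = 57.7, `MSI-L` = 4.1,
                                          MSS = 3.8),
                          rate_dispersion = 0.6,
                          callable_mb = 30,
                          signature_weights = default_signature_weights(),
                          hotspots = default_hotspots(),
                          germline_common_rate = 20,
                          novel_fraction = 0.1,
                          mss_outlier_rate = 244,
                          mss_outlier_weights = c(Sig1 = 0.10, Sig6 = 0.10,
                                                  Sig10 = 0.80),
                          snv_fraction = 0.8,
                          seed) {
  if (missing(seed)) stop("cohort_config requires an explicit seed")
  stopifnot(n_samples >= 1L,
            abs(sum(msi_proportions) - 1) <= 1e-9,
            setequal(names(msi_proportions), MSI_LEVELS),
            setequal(names(rate_median), MSI_LEVELS),
            all(rate_median > 0), rate_dispersion >= 0, callable_mb > 0,
            novel_fraction >= 0, novel_fraction <= 1,
            snv_fraction >= 0, snv_fraction <= 1)
  if (!is.null(hotspots) && nrow(hotspots) &&
      any(hotspots$target_carrier_count > n_samples)) {
    stop("configuration error: hotspot target_carrier_count exceeds n_samples")
  }
  if (any(abs(rowSums(signature_weights) - 1) > 1e-9) ||
      any(signature_weights < 0)) {
    stop("signature_weights rows must be non-negative and sum to 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 msi_proportions = msi_proportions[MSI_LEVELS],
                 rate_median = rate_median[MSI_LEVELS],
                 rate_dispersion = rate_dispersion,
                 callable_mb = callable_mb,
                 signature_weights = signature_weights,
                 hotspots = hotspots,
                 germline_common_rate = germline_common_rate,
                 novel_fraction = novel_fraction,
                 mss_outlier_rate = mss_outlier_rate,
                 mss_outlier_weights = mss_outlier_weights,
                 snv_fraction = snv_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic largest-remainder apportionment of n into proportions
apportion <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# draw SNV alleles/contexts from a 96-channel probability vector; half the
# records are emitted on the purine strand to exercise normalization
draw_snv_channels <- function(n, probs) {
  labels <- channel_labels()
  idx <- sample.int(96L, n, replace = TRUE, prob = probs)
  lab <- labels[idx]
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  flip <- runif(n) < 0.5
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  data.frame(ref = ref, alt = alt, context3 = ctx, stringsAsFactors = FALSE)
}

random_bases <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(SS_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a paired tumour/normal cohort with ground truth
#'
#' Per sample, the somatic count is `round(callable_mb * R)` with `R`
#' log-normal around the MSI-group median; each somatic SNV's channel is a
#' draw from the group's signature mixture (emitted on a random strand,
#' `context3` set accordingly); hotspots are planted in exactly their
#' target carrier counts; population-common germline variants (AF > 0.05,
#' catalogued in dbSNP) appear identically in tumour and normal call sets;
#' novel somatic variants are uncatalogued with confident normal coverage
#' (depth >= 10, zero variant reads). All generated somatic variants pass
#' the default prioritization thresholds with margin, so filter recovery
#' against the truth labels is exact. A fixed seed gives bit-identical
#' output.
#'
#' @param config a [cohort_config()].
#' @param reference a [signature_matrix()] containing every signature named
#'   in `config$signature_weights`.
#' @param panel gene panel data.frame (gene/chrom/offset/length_bp).
#' @return list: `tumour` and `normal` ([variant_calls()]), `meta`
#'   ([sample_meta()]), `truth` (list with `samples` — group, true rate and
#'   exposures per sample — and `variants` — per-variant label among
#'   somatic/hotspot/novel/germline_common).
#' @export
simulate_cohort <- function(config, reference = reference_signatures(),
                            panel = fixture_gene_panel()) {
  stopifnot(inherits(config, "cohort_config"))
  missing_sigs <- setdiff(colnames(config$signature_weights),
                          colnames(reference))
  if (length(missing_sigs)) {
    stop("reference lacks signature(s) named in the configuration: ",
         paste(missing_sigs, collapse = ", "))
  }
  set.seed(config$seed)
  n <- config$n_samples
  counts_by_group <- apportion(n, config$msi_proportions)
  group <- rep(MSI_LEVELS, counts_by_group)
  sample_ids <- sprintf("S%03d", seq_len(n))

  outlier <- rep(FALSE, n)
  if (!is.null(config$mss_outlier_rate) && any(group == "MSS")) {
    outlier[which(group == "MSS")[1]] <- TRUE
  }

  rate <- rlnorm(n, log(config$rate_median[group]), config$rate_dispersion)
  rate[outlier] <- config$mss_outlier_rate
  som_count <- as.integer(round(config$callable_mb * rate))

  meta <- sample_meta(data.frame(sample_id = sample_ids, msi_status = group,
                                 callable_mb = config$callable_mb,
                                 stringsAsFactors = FALSE))

  W <- unclass(reference)[, colnames(config$signature_weights), drop = FALSE]
  mix_probs <- function(i) {
    e <- if (outlier[i]) config$mss_outlier_weights[colnames(W)] else
      config$signature_weights[group[i], ]
    as.numeric(W %*% e)
  }

  snv_effects <- c(missense = 0.82, nonsense = 0.13, stoploss = 0.05)
  indel_effects <- c(frameshift_del = 0.5, frameshift_ins = 0.3,
                     inframe_del = 0.1, inframe_ins = 0.1)
  rs_counter <- 0L

  gene_row <- function(m) sample.int(nrow(panel), m, replace = TRUE,
                                     prob = panel$length_bp)

  per_sample <- lapply(seq_len(n), function(i) {
    m <- som_count[i]
    if (m == 0L) return(NULL)
    m_snv <- sum(runif(m) < config$snv_fraction)
    m_ind <- m - m_snv

    alleles <- if (m_snv) draw_snv_channels(m_snv, mix_probs(i)) else NULL
    eff_snv <- if (m_snv) sample(names(snv_effects), m_snv, TRUE,
                                 prob = snv_effects) else character()
    ind <- NULL
    if (m_ind) {
      kinds <- sample(names(indel_effects), m_ind, TRUE, prob = indel_effects)
      is_del <- kinds %in% c("frameshift_del", "inframe_del")
      base <- random_bases(m_ind, 1L)
      ext <- random_bases(m_ind, 1L)
      ind <- data.frame(
        ref = ifelse(is_del, paste0(base, ext), base),
        alt = ifelse(is_del, base, paste0(base, ext)),
        context3 = NA_character_, effect = kinds, stringsAsFactors = FALSE)
    }
    df <- data.frame(
      ref = c(if (m_snv) alleles$ref, if (m_ind) ind$ref),
      alt = c(if (m_snv) alleles$alt, if (m_ind) ind$alt),
      context3 = c(if (m_snv) alleles$context3, if (m_ind) ind$context3),
      effect = c(eff_snv, if (m_ind) ind$effect),
      stringsAsFactors = FALSE)
    gi <- gene_row(m)
    df$gene <- panel$gene[gi]
    df$chrom <- panel$chrom[gi]
    df$pos <- panel$offset[gi] +
      as.integer(floor(runif(m) * panel$length_bp[gi])) + 1L
    df$sample_id <- sample_ids[i]
    aa_pos <- as.integer(ceiling((df$pos - panel$offset[gi]) / 3))
    df$aa_change <- ifelse(grepl("frameshift", df$effect),
                           sprintf("%s%dfs", sample(LETTERS, m, TRUE), aa_pos),
                           sprintf("%s%d%s", sample(LETTERS, m, TRUE), aa_pos,
                                   sample(LETTERS, m, TRUE)))
    df
  })
  som <- do.call(rbind, per_sample)
  if (is.null(som)) {
    som <- data.frame(ref = character(), alt = character(),
                      context3 = character(), effect = character(),
                      gene = character(), chrom = character(),
                      pos = integer(), sample_id = character(),
                      aa_change = character(), stringsAsFactors = FALSE)
  }
  # drop colliding genomic keys within a sample (the generator guarantees
  # label disjointness per variant)
  som <- som[!duplicated(paste(som$sample_id, som$chrom, som$pos, som$ref,
                               som$alt)), , drop = FALSE]
  m_tot <- nrow(som)
  is_novel <- runif(m_tot) < config$novel_fraction
  rs_id <- sprintf("rs9%08d", seq_len(m_tot))
  cosm_id <- sprintf("COSM9%06d", seq_len(m_tot))
  has_cosmic <- runif(m_tot) < 0.5
  som_calls <- data.frame(
    sample_id = som$sample_id, chrom = som$chrom, pos = som$pos,
    ref = som$ref, alt = som$alt, gene = som$gene, region = "exonic",
    effect = som$effect, aa_change = som$aa_change,
    quality = runif(m_tot, 45, 70),
    tumor_depth = 60L, tumor_alt = 15L + as.integer(floor(runif(m_tot) * 20)),
    normal_depth = 15L + as.integer(floor(runif(m_tot) * 30)),
    normal_alt = 0L,
    dbsnp_id = ifelse(is_novel, NA_character_, rs_id),
    cosmic_id = ifelse(is_novel | !has_cosmic, NA_character_, cosm_id),
    context3 = som$context3,
    stringsAsFactors = FALSE)
  som_calls$label <- ifelse(is_novel, "novel", "somatic")

  # planted hotspots: exact carrier counts, catalogued (COSMIC) and passing
  hs <- config$hotspots
  hs_calls <- NULL
  if (!is.null(hs) && nrow(hs)) {
    hs_rows <- lapply(seq_len(nrow(hs)), function(j) {
      carriers <- sample(sample_ids, hs$target_carrier_count[j])
      data.frame(
        sample_id = carriers, chrom = hs$chrom[j], pos = hs$pos[j],
        ref = hs$ref[j], alt = hs$alt[j], gene = hs$gene[j],
        region = "exonic", effect = hs$effect[j], aa_change = hs$aa_change[j],
        quality = runif(length(carriers), 50, 70),
        tumor_depth = 60L, tumor_alt = 25L,
        normal_depth = 30L, normal_alt = 0L,
        dbsnp_id = NA_character_, cosmic_id = hs$cosmic_id[j],
        context3 = hs$context3[j], label = "hotspot",
        stringsAsFactors = FALSE)
    })
    hs_calls <- do.call(rbind, hs_rows)
    # a hotspot plant supersedes any colliding background variant
    som_calls <- som_calls[!paste(som_calls$sample_id, som_calls$chrom,
                                  som_calls$pos) %in%
                             paste(hs_calls$sample_id, hs_calls$chrom,
                                   hs_calls$pos), , drop = FALSE]
  }

  # population-common germline variants, present in tumour AND normal with
  # identical genotype evidence, AF > 0.05 in every database
  germ_n <- rpois(n, config$germline_common_rate)
  germ_rows <- lapply(seq_len(n), function(i) {
    g <- germ_n[i]
    if (g == 0L) return(NULL)
    gi <- gene_row(g)
    data.frame(
      sample_id = sample_ids[i], chrom = panel$chrom[gi],
      pos = panel$offset[gi] +
        as.integer(floor(runif(g) * panel$length_bp[gi])) + 1L,
      ref = random_bases(g, 1L), alt = random_bases(g, 1L),
      gene = panel$gene[gi], region = "exonic",
      effect = sample(c("missense", "synonymous"), g, TRUE, c(0.6, 0.4)),
      aa_change = NA_character_,
      quality = runif(g, 45, 70),
      tumor_depth = 60L, tumor_alt = 30L,
      normal_depth = 40L, normal_alt = 20L,
      dbsnp_id = sprintf("rs1%07d", sample.int(9999999L, g)),
      cosmic_id = NA_character_,
      af_1000g = runif(g, 0.06, 0.5), af_exac = runif(g, 0.06, 0.5),
      af_esp6500 = runif(g, 0.06, 0.5),
      context3 = NA_character_, label = "germline_common",
      stringsAsFactors = FALSE)
  })
  germ <- do.call(rbind, germ_rows)
  if (!is.null(germ) && nrow(germ)) {
    germ <- germ[germ$ref != germ$alt, , drop = FALSE]
    germ <- germ[!duplicated(paste(germ$sample_id, germ$chrom, germ$pos)), ,
                 drop = FALSE]
    # never collide with a somatic/hotspot key
    somatic_keys <- paste(som_calls$sample_id, som_calls$chrom, som_calls$pos)
    if (!is.null(hs_calls)) {
      somatic_keys <- c(somatic_keys,
                        paste(hs_calls$sample_id, hs_calls$chrom, hs_calls$pos))
    }
    germ <- germ[!paste(germ$sample_id, germ$chrom, germ$pos) %in%
                   somatic_keys, , drop = FALSE]
  }

  fill_af <- function(df) {
    for (nm in AF_COLUMNS) if (!nm %in% names(df)) df[[nm]] <- NA_real_
    df
  }
  tumour_df <- rbind(fill_af(som_calls),
                     if (!is.null(hs_calls)) fill_af(hs_calls),
                     germ)
  labels <- tumour_df$label
  tumour_df$label <- NULL
  tumour <- variant_calls(tumour_df)
  truth_variants <- data.frame(
    sample_id = tumour_df$sample_id, chrom = tumour_df$chrom,
    pos = tumour_df$pos, ref = tumour_df$ref, alt = tumour_df$alt,
    label = labels, stringsAsFactors = FALSE)

  normal <- if (!is.null(germ) && nrow(germ)) {
    nd <- germ
    nd$label <- NULL
    variant_calls(nd)
  } else {
    tumour[0, , drop = FALSE]
  }

  exposures <- t(vapply(seq_len(n), function(i) {
    e <- if (outlier[i]) config$mss_outlier_weights[colnames(W)] else
      config$signature_weights[group[i], ]
    as.numeric(e)
  }, numeric(ncol(W))))
  colnames(exposures) <- colnames(W)

  truth_samples <- data.frame(sample_id = sample_ids, msi_status = group,
                              true_rate = rate, true_somatic_count = som_count,
                              mss_outlier = outlier, stringsAsFactors = FALSE)
  truth_samples <- cbind(truth_samples, exposures)

  list(tumour = tumour, normal = normal, meta = meta,
       truth = list(samples = truth_samples, variants = truth_variants),
       config = config)
}
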