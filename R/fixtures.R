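# Bundled fixtures, all generated deterministically in code: transcriptions
# of the study's printed cohort tables, a synthetic three-signature
# reference, an abstract gene panel, and the default druggability rules.

#' Clinicopathological cohort summary fixture
#'
#' Category/level/count table for the 50-patient colorectal cancer cohort
#' (age group, gender, ethnicity, tumour stage, differentiation, vital
#' status). Percentages are re-derivable as `n / 50 * 100`.
#'
#' @return data.frame with columns `category`, `level`, `n`.
#' @export
fixture_table1 <- function() {
  df <- data.frame(
    category = c("all", "age", "age", "gender", "gender",
                 "ethnicity", "ethnicity", "ethnicity",
                 "stage", "stage", "stage", "stage",
                 "nodes", "nodes",
                 "differentiation", "differentiation", "differentiation",
                 "vital_status", "vital_status", "vital_status"),
    level = c("all_patients", ">50", "<50", "male", "female",
              "malay", "chinese", "indian",
              "T1", "T2", "T3", "T4",
              "metastasized", "non_metastasized",
              "moderate", "well", "poor",
              "deceased", "alive", "untraceable"),
    n = c(50L, 46L, 4L, 28L, 22L, 37L, 13L, 0L, 3L, 6L, 35L, 6L,
          27L, 23L, 25L, 25L, 0L, 18L, 27L, 5L),
    stringsAsFactors = FALSE)
  df
}

#' Percentage of patients in a cohort-summary level
#'
#' @param table1 a [fixture_table1()]-shaped data.frame.
#' @param category,level the row to report.
#' @return percentage of all patients, on the 0-100 scale.
#' @export
cohort_percentage <- function(table1, category, level) {
  total <- table1$n[table1$category == "all"][1]
  n <- table1$n[table1$category == category & table1$level == level]
  if (length(n) != 1L) stop("no unique row for ", category, "/", level)
  100 * n / total
}

#' Recurrent-variant table fixture
#'
#' The 16 known and novel recurrent somatic variants of the study cohort:
#' genomic change, carrier samples, amino-acid change, catalog identifiers
#' (`NA` = never reported) and clinical significance.
#'
#' @return data.frame, one row per recurrent variant; `samples` is a
#'   comma-separated carrier list.
#' @export
fixture_table4 <- function() {
  df <- data.frame(
    gene = c("KDM4E", "KRAS", "TP53", "MUC16", "MUC16", "POTED", "PIK3CA",
             "APC", "APC", "APC", "KRAS", "TP53", "BRAF", "TP53", "ACVR2A",
             "KRAS"),
    chrom = c("11", "12", "17", "19", "19", "21", "3", "5", "5", "5", "12",
              "17", "7", "17", "2", "12"),
    pos = c(94759020L, 25398284L, 7577120L, 9015323L, 9015324L, 14983063L,
            178936091L, 112116592L, 112175507L, 112175639L, 25398281L,
            7577539L, 140453136L, 7578406L, 148683686L, 25398284L),
    ref = c("G", "C", "C", "C", "A", "G", "G", "C", "C", "C", "C", "G", "A",
            "C", "TA", "C"),
    alt = c("A", "G", "T", "A", "G", "C", "A", "T", "T", "T", "T", "A", "T",
            "T", "T", "T"),
    samples = c("C434T,C569T", "C414T,C678T", "C547T,C668T", "C187T,C330T",
                "C187T,C330T", "C662T,C666T", "C396T,C398T", "C187T,C506T",
                "C467T,C501T", "C569T,C594T", "C459T,C467T,C497T",
                "C414T,C450T,C511T", "C396T,C449T,C474T",
                "C404T,C484T,C501T,C649T", "C420T,C474T,C594T,C666T",
                "C273T,C469T,C547T,C570T,C649T,C663T"),
    aa_change = c("R100H", "G12A", "R273H", "L12755F", "L12755S", "E172Q",
                  "E545K", "R223X", "Q1406X", "R1450X", "G13D", "R248W",
                  "V600E", "R175H", "K435fs", "G12D"),
    effect = c("missense", "missense", "missense", "missense", "missense",
               "missense", "missense", "nonsense", "nonsense", "nonsense",
               "missense", "missense", "missense", "missense",
               "frameshift_del", "missense"),
    cosmic_id = c(NA, "COSM1140134", "COSM99729", NA, NA, NA, "COSM763",
                  "COSM13134", "COSM19087", "COSM13127", "COSM1140132",
                  "COSM3388183", "COSM476", "COSM3355994", "COSM252949",
                  "COSM521"),
    dbsnp_id = c(NA, "rs121913529", "rs28934576", NA, NA, NA, "rs104886003",
                 "rs587781392", "rs587782518", "rs121913332", "rs112445441",
                 "rs121912651", "rs113488022", "rs28934578", "rs764719749",
                 "rs121913529"),
    clinsig = c(NA, "pathogenic", "pathogenic", NA, NA, NA, "pathogenic",
                "pathogenic", "pathogenic", "pathogenic", "pathogenic",
                "pathogenic", "pathogenic", "pathogenic", NA, "pathogenic"),
    stringsAsFactors = FALSE)
  df
}

#' Expand the recurrent-variant fixture into per-sample calls
#'
#' One call per (variant, carrier sample), with evidence fields filled to
#' the prioritization chain's passing ranges (quality 60, normal coverage
#' 30x with zero variant reads) so the fixture exercises counting logic, not
#' filtering.
#'
#' @param table4 a [fixture_table4()]-shaped data.frame.
#' @return a [variant_calls()] data.frame.
#' @export
table4_calls <- function(table4 = fixture_table4()) {
  carriers <- strsplit(table4$samples, ",", fixed = TRUE)
  idx <- rep.int(seq_len(nrow(table4)), lengths(carriers))
  variant_calls(data.frame(
    sample_id = unlist(carriers, use.names = FALSE),
    chrom = table4$chrom[idx], pos = table4$pos[idx],
    ref = table4$ref[idx], alt = table4$alt[idx],
    gene = table4$gene[idx], region = "exonic", effect = table4$effect[idx],
    aa_change = table4$aa_change[idx], quality = 60,
    tumor_depth = 40L, tumor_alt = 15L, normal_depth = 30L, normal_alt = 0L,
    dbsnp_id = table4$dbsnp_id[idx], cosmic_id = table4$cosmic_id[idx],
    clinsig = table4$clinsig[idx],
    stringsAsFactors = FALSE))
}

#' Synthetic three-signature reference matrix
#'
#' A deterministic stand-in for a COSMIC-v2-style reference, with the
#' qualitative features of the processes the cohort analysis attributes:
#' `Sig1` (ageing-like, C>T concentrated at NpCpG from 5-methylcytosine
#' deamination), `Sig6` (mismatch-repair-deficiency-like, broad C>T at
#' non-CpG contexts), and `Sig10` (POLE-exonuclease-like, C>A at TpCpT with
#' secondary C>T at TpCpG). These are synthetic constructions, not the real
#' COSMIC profiles; a genuine reference can be supplied to any consumer via
#' [read_signature_matrix()].
#'
#' @return a [signature_matrix()] with columns `Sig1`, `Sig6`, `Sig10`.
#' @export
reference_signatures <- function() {
  ch <- channel_labels()
  five <- substr(ch, 1, 1); sub <- substr(ch, 3, 5); three <- substr(ch, 7, 7)
  w <- matrix(0, 96L, 3L, dimnames = list(ch, c("Sig1", "Sig6", "Sig10")))

  # Sig1: sharp C>T at CpG, light uniform background
  cpg_ct <- sub == "C>T" & three == "G"
  w[cpg_ct, "Sig1"] <- c(0.30, 0.25, 0.25, 0.15)
  w[, "Sig1"] <- w[, "Sig1"] * 0.95 + 0.05 / 96

  # Sig6: broad C>T away from CpG, 5'G-enriched, plus a mild CpG shoulder
  non_cpg_ct <- sub == "C>T" & three != "G"
  w[non_cpg_ct, "Sig6"] <- ifelse(five[non_cpg_ct] == "G", 2, 1)
  w[non_cpg_ct, "Sig6"] <- w[non_cpg_ct, "Sig6"] / sum(w[non_cpg_ct, "Sig6"]) * 0.80
  w[cpg_ct, "Sig6"] <- w[cpg_ct, "Sig6"] + 0.12 / 4
  w[, "Sig6"] <- w[, "Sig6"] + 0.08 / 96

  # Sig10: dominant T[C>A]T with secondary T[C>T]G and minor T[C>A]N
  w["T[C>A]T", "Sig10"] <- 0.55
  w["T[C>T]G", "Sig10"] <- 0.20
  w[c("T[C>A]A", "T[C>A]C", "T[C>A]G"), "Sig10"] <-
    w[c("T[C>A]A", "T[C>A]C", "T[C>A]G"), "Sig10"] + 0.15 / 3
  w[, "Sig10"] <- w[, "Sig10"] + 0.10 / 96

  signature_matrix(sweep(w, 2L, colSums(w), "/"))
}

#' Abstract gene panel fixture
#'
#' A small panel of genes (coding length in bp, chromosome, genomic offset)
#' used by the synthetic cohort generator to place variants and by the
#' driver tests as gene-length input. Lengths are order-of-magnitude
#' realistic for the coding footprint of each gene, not transcript-exact.
#'
#' @return data.frame with columns `gene`, `chrom`, `offset`, `length_bp`.
#' @export
fixture_gene_panel <- function() {
  df <- data.frame(
    gene = c("APC", "TP53", "KRAS", "TCF7L2", "ACVR2A", "MUC16", "MUC4",
             "RNF43", "PIK3CA", "BRAF", "POLE", "KDM4E", "POTED", "FAT3",
             "KMT2C", "LRP1B", "PCLO", "SCN1A", "SPEG", "CCDC168", "FBXW7",
             "DSCAM", "JARID2", "OCA2", "PTPRS", "CNTLN", "IGSF3", "COL6A3",
             "CSMD1", "TNRC18"),
    chrom = c("5", "17", "12", "10", "2", "19", "3", "17", "3", "7", "12",
              "11", "21", "11", "7", "2", "7", "2", "2", "13", "4", "21",
              "6", "15", "19", "9", "1", "2", "8", "7"),
    offset = c(112116000L, 7577100L, 25398000L, 114710000L, 148683000L,
               8959000L, 195473000L, 56429000L, 178866000L, 140419000L,
               133200000L, 94730000L, 14982000L, 92085000L, 151832000L,
               140988000L, 82383000L, 166845000L, 220299000L, 103000000L,
               153242000L, 41382000L, 15246000L, 28000000L, 5212000L,
               25700000L, 117100000L, 238232000L, 2792000L, 5346000L),
    length_bp = c(8532L, 1500L, 567L, 1851L, 1542L, 43524L, 16327L, 2352L,
                  3207L, 2301L, 6861L, 1500L, 1500L, 13766L, 14733L, 13848L,
                  15276L, 6030L, 10074L, 2100L, 2124L, 6051L, 3747L, 2517L,
                  5841L, 4050L, 3651L, 9528L, 10713L, 8850L),
    stringsAsFactors = FALSE)
  df
}

#' Default druggability rules fixture
#'
#' A transparent, editable rules table standing in for a clinical
#' variant-interpretation service. The rows encode the drug response and
#' resistance statements reported for this cohort (KRAS G12D resistance to
#' EGFR/ERBB2 monoclonal antibodies, other KRAS variants responsive to MEK
#' combination regimens, PIK3CA response to PI3K-pathway inhibition and
#' cetuximab resistance, APC truncations responsive to tankyrase inhibitors,
#' RNF43 frameshifts responsive to the porcupine inhibitor LGK974, BRAF
#' V600E combination response, POLE variants and immune checkpoint
#' blockade). They are an illustrative fixture, not clinical guidance.
#'
#' @return rules data.frame (see [validate_rules()] for the schema).
#' @export
fixture_rules <- function() {
  df <- data.frame(
    gene = c("KRAS", "KRAS", "KRAS", "KRAS", "PIK3CA", "PIK3CA", "APC",
             "RNF43", "BRAF", "BRAF", "POLE"),
    pattern_kind = c("exact_aa", "exact_aa", "any_nonsynonymous",
                     "any_nonsynonymous", "any_nonsynonymous",
                     "any_nonsynonymous", "truncating", "frameshift",
                     "exact_aa", "exact_aa", "any_nonsynonymous"),
    pattern_payload = c("G12D", "G12D", NA, NA, NA, NA, NA, NA, "V600E",
                        "V600E", NA),
    drug = c("EGFR mAb inhibitors (cetuximab, panitumumab)",
             "ERBB2 mAb inhibitors (trastuzumab, lapatinib)",
             "MEK + PI3K pathway inhibitor combination",
             "MEK + BCL-XL inhibitor combination",
             "PI3K pathway inhibitors",
             "Cetuximab",
             "Tankyrase inhibitors",
             "Porcupine inhibitor LGK974",
             "BRAF + EGFR inhibitor combination (encorafenib + cetuximab)",
             "EGFR mAb monotherapy",
             "PD-1 immune checkpoint inhibitors"),
    effect = c("resistant", "resistant", "responsive", "responsive",
               "responsive", "resistant", "responsive", "responsive",
               "responsive", "resistant", "responsive"),
    evidence = c("FDA", "NCCN", "early_trials", "early_trials",
                 "early_trials", "late_trials", "pre_clinical",
                 "early_trials", "FDA", "NCCN", "late_trials"),
    disease = "COREAD",
    stringsAsFactors = FALSE)
  validate_rules(df)
}

#' Write a named fixture to disk
#'
#' Deterministic writer for the bundled fixtures; calling it twice produces
#' byte-identical files.
#'
#' @param name one of `"table1"`, `"table4"`, `"rules_default"`,
#'   `"reference_signatures"`, `"gene_panel"`.
#' @param dir output directory (created if needed).
#' @return the written file path, invisibly.
#' @export
build_fixtures <- function(name = c("table1", "table4", "rules_default",
                                    "reference_signatures", "gene_panel"),
                           dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".tsv"))
  switch(name,
         table1 = write_table(fixture_table1(), path),
         table4 = write_table(fixture_table4(), path),
         rules_default = write_table(fixture_rules(), path),
         gene_panel = write_table(fixture_gene_panel(), path),
         reference_signatures = write_signature_matrix(reference_signatures(),
                                                       path))
  invisible(path)
}
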