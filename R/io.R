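# Tabular input/output. All tables are UTF-8 TSV with a header row and "."
# for absent values; typed schemas funnel external files into the shared
# domain types.

TABLE_SCHEMAS <- list(
  variants    = c("sample_id", "chrom", "pos", "ref", "alt"),
  annotations = c("chrom", "pos", "ref", "alt"),
  rules       = c("gene", "pattern_kind", "pattern_payload", "drug",
                  "effect", "evidence", "disease"),
  metadata    = c("sample_id", "msi_status", "callable_mb")
)

#' Read a typed TSV table
#'
#' @param path file path to a tab-delimited file with a header row.
#' @param schema one of `"variants"`, `"annotations"`, `"rules"`,
#'   `"metadata"`; decides the required columns and the validation applied.
#'   Extra columns are preserved untouched.
#' @return a validated data.frame ([variant_calls()], [sample_meta()], a
#'   rules table, or a plain annotation data.frame).
#' @export
read_table <- function(path, schema = c("variants", "annotations", "rules",
                                        "metadata")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dup <- unique(header[duplicated(header)])
  if (length(dup)) {
    stop("schema error in ", path, ": duplicated header column(s): ",
         paste(dup, collapse = ", "))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c(".", "NA", ""))
  missing <- setdiff(TABLE_SCHEMAS[[schema]], names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing required column(s) for '",
         schema, "': ", paste(missing, collapse = ", "))
  }
  switch(schema,
         variants = variant_calls(df),
         metadata = sample_meta(df),
         rules = validate_rules(df),
         annotations = df)
}

#' Write a table as TSV
#'
#' Inverse of [read_table()]: tab-delimited, header row, `NA` written as
#' `"."`, no quoting. Reading the result back reproduces the field values.
#'
#' @param x data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

# --- VCF ------------------------------------------------------------------

# INFO-key dialects. Each entry maps canonical columns to INFO keys plus
# recode tables for the enumerated annotation vocabularies.
VCF_DIALECTS <- list(
  simple = list(
    keys = c(gene = "GENE", region = "REGION", effect = "EFFECT",
             aa_change = "AA", af_1000g = "AF_1KG", af_exac = "AF_EXAC",
             af_esp6500 = "AF_ESP", dbsnp_id = "DBSNP", cosmic_id = "COSMIC",
             clinsig = "CLNSIG", sift = "SIFT", polyphen = "PPH",
             context3 = "CTX", tumor_depth = "TDP", tumor_alt = "TAD",
             normal_depth = "NDP", normal_alt = "NAD"),
    region_map = NULL, effect_map = NULL, impact_map = NULL,
    clinsig_map = NULL),
  annovar = list(
    keys = c(gene = "Gene.refGene", region = "Func.refGene",
             effect = "ExonicFunc.refGene", aa_change = "AAChange.refGene",
             af_1000g = "1000g2015aug_all", af_exac = "ExAC_ALL",
             af_esp6500 = "esp6500siv2_all", dbsnp_id = "avsnp144",
             cosmic_id = "cosmic70", clinsig = "CLNSIG", sift = "SIFT_pred",
             polyphen = "Polyphen2_HDIV_pred", context3 = "CTX",
             tumor_depth = "TDP", tumor_alt = "TAD",
             normal_depth = "NDP", normal_alt = "NAD"),
    region_map = c(exonic = "exonic", splicing = "splicing",
                   intronic = "intronic", UTR3 = "UTR3", UTR5 = "UTR5",
                   upstream = "upstream", downstream = "downstream",
                   intergenic = "intergenic"),
    effect_map = c(nonsynonymous_SNV = "missense", stopgain = "nonsense",
                   stoploss = "stoploss",
                   frameshift_insertion = "frameshift_ins",
                   frameshift_deletion = "frameshift_del",
                   nonframeshift_insertion = "inframe_ins",
                   nonframeshift_deletion = "inframe_del",
                   synonymous_SNV = "synonymous"),
    impact_map = c(D = "damaging", P = "damaging", T = "tolerated",
                   B = "tolerated"),
    clinsig_map = c(Pathogenic = "pathogenic", pathogenic = "pathogenic",
                    Benign = "benign", benign = "benign",
                    VUS = "vus", uncertain_significance = "vus"))
)

info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", gsub("([.\\\\])", "\\\\\\1", key), "=([^;]*)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

recode_or_default <- function(x, map, default) {
  if (is.null(map)) return(ifelse(is.na(x) | x == ".", NA_character_, x))
  out <- unname(map[x])
  out[is.na(x) | x == "."] <- NA_character_
  out[!is.na(x) & x != "." & is.na(out)] <- default
  out
}

# pick the i-th comma-separated entry, recycling scalars
nth_csv <- function(x, i) {
  parts <- strsplit(x, ",", fixed = TRUE)
  vapply(seq_along(parts), function(j) {
    p <- parts[[j]]
    if (length(p) >= i[j]) p[i[j]] else p[1]
  }, character(1))
}

#' Read annotated variant calls from a VCF file
#'
#' Parses a VCF 4.x file whose INFO field carries variant annotations in one
#' of the supported dialects, and returns one call per (record, ALT allele):
#' multi-allelic records are split, positions stay 1-based, and annotations
#' absent from the INFO field map to `NA`.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param sample_id sample identifier attached to every returned call.
#' @param annotation_dialect `"simple"` (this package's own INFO keys) or
#'   `"annovar"` (ANNOVAR-style refGene/population-frequency keys).
#' @return a [variant_calls()] data.frame.
#' @export
read_vcf <- function(path, sample_id,
                     annotation_dialect = c("simple", "annovar")) {
  annotation_dialect <- match.arg(annotation_dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "##fileformat=VCF")) {
    stop("format error in ", path,
         ": line 1 must be a ##fileformat=VCF header, got: ", first)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  empty <- variant_calls(data.frame(sample_id = character(), chrom = character(),
                                    pos = integer(), ref = character(),
                                    alt = character(),
                                    stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) return(empty)

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  dialect <- VCF_DIALECTS[[annotation_dialect]]
  info <- fix$INFO[row_idx]
  get <- function(col) info_field(info, dialect$keys[[col]])

  df <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM[row_idx],
    pos = as.integer(fix$POS[row_idx]),
    ref = fix$REF[row_idx],
    alt = unlist(alts, use.names = FALSE),
    gene = recode_or_default(get("gene"), NULL, NA),
    region = {
      r <- recode_or_default(get("region"), dialect$region_map, "unknown")
      ifelse(is.na(r), "unknown", r)
    },
    effect = {
      e <- recode_or_default(get("effect"), dialect$effect_map, "other")
      ifelse(is.na(e), "other", e)
    },
    aa_change = get("aa_change"),
    quality = suppressWarnings(as.numeric(fix$QUAL[row_idx])),
    tumor_depth = suppressWarnings(as.integer(get("tumor_depth"))),
    tumor_alt = suppressWarnings(as.integer(nth_csv(get("tumor_alt"), alt_idx))),
    normal_depth = suppressWarnings(as.integer(get("normal_depth"))),
    normal_alt = suppressWarnings(as.integer(nth_csv(get("normal_alt"), alt_idx))),
    af_1000g = suppressWarnings(as.numeric(get("af_1000g"))),
    af_exac = suppressWarnings(as.numeric(get("af_exac"))),
    af_esp6500 = suppressWarnings(as.numeric(get("af_esp6500"))),
    dbsnp_id = get("dbsnp_id"),
    cosmic_id = get("cosmic_id"),
    clinsig = recode_or_default(get("clinsig"), dialect$clinsig_map, NA),
    sift = recode_or_default(get("sift"), dialect$impact_map, NA),
    polyphen = recode_or_default(get("polyphen"), dialect$impact_map, NA),
    context3 = get("context3"),
    stringsAsFactors = FALSE)
  variant_calls(df)
}

#' Write variant calls as a simple-dialect VCF
#'
#' Emits a minimal VCF 4.2 body carrying the package's annotation columns as
#' INFO keys of the `"simple"` dialect, so [read_vcf()] round-trips the
#' calls. One record per call; no multi-allelic merging is attempted.
#'
#' @param calls a [variant_calls()] data.frame (single sample).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  keys <- VCF_DIALECTS$simple$keys
  fmt <- function(x) ifelse(is.na(x), NA_character_, as.character(x))
  info_cols <- vapply(names(keys), function(col) {
    v <- fmt(calls[[col]])
    ifelse(is.na(v), NA_character_, paste0(keys[[col]], "=", v))
  }, character(nrow(calls)))
  if (nrow(calls) == 1L) info_cols <- matrix(info_cols, nrow = 1L)
  info <- apply(info_cols, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"%s\">",
            unname(keys), names(keys)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
          ifelse(is.na(calls$quality), ".", format(calls$quality)),
          "PASS", info, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}
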