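# Domain types: annotated variant calls and per-sample metadata.
# Both are plain data.frames with a fixed set of typed columns; extra
# columns are carried through untouched.

VARIANT_REGIONS <- c("exonic", "splicing", "intronic", "UTR3", "UTR5",
                     "upstream", "downstream", "intergenic", "unknown")
VARIANT_EFFECTS <- c("missense", "nonsense", "stoploss", "frameshift_ins",
                     "frameshift_del", "inframe_ins", "inframe_del",
                     "synonymous", "other")
CLINSIG_LEVELS <- c("pathogenic", "benign", "vus")
IMPACT_LEVELS <- c("damaging", "tolerated")
MSI_LEVELS <- c("MSI-H", "MSI-L", "MSS")

# population allele-frequency columns understood by the filters; values are
# NA when the variant is absent from the corresponding database
AF_COLUMNS <- c("af_1000g", "af_exac", "af_esp6500")

variant_columns <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "gene", "region", "effect",
    "aa_change", "quality", "tumor_depth", "tumor_alt", "normal_depth",
    "normal_alt", AF_COLUMNS, "dbsnp_id", "cosmic_id", "clinsig", "sift",
    "polyphen", "context3")
}

#' Construct a table of annotated variant calls
#'
#' The variant call table is the atom of every analysis stage: one row per
#' observed tumour (or normal) alteration per sample, annotated with gene,
#' region and consequence, evidence depths in tumour and matched normal,
#' population allele frequencies, known-variant identifiers, clinical
#' significance, protein-impact predictions and trinucleotide context.
#' Missing annotations are `NA` ("absent"), never sentinel numbers.
#'
#' @param df data.frame supplying the columns of `variant_columns()`; missing
#'   optional columns are filled with `NA`, extra columns are preserved.
#' @return validated data.frame of class `variant_calls`.
#' @export
variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  defaults <- list(
    gene = NA_character_, region = "unknown", effect = "other",
    aa_change = NA_character_, quality = NA_real_,
    tumor_depth = NA_integer_, tumor_alt = NA_integer_,
    normal_depth = NA_integer_, normal_alt = NA_integer_,
    af_1000g = NA_real_, af_exac = NA_real_, af_esp6500 = NA_real_,
    dbsnp_id = NA_character_, cosmic_id = NA_character_,
    clinsig = NA_character_, sift = NA_character_, polyphen = NA_character_,
    context3 = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }

  df$pos <- as.integer(df$pos)
  for (nm in c("quality", AF_COLUMNS)) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("tumor_depth", "tumor_alt", "normal_depth", "normal_alt")) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  for (nm in c("sample_id", "chrom", "gene", "region", "effect", "aa_change",
               "dbsnp_id", "cosmic_id", "clinsig", "sift", "polyphen",
               "context3")) {
    df[[nm]] <- as.character(df[[nm]])
  }
  for (nm in c("ref", "alt")) df[[nm]] <- toupper(as.character(df[[nm]]))
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_

  validate_variant_calls(df)
  df <- df[c(intersect(variant_columns(), names(df)),
             setdiff(names(df), variant_columns()))]
  class(df) <- unique(c("variant_calls", class(df)))
  df
}

validate_variant_calls <- function(df) {
  fail <- function(...) stop("invalid variant table: ", ...)
  if (any(is.na(df$pos)) || any(df$pos < 1L)) fail("positions must be >= 1 (1-based)")
  if (any(df$ref == df$alt)) fail("ref and alt alleles must differ")
  bad_region <- !df$region %in% VARIANT_REGIONS
  if (any(bad_region)) fail("unknown region value(s): ",
                            paste(unique(df$region[bad_region]), collapse = ", "))
  bad_eff <- !df$effect %in% VARIANT_EFFECTS
  if (any(bad_eff)) fail("unknown effect value(s): ",
                         paste(unique(df$effect[bad_eff]), collapse = ", "))
  if (any(!is.na(df$quality) & df$quality < 0)) fail("quality must be non-negative")
  ok_pair <- function(alt, depth) all(is.na(alt) | is.na(depth) | alt <= depth)
  if (!ok_pair(df$tumor_alt, df$tumor_depth)) fail("tumor_alt exceeds tumor_depth")
  if (!ok_pair(df$normal_alt, df$normal_depth)) fail("normal_alt exceeds normal_depth")
  for (nm in AF_COLUMNS) {
    v <- df[[nm]]
    if (any(!is.na(v) & (v < 0 | v > 1))) fail(nm, " outside [0, 1]")
  }
  if (any(!is.na(df$clinsig) & !df$clinsig %in% CLINSIG_LEVELS)) {
    fail("clinsig must be pathogenic/benign/vus or absent")
  }
  for (nm in c("sift", "polyphen")) {
    if (any(!is.na(df[[nm]]) & !df[[nm]] %in% IMPACT_LEVELS)) {
      fail(nm, " must be damaging/tolerated or absent")
    }
  }
  ctx <- df$context3[!is.na(df$context3)]
  if (any(nchar(ctx) != 3L)) fail("context3 must be 3 bases when present")
  snv_ctx <- !is.na(df$context3) & is_snv(df$ref, df$alt)
  if (any(snv_ctx)) {
    norm <- normalize_pyrimidine(df$ref[snv_ctx], df$alt[snv_ctx],
                                 df$context3[snv_ctx])
    if (any(substr(norm$context3, 2, 2) != norm$ref)) {
      fail("context3 middle base must equal the (pyrimidine-normalized) ref")
    }
  }
  invisible(df)
}

#' Construct per-sample metadata
#'
#' One row per patient: microsatellite-instability status, the callable
#' genome size in megabases used as the mutation-rate denominator, and any
#' clinical fields (age, gender, stage, ...) carried as extra columns.
#'
#' @param df data.frame with columns `sample_id`, `msi_status`,
#'   `callable_mb`; extra columns preserved.
#' @return validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(c("sample_id", "msi_status", "callable_mb"), names(df))
  if (length(missing)) {
    stop("sample metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$callable_mb <- as.numeric(df$callable_mb)
  if (any(!df$msi_status %in% MSI_LEVELS)) {
    stop("msi_status must be one of ", paste(MSI_LEVELS, collapse = ", "))
  }
  if (any(is.na(df$callable_mb) | df$callable_mb <= 0)) {
    stop("callable_mb must be positive for every sample")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  class(df) <- unique(c("sample_meta", class(df)))
  df
}

# genomic identity of a call, used for germline subtraction and recurrence
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# row-wise maximum AF over the configured databases; NA when absent from all
max_pop_af <- function(df, databases = AF_COLUMNS) {
  missing <- setdiff(databases, names(df))
  if (length(missing)) stop("unknown allele-frequency database column(s): ",
                            paste(missing, collapse = ", "))
  m <- as.matrix(df[databases])
  out <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}
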