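write_test_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           header = c("##fileformat=VCFv4.2",
                                      paste(c("#CHROM", "POS", "ID", "REF",
                                              "ALT", "QUAL", "FILTER",
                                              "INFO"), collapse = "\t"))) {
  writeLines(c(header, body), path)
  path
}

test_that("read_vcf parses an annotated record into a typed call", {
  path <- write_test_vcf(paste(
    "12", "25398284", ".", "C", "T", "60", "PASS",
    "GENE=KRAS;REGION=exonic;EFFECT=missense;AA=G12D;COSMIC=COSM521;DBSNP=rs121913529;CLNSIG=pathogenic;TDP=60;TAD=25;NDP=30;NAD=0",
    sep = "\t"))
  calls <- read_vcf(path, "C273T", "simple")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$chrom, "12")
  expect_equal(calls$pos, 25398284L)
  expect_equal(calls$ref, "C")
  expect_equal(calls$alt, "T")
  expect_equal(calls$gene, "KRAS")
  expect_equal(calls$aa_change, "G12D")
  expect_equal(calls$cosmic_id, "COSM521")
  expect_equal(calls$clinsig, "pathogenic")
  expect_equal(calls$quality, 60)
  expect_equal(calls$normal_depth, 30L)
  expect_equal(calls$normal_alt, 0L)
})

test_that("read_vcf returns an empty table for a header-only file and splits multi-allelic records", {
  empty <- read_vcf(write_test_vcf(character()), "S1")
  expect_s3_class(empty, "variant_calls")
  expect_equal(nrow(empty), 0L)

  path <- write_test_vcf(paste(
    "1", "100", ".", "C", "A,G", "50", "PASS",
    "GENE=G1;TAD=7,3;TDP=40", sep = "\t"))
  calls <- read_vcf(path, "S1")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$chrom, c("1", "1"))
  expect_equal(calls$pos, c(100L, 100L))
  expect_equal(calls$ref, c("C", "C"))
  expect_equal(calls$alt, c("A", "G"))
  expect_equal(calls$tumor_alt, c(7L, 3L))
})

test_that("read_vcf rejects a file without a VCF header and unknown dialects", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("#CHROM\tPOS", "1\t2"), bad)
  expect_error(read_vcf(bad, "S1"), "line 1")
  good <- write_test_vcf(character())
  expect_error(read_vcf(good, "S1", annotation_dialect = "vep"))
})

test_that("annovar dialect recodes region, effect and impact vocabularies", {
  path <- write_test_vcf(paste(
    "7", "140453136", ".", "A", "T", "55", "PASS",
    paste0("Gene.refGene=BRAF;Func.refGene=exonic;",
           "ExonicFunc.refGene=nonsynonymous_SNV;AAChange.refGene=V600E;",
           "1000g2015aug_all=0.001;SIFT_pred=D;Polyphen2_HDIV_pred=B;",
           "CLNSIG=Pathogenic"),
    sep = "\t"))
  calls <- read_vcf(path, "S1", "annovar")
  expect_equal(calls$effect, "missense")
  expect_equal(calls$region, "exonic")
  expect_equal(calls$sift, "damaging")
  expect_equal(calls$polyphen, "tolerated")
  expect_equal(calls$clinsig, "pathogenic")
  expect_equal(calls$af_1000g, 0.001)
})

test_that("write_vcf/read_vcf round-trips call fields", {
  calls <- make_calls(3L, pos = c(5L, 9L, 12L), ref = c("C", "G", "T"),
                      alt = c("T", "A", "G"), aa_change = c("A1B", NA, "C3D"),
                      dbsnp_id = c("rs1", NA, NA))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf(path, "S1")
  for (col in c("chrom", "pos", "ref", "alt", "gene", "aa_change",
                "quality", "dbsnp_id", "effect", "region")) {
    expect_equal(back[[col]], calls[[col]], info = col)
  }
})

test_that("write_table/read_table round-trips every schema's field values", {
  calls <- table4_calls()
  path <- tempfile(fileext = ".tsv")
  write_table(calls, path)
  back <- read_table(path, "variants")
  for (col in variant_columns()) expect_equal(back[[col]], calls[[col]],
                                              info = col)

  meta <- sample_meta(data.frame(sample_id = c("a", "b"),
                                 msi_status = c("MSI-H", "MSS"),
                                 callable_mb = c(30, 28.5),
                                 age = c(64L, 70L)))
  write_table(meta, path)
  back <- read_table(path, "metadata")
  expect_equal(back$callable_mb, meta$callable_mb)
  expect_equal(back$age, meta$age)  # extra columns preserved

  rules <- fixture_rules()
  write_table(rules, path)
  back <- read_table(path, "rules")
  expect_equal(back$drug, rules$drug)
  expect_equal(back$pattern_payload, rules$pattern_payload)
})

test_that("read_table validates schemas", {
  path <- tempfile(fileext = ".tsv")
  write_table(fixture_table4(), path)
  t4 <- utils::read.delim(path)
  expect_equal(nrow(t4), 16L)

  writeLines("sample_id\tchrom\tpos\tref\talt", path)  # header only
  expect_equal(nrow(read_table(path, "variants")), 0L)

  writeLines(c("sample_id\tchrom\tchrom", "a\t1\t2"), path)
  expect_error(read_table(path, "variants"), "duplicated header")

  writeLines(c("sample_id\tchrom", "a\t1"), path)
  expect_error(read_table(path, "variants"), "missing required column")
})

test_that("signature matrix reading canonicalizes row order and validates sums", {
  ref <- reference_signatures()
  path <- tempfile(fileext = ".tsv")
  write_signature_matrix(ref, path)
  back <- read_signature_matrix(path)
  expect_equal(unclass(back), unclass(ref), tolerance = 1e-12)

  # permuted rows give the same matrix (canonicalization is order-free)
  df <- utils::read.delim(path, check.names = FALSE)
  set.seed(1)
  write_table(df[sample.int(96), ], path)
  perm <- read_signature_matrix(path)
  expect_identical(rownames(perm), channel_labels())
  expect_equal(unclass(perm), unclass(ref), tolerance = 1e-12)

  # a flat signature is accepted unchanged
  flat <- matrix(1 / 96, 96, 1, dimnames = list(channel_labels(), "Flat"))
  expect_equal(as.numeric(signature_matrix(flat)), rep(1 / 96, 96))

  # columns far from sum 1, negative entries, wrong row count all fail
  off <- unclass(ref); off[, 1] <- off[, 1] * 0.90
  expect_error(signature_matrix(off), "sum to 1")
  neg <- unclass(ref); neg[1, 1] <- -0.01
  expect_error(signature_matrix(neg), "non-negative")
  df96 <- utils::read.delim(path, check.names = FALSE)
  write_table(df96[-1, ], path)
  expect_error(read_signature_matrix(path), "96 data rows")
})

test_that("variant table invariants are enforced", {
  expect_error(make_calls(pos = 0L), "1-based")
  expect_error(make_calls(ref = "C", alt = "C"), "differ")
  expect_error(make_calls(tumor_depth = 10L, tumor_alt = 11L), "exceeds")
  expect_error(make_calls(af_1000g = 1.2), "af_1000g")
  expect_error(make_calls(region = "coding"), "region")
  expect_error(make_calls(context3 = "AGT"), "middle base")
  ok <- make_calls(ref = "G", alt = "A", context3 = "AGT")  # purine strand
  expect_equal(nrow(ok), 1L)
})
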