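test_that("quality filter is strictly above the threshold", {
  calls <- make_calls(3L, quality = c(29.9, 30, 30.1))
  kept <- filter_quality(calls)
  expect_equal(kept$quality, 30.1)
  expect_equal(nrow(filter_quality(calls[0, ])), 0L)
  expect_error(filter_quality(make_calls(quality = NA)), "quality is absent")

  set.seed(5)
  many <- make_calls(1000L, quality = runif(1000, 0, 60))
  expect_equal(nrow(filter_quality(many)), sum(many$quality > 30))
})

test_that("population AF filter removes only variants common in some database", {
  calls <- make_calls(4L, af_1000g = c(0.06, 0.05, NA, NA),
                      af_exac = c(NA, NA, NA, 0.2))
  kept <- filter_population_af(calls)
  # 0.06 -> removed (strict >), 0.05 -> kept, all-absent -> kept, 0.2 -> removed
  expect_equal(kept$pos, c(2L, 3L))
  sim <- default_sim()
  tv <- sim$truth$variants
  germ_keys <- paste(tv$sample_id[tv$label == "germline_common"],
                     tv$chrom[tv$label == "germline_common"],
                     tv$pos[tv$label == "germline_common"])
  kept <- filter_population_af(sim$tumour)
  kept_keys <- paste(kept$sample_id, kept$chrom, kept$pos)
  expect_length(intersect(kept_keys, germ_keys), 0L)
  expect_equal(nrow(sim$tumour) - nrow(kept), length(germ_keys))
})

test_that("functional filter keeps exonic/splicing, gene-annotated, consequential calls", {
  syn <- make_calls(effect = "synonymous")
  expect_equal(nrow(filter_functional(syn)), 0L)
  intronic <- make_calls(region = "intronic")  # missense but wrong region
  expect_equal(nrow(filter_functional(intronic)), 0L)
  no_gene <- make_calls(gene = NA)
  expect_equal(nrow(filter_functional(no_gene)), 0L)

  set.seed(6)
  mixed <- make_calls(200L,
                      region = sample(c("exonic", "splicing", "intronic",
                                        "intergenic"), 200, TRUE),
                      effect = sample(c("missense", "synonymous", "other",
                                        "nonsense"), 200, TRUE),
                      gene = sample(c("G1", NA), 200, TRUE))
  kept <- filter_functional(mixed)
  brute <- mixed[mixed$region %in% c("exonic", "splicing") &
                   !is.na(mixed$gene) &
                   !mixed$effect %in% c("synonymous", "other"), ]
  expect_equal(call_keys(kept), call_keys(brute))
})

test_that("germline subtraction removes exactly the shared genomic changes", {
  tum <- make_calls(3L, pos = c(1L, 2L, 3L))
  expect_equal(nrow(subtract_germline(tum, tum)), 0L)
  norm <- make_calls(2L, pos = c(10L, 11L))
  expect_equal(nrow(subtract_germline(tum, norm)), 3L)

  sim <- default_sim()
  survivors <- subtract_germline(sim$tumour, sim$normal)
  removed <- setdiff(call_keys(sim$tumour), call_keys(survivors))
  tv <- sim$truth$variants
  germ <- tv[tv$label == "germline_common", ]
  expect_setequal(removed,
                  paste(germ$sample_id, germ$chrom, germ$pos, germ$ref,
                        germ$alt))
})

test_that("germline subtraction refuses mismatched patient pairs", {
  tum <- make_calls(patient_id = "P1")
  norm <- make_calls(patient_id = "P2")
  expect_error(subtract_germline(tum, norm), "different patients")
})

test_that("novelty needs both catalogs absent and confident normal coverage", {
  t4 <- classify_novel(table4_calls())
  novel_aa <- sort(unique(t4$aa_change[t4$novel]))
  expect_equal(novel_aa, c("E172Q", "L12755F", "L12755S", "R100H"))
  expect_true(all(!t4$novel[!is.na(t4$cosmic_id) | !is.na(t4$dbsnp_id)]))

  shallow <- classify_novel(make_calls(normal_depth = 9L, normal_alt = 0L))
  expect_false(shallow$novel)
  contaminated <- classify_novel(make_calls(normal_depth = 10L,
                                            normal_alt = 1L))
  expect_false(contaminated$novel)
  clean <- classify_novel(make_calls(normal_depth = 10L, normal_alt = 0L))
  expect_true(clean$novel)
})

test_that("the full chain recovers the simulated somatic truth with exact counts", {
  sim <- default_sim()
  pri <- run_prioritization(sim$tumour, sim$normal)
  expect_setequal(call_keys(pri$calls), truth_somatic_keys(sim))

  # trace bookkeeping: counts chain and removals account for the difference
  tr <- pri$trace
  expect_equal(tr$stage, c("quality", "population_af", "functional",
                           "germline_subtraction", "novelty"))
  expect_true(all(tr$out <= tr$`in`))
  expect_equal(tr$`in`[-1], tr$out[-length(tr$out)])
  expect_equal(nrow(sim$tumour) - nrow(pri$calls), sum(tr$removed))

  # output ordering contract
  expect_false(is.unsorted(pri$calls$sample_id))
})

test_that("disabled thresholds reduce the chain to germline subtraction", {
  sim <- default_sim()
  cfg <- filter_config(min_quality = -Inf, max_pop_af = 1,
                       keep_regions = somascape:::VARIANT_REGIONS,
                       drop_effects = character(0))
  pri <- run_prioritization(sim$tumour, sim$normal, cfg)
  expect_setequal(call_keys(pri$calls),
                  call_keys(subtract_germline(sim$tumour, sim$normal)))
})

test_that("an empty cohort yields an empty result and a zero trace", {
  empty <- make_calls()[0, ]
  pri <- run_prioritization(empty, empty)
  expect_equal(nrow(pri$calls), 0L)
  expect_equal(nrow(pri$trace), 5L)
  expect_true(all(pri$trace$`in` == 0L & pri$trace$out == 0L))
})

test_that("keeping a no-gene intronic call requires lifting both predicates", {
  # functional filter needs region AND gene AND effect simultaneously
  call <- make_calls(region = "intronic", gene = NA, effect = "synonymous")
  cfg <- filter_config(keep_regions = somascape:::VARIANT_REGIONS,
                       drop_effects = character(0))
  expect_equal(nrow(filter_functional(call, cfg)), 0L)  # gene still missing
})
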