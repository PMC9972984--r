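test_that("pattern kinds match their intended alteration classes", {
  rules <- fixture_rules()

  rnf43 <- make_calls(gene = "RNF43", effect = "frameshift_del",
                      aa_change = "G156fs", ref = "CA", alt = "C")
  rep <- match_rules(rnf43, rules)
  expect_true(any(grepl("Porcupine", rep$matches$drug)))
  expect_equal(unique(rep$matches$effect), "responsive")

  g12d <- make_calls(gene = "KRAS", aa_change = "G12D")
  m <- match_rules(g12d, rules)$matches
  expect_true(any(m$effect == "resistant" & grepl("EGFR mAb", m$drug)))
  expect_true(any(m$effect == "responsive" & grepl("MEK", m$drug)))

  syn_apc <- make_calls(gene = "APC", effect = "synonymous")
  expect_equal(nrow(match_rules(syn_apc, rules)$matches), 0L)

  # exact_aa tolerates the p. prefix and case
  g12d_p <- make_calls(gene = "KRAS", aa_change = "p.g12d")
  expect_true(any(grepl("EGFR mAb", match_rules(g12d_p, rules)$matches$drug)))
})

test_that("position_class rules match by affected residue", {
  rules <- validate_rules(data.frame(
    gene = "RNF43", pattern_kind = "position_class",
    pattern_payload = "100-300", drug = "X", effect = "responsive",
    evidence = "pre_clinical", disease = "COREAD",
    stringsAsFactors = FALSE))
  inside <- make_calls(gene = "RNF43", aa_change = "G156fs")
  outside <- make_calls(gene = "RNF43", aa_change = "G659fs")
  expect_equal(nrow(match_rules(inside, rules)$matches), 1L)
  expect_equal(nrow(match_rules(outside, rules)$matches), 0L)
})

test_that("matching is independent of call and rule order", {
  calls <- table4_calls()
  rules <- fixture_rules()
  set.seed(41)
  shuffled <- match_rules(calls[sample.int(nrow(calls)), ],
                          rules[sample.int(nrow(rules)), ])
  straight <- match_rules(calls, rules)
  expect_identical(straight$matches, shuffled$matches)
  expect_identical(straight$patients, shuffled$patients)
})

test_that("the bundled rules reproduce the cohort's reported annotations", {
  rep <- match_rules(table4_calls(), fixture_rules())
  m <- rep$matches

  egfr <- m[m$effect == "resistant" & grepl("EGFR mAb inhibitors", m$drug), ]
  expect_setequal(egfr$sample_id[egfr$aa_change == "G12D"],
                  c("C273T", "C469T", "C547T", "C570T", "C649T", "C663T"))

  braf <- m[m$gene == "BRAF" & m$effect == "responsive", ]
  expect_setequal(braf$sample_id, c("C396T", "C449T", "C474T"))

  pik3ca <- m[m$gene == "PIK3CA" & grepl("PI3K", m$drug), ]
  expect_setequal(pik3ca$sample_id, c("C396T", "C398T"))

  apc <- m[m$gene == "APC", ]
  expect_true(all(grepl("Tankyrase", apc$drug)))
  expect_true(all(apc$evidence == "pre_clinical"))
  expect_equal(nrow(apc), 6L)  # three truncating variants x two carriers
})

test_that("matches sort by evidence strength", {
  rep <- match_rules(table4_calls(), fixture_rules())
  lv <- match(rep$matches$evidence,
              c("FDA", "NCCN", "late_trials", "early_trials", "case_report",
                "pre_clinical"))
  expect_false(is.unsorted(lv))
})

test_that("actionability summary counts patients, not matches", {
  calls <- do.call(rbind, lapply(1:50, function(i) {
    if (i <= 44) make_calls(sample_id = sprintf("P%02d", i), gene = "KRAS",
                            aa_change = "G12D")
    else make_calls(sample_id = sprintf("P%02d", i), gene = "GENE_X")
  }))
  rep <- match_rules(variant_calls(calls), fixture_rules())
  s <- summarize_actionability(rep, 50L)
  expect_equal(s$fraction_actionable, 0.88)
  expect_equal(s$n_actionable, 44L)

  empty <- match_rules(make_calls()[0, ], fixture_rules())
  expect_equal(summarize_actionability(empty, 50L)$fraction_actionable, 0)

  sim <- default_sim()
  pri <- run_prioritization(sim$tumour, sim$normal)
  rep <- match_rules(pri$calls, fixture_rules())
  s <- summarize_actionability(rep, nrow(sim$meta))
  brute <- length(unique(rep$matches$sample_id)) / nrow(sim$meta)
  expect_equal(s$fraction_actionable, brute)
})

test_that("malformed rules are rejected with their row number", {
  bad <- data.frame(gene = "KRAS", pattern_kind = "exact_aa",
                    pattern_payload = NA, drug = "X", effect = "responsive",
                    evidence = "FDA", disease = "COREAD",
                    stringsAsFactors = FALSE)
  expect_error(validate_rules(bad), "row 1")
  bad$pattern_payload <- "G12D"; bad$evidence <- "rumour"
  expect_error(validate_rules(bad), "evidence")
})
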