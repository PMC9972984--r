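test_that("mutation rate is count over callable megabases", {
  expect_equal(mutation_rate(0, 30), 0)
  expect_equal(mutation_rate(120, 10), 12)
  expect_equal(round(mutation_rate(7319, 30), 2), 243.97)
  expect_error(mutation_rate(10, 0), "positive")
})

test_that("hypermutation is strictly above 12 mutations per Mb", {
  expect_true(classify_hypermutated(243.97))
  expect_false(classify_hypermutated(12.0))
  expect_false(classify_hypermutated(3.8))
  expect_true(classify_hypermutated(12.0000001))
})

test_that("burden table accounts for every survivor and every sample", {
  sim <- default_sim()
  pri <- run_prioritization(sim$tumour, sim$normal)
  burden <- burden_table(pri$calls, sim$meta)
  expect_equal(sum(burden$somatic_count), nrow(pri$calls))
  expect_equal(burden$sample_id, sim$meta$sample_id)
  expect_equal(burden$rate_per_mb,
               burden$somatic_count / burden$callable_mb)
  expect_equal(burden$hypermutated, burden$rate_per_mb > 12)
})

test_that("MSI group statistics match exact enumeration on small groups", {
  mk_burden <- function(h, l) {
    data.frame(sample_id = paste0("S", seq_along(c(h, l))),
               msi_status = rep(c("MSI-H", "MSI-L"), c(length(h), length(l))),
               somatic_count = 1L, callable_mb = 1,
               rate_per_mb = c(h, l),
               hypermutated = c(h, l) > 12, stringsAsFactors = FALSE)
  }
  st <- msi_group_stats(mk_burden(c(50, 60, 70), c(3, 4, 5)))
  expect_equal(unname(st$medians[c("MSI-H", "MSI-L")]), c(60, 4))
  expect_equal(st$rank_p, oracle_rank_p(c(50, 60, 70), c(3, 4, 5)))

  # identical rate vectors: no evidence of a shift
  st_tie <- msi_group_stats(mk_burden(c(3, 4, 5), c(3, 4, 5)))
  expect_equal(st_tie$rank_p, 1)

  set.seed(8)
  for (n1 in c(2L, 4L, 6L, 8L)) {
    for (n2 in c(3L, 5L, 8L)) {
      x <- sample(seq_len(100), n1); y <- sample(setdiff(seq_len(200), x), n2)
      st <- msi_group_stats(mk_burden(x, y))
      expect_equal(st$rank_p, oracle_rank_p(x, y),
                   info = paste(n1, n2), tolerance = 1e-12)
    }
  }
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  tab <- matrix(c(4L, 1L, 1L, 44L), 2, byrow = TRUE)
  burden <- data.frame(
    sample_id = paste0("S", 1:50),
    msi_status = rep(c("MSI-H", "MSS"), c(5, 45)),
    somatic_count = 1L, callable_mb = 1,
    rate_per_mb = 1,
    hypermutated = c(rep(TRUE, 4), FALSE, TRUE, rep(FALSE, 44)),
    stringsAsFactors = FALSE)
  st <- suppressWarnings(msi_group_stats(burden))  # no MSI-L group here
  expect_equal(matrix(as.integer(st$fisher_table), 2), tab)
  expect_equal(st$fisher_p, oracle_fisher_p(tab), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:10) {
    cells <- matrix(sample(0:8, 4, TRUE), 2)
    if (sum(cells) == 0) next
    expect_equal(stats::fisher.test(cells)$p.value, oracle_fisher_p(cells),
                 tolerance = 1e-10, info = paste(cells, collapse = ","))
  }
})

test_that("variant class distribution is an exhaustive recount", {
  one <- variant_class_distribution(make_calls(effect = "synonymous"))
  expect_equal(sum(one$effect$count), 1L)
  expect_equal(one$effect$count[one$effect$effect == "synonymous"], 1L)

  sim <- default_sim()
  calls <- sim$tumour[1:500, ]
  dist <- variant_class_distribution(calls)
  expect_equal(sum(dist$effect$count), 500L)
  for (e in dist$effect$effect) {
    expect_equal(dist$effect$count[dist$effect$effect == e],
                 sum(calls$effect == e), info = e)
  }
  # missense dominates the cohort's consequence classes
  full <- variant_class_distribution(sim$tumour)
  expect_equal(full$effect$effect[which.max(full$effect$count)], "missense")
})

test_that("recurrence is keyed on genomic change with distinct carriers", {
  rec <- recurrent_variants(table4_calls())
  expect_equal(nrow(rec), 16L)
  expect_equal(rec$carrier_count[rec$gene == "KRAS" & rec$aa_change == "G12D"], 6L)
  expect_equal(rec$carrier_count[rec$gene == "ACVR2A"], 4L)
  expect_equal(rec$carrier_count[rec$gene == "TP53" & rec$aa_change == "R175H"], 4L)
  expect_true(all(rec$carrier_count >= 2L))
  expect_false(is.unsorted(-rec$carrier_count))

  unique_calls <- make_calls(5L, sample_id = paste0("S", 1:5), pos = 1:5)
  expect_equal(nrow(recurrent_variants(unique_calls)), 0L)

  cfg <- cohort_config(n_samples = 10L, callable_mb = 2,
                       hotspots = data.frame(default_hotspots()[1, ],
                                             stringsAsFactors = FALSE),
                       germline_common_rate = 0, mss_outlier_rate = NULL,
                       seed = 13L)
  cfg$hotspots$target_carrier_count <- 3L
  sim <- simulate_cohort(cfg)
  rec <- recurrent_variants(sim$tumour)
  planted <- rec[rec$pos == 25398284L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$carrier_count, 3L)
})

test_that("gene frequency counts each carrier sample once", {
  freq <- gene_mutation_frequency(table4_calls(), 50L)
  expect_equal(freq$frequency[freq$gene == "ACVR2A"], 0.08)
  expect_equal(nrow(freq[freq$gene == "NOTHERE", ]), 0L)

  # a sample with two hits in one gene counts once
  dup <- make_calls(2L, pos = c(1L, 2L), gene = "G1")
  expect_equal(gene_mutation_frequency(dup, 10L)$frequency, 0.1)

  sim <- default_sim()
  calls <- sim$tumour
  freq <- gene_mutation_frequency(calls, nrow(sim$meta))
  for (g in freq$gene[1:5]) {
    expect_equal(freq$carriers[freq$gene == g],
                 length(unique(calls$sample_id[!is.na(calls$gene) &
                                                 calls$gene == g])),
                 info = g)
  }
})

test_that("pathogenic accounting deduplicates shared variants", {
  expect_equal(unname(count_pathogenic(table4_calls())), c(11L, 5L))
  expect_equal(unname(count_pathogenic(make_calls())), c(0L, 0L))
  shared <- make_calls(3L, sample_id = c("a", "b", "c"), pos = 7L,
                       clinsig = "pathogenic")
  expect_equal(unname(count_pathogenic(shared)), c(1L, 1L))
})
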