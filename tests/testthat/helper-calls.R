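# quick variant-call builder with passing defaults; override any field
make_calls <- function(n = 1L, sample_id = "S1", chrom = "1",
                       pos = seq_len(n), ref = "C", alt = "T",
                       gene = "GENE1", region = "exonic",
                       effect = "missense", quality = 60, ...) {
  variant_calls(data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                           ref = ref, alt = alt, gene = gene, region = region,
                           effect = effect, quality = quality, ...,
                           stringsAsFactors = FALSE))
}

# one simulated default cohort shared across test files (built lazily)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config(seed = 101L))
    cache
  }
})

truth_somatic_keys <- function(sim) {
  tv <- sim$truth$variants
  tv <- tv[tv$label != "germline_common", ]
  paste(tv$sample_id, tv$chrom, tv$pos, tv$ref, tv$alt)
}

call_keys <- function(calls) {
  paste(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt)
}
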