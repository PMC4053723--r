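# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small cohort for fast unit tests
small_cohort <- function() {
  memo("small", simulate_cohort(cohort_config(n_females_per_set = 6,
                                              n_autosomal_probes = 800,
                                              seed = 42)))
}

# study-scale cohort: 3 sets x 20 females, 200 X genes (100 subject-training
# + 30 escape-training), noise sd 0.02 above the intensity threshold
study_cohort <- function() {
  memo("study", simulate_cohort(cohort_config(seed = 20260930)))
}

study_pipeline <- function() {
  memo("study_pipe", {
    co <- study_cohort()
    suppressWarnings(run_xci_pipeline(
      co$probes, co$annotation, co$training$subject, co$training$escape,
      n_permutations = 200, seed = 20260930))
  })
}

# minimal hand-rolled probe table row builder
probe_rows <- function(probe_id, gene, sample_id, frac_cdna,
                       sample_set = "S1", informative = TRUE,
                       intensity = 1e4, frac_gdna = 0.5, pos = 1000L,
                       chrom = "chrX", channel = "expression") {
  tibble::tibble(probe_id = probe_id, gene = gene, chrom = chrom,
                 pos = pos, sample_id = sample_id, sex = "F",
                 sample_set = sample_set, informative = informative,
                 intensity = intensity, frac_cdna = frac_cdna,
                 frac_gdna = frac_gdna, channel = channel)
}
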