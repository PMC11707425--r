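# Programmatic fixtures shared across test files.

# Desk-scale cohort for module-level tests (smaller than the generator
# defaults to keep the suite quick); memoised per seed.
.sim_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 101L, ...) {
  sim_config(n_genes = 600L, n_samples = 150L, n_components = 5L,
             n_immune_components = 2L, support_size = 25L,
             n_drivers = 10L, n_driver_links = 5L, n_risk_genes = 6L,
             seed = seed, ...)
}

small_sim <- function(seed = 101L) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_cohort(small_sim_config(seed))
  .sim_cache[[key]]
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

expression_fixture <- function() {
  write_tmp(c(
    "gene\ts1\ts2",
    "TP53\t1.5\t2.5",
    "BRAF\t0.1\t0.9",
    "NRAS\t3.0\t1.0"
  ))
}

maf_fixture <- function() {
  write_tmp(c(
    paste("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
          sep = "\t"),
    "TP53\tS1\tMissense_Mutation",
    "TP53\tS2\tSilent",
    "BRAF\tS1\tNonsense_Mutation",
    "BRAF\tS1\tMissense_Mutation",
    "BRAF\tS2\tFrame_Shift_Del"
  ), ext = ".maf")
}

gmt_fixture <- function() {
  write_tmp(c(
    "setA\tdescA\tTP53\tBRAF\tTP53",
    "setB\tdescB\tNRAS\tKRAS"
  ), ext = ".gmt")
}

# tiny random survival instance for oracle comparisons
random_survival_instance <- function(n, allow_score_ties = TRUE) {
  list(
    scores = if (allow_score_ties) sample(1:4, n, replace = TRUE)
             else runif(n),
    times = runif(n, 0, 10),          # continuous: no time ties
    events = rbinom(n, 1, 0.7)
  )
}
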