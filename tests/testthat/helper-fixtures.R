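# Small in-code fixtures shared across test files.

tiny_manifest <- function() {
  data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05", "rs01"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    pos = c(100L, 150L, 250L, 100L, 500L, 900L),
    gene_regions = c("TSS200", "Body", "", "TSS200;1stExon", "", ""),
    cgi_relation = c("Island", "Shore", "OpenSea", "Island", "OpenSea",
                     "OpenSea"),
    is_snp = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

make_beta <- function(values, probes, samples) {
  matrix(values, nrow = length(probes), ncol = length(samples),
         dimnames = list(probes, samples))
}

random_beta <- function(n_probes, samples, seed, na_frac = 0) {
  set.seed(seed)
  m <- matrix(runif(n_probes * length(samples)), n_probes,
              length(samples),
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              samples))
  if (na_frac > 0)
    m[sample(length(m), round(na_frac * length(m)))] <- NA
  m
}

small_design <- function(...) {
  args <- list(...)
  defaults <- list(n_probes = 2000L, n_snp_probes = 15L,
                   n_spatial_patients = 3L, biopsies_min = 3L,
                   biopsies_max = 4L, n_temporal_patients = 4L,
                   spatial_dmps_per_biopsy = 40L, seed = 11L)
  do.call(simulation_design, utils::modifyList(defaults, args))
}
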