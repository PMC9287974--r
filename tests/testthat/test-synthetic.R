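test_that("manifest category frequencies follow the design", {
  d <- simulation_design(seed = 5L)
  man <- simulate_manifest(d)
  expect_equal(nrow(man), d$n_probes + d$n_snp_probes)
  expect_equal(sum(man$is_snp), d$n_snp_probes)
  # empirical CGI frequencies within 3 binomial standard errors
  n <- nrow(man)
  for (cat in names(d$cgi_freqs)) {
    p <- d$cgi_freqs[[cat]]
    expect_lt(abs(mean(man$cgi_relation == cat) - p),
              3 * sqrt(p * (1 - p) / n))
  }
  igr_p <- d$gene_region_freqs[["IGR"]]
  expect_lt(abs(mean(man$gene_regions == "") - igr_p),
            3 * sqrt(igr_p * (1 - igr_p) / n))
  # positions sorted within chromosomes
  for (ch in unique(man$chrom))
    expect_true(!is.unsorted(man$pos[man$chrom == ch]))

  all_sea <- simulation_design(
    cgi_freqs = c(Island = 0, Shore = 0, Shelf = 0, OpenSea = 1),
    n_probes = 500L, seed = 5L)
  expect_true(all(simulate_manifest(all_sea)$cgi_relation == "OpenSea"))
})

test_that("equal seeds reproduce the cohort bit-identically, different seeds do not", {
  d <- small_design()
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$segments, c2$segments)
  c3 <- simulate_cohort(d, seed = 99L)
  expect_false(identical(c1$beta, c3$beta))
  expect_false(identical(
    c1$truth$patients$SP01$injected,
    c3$truth$patients$SP01$injected))
})

test_that("pure noiseless biopsies are identical when nothing is injected", {
  d <- small_design(spatial_dmps_per_biopsy = 0L, noise_sd = 0,
                    purity_range = c(1, 1), hd_per_patient = 0L,
                    n_temporal_patients = 0L)
  co <- simulate_cohort(d)
  ss <- co$sheet$sample_id[co$sheet$patient_id == "SP01"]
  for (s in ss[-1]) expect_identical(co$beta[, ss[1]], co$beta[, s])
})

test_that("injected shifts are exactly +/- effect size without noise, attenuated by purity", {
  d <- small_design(noise_sd = 0, purity_range = c(1, 1),
                    n_temporal_patients = 0L)
  co <- simulate_cohort(d)
  pr <- co$truth$patients$SP01
  s1 <- pr$samples[1]; s2 <- pr$samples[2]
  delta <- co$beta[, s2] - co$beta[, s1]
  inj <- union(pr$injected[[s1]], pr$injected[[s2]])
  expect_true(all(abs(abs(delta[inj]) - d$dmp_effect_size) < 1e-12))
  non_inj <- setdiff(rownames(co$beta), inj)
  expect_true(all(delta[non_inj] == 0 |
                    non_inj %in% unlist(pr$deleted)))

  # shared purity p makes the observed shift exactly p * effect
  dp <- small_design(noise_sd = 0, purity_range = c(0.8, 0.8),
                     n_temporal_patients = 0L)
  cop <- simulate_cohort(dp)
  prp <- cop$truth$patients$SP01
  inj2 <- prp$injected[[prp$samples[2]]]
  delta2 <- cop$beta[inj2, prp$samples[2]] - cop$beta[inj2, prp$samples[1]]
  expect_true(all(abs(abs(delta2) - 0.8 * dp$dmp_effect_size) < 1e-12))
})

test_that("relapse alteration counts follow the Poisson accumulation model", {
  d <- simulation_design(n_probes = 4000L, n_snp_probes = 10L,
                         n_spatial_patients = 0L,
                         n_temporal_patients = 25L,
                         dmp_rate_per_day = 0.5, rate_sdlog = 0,
                         interval_range_days = c(300, 300), seed = 21L)
  co <- simulate_cohort(d)
  counts <- vapply(co$truth$patients, `[[`, numeric(1),
                   "n_injected_relapse")
  # mean of 25 Poisson(150) draws within 3 * sqrt(150 / 25)
  expect_lt(abs(mean(counts) - 150), 3 * sqrt(150 / 25))
})

test_that("SNP probes carry patient-constant tri-modal genotypes", {
  d <- small_design()
  co <- simulate_cohort(d)
  snp <- co$manifest$probe_id[co$manifest$is_snp]
  pr <- co$truth$patients$SP01
  g <- unlist(pr$genotypes)[snp]
  expect_true(all(g %in% c(0.05, 0.5, 0.95)))
  for (s in pr$samples)
    expect_true(all(abs(co$beta[snp, s] - g) < 6 * d$noise_sd + 1e-12))
})

test_that("ground-truth deletions map to sub-threshold segments and are disjoint from injections", {
  d <- small_design()
  co <- simulate_cohort(d)
  expect_true(all(co$segments$seg_mean < -0.4))
  for (pr in co$truth$patients$patients) {
    expect_length(intersect(unlist(pr$injected), unlist(pr$deleted)), 0)
  }
  # segment coordinates cover exactly the deleted probes
  for (pid in names(co$truth$patients)) {
    pr <- co$truth$patients[[pid]]
    for (s in names(pr$deleted)) {
      dels <- pr$deleted[[s]]
      if (is.null(dels) || length(dels) == 0) next
      seg <- co$segments[co$segments$sample == s, ]
      idx <- match(dels, co$manifest$probe_id)
      covered <- mapply(function(ch, p) any(seg$chrom == ch &
                                              seg$start <= p & seg$end >= p),
                        co$manifest$chrom[idx], co$manifest$pos[idx])
      expect_true(all(covered))
    }
  }
})

test_that("written cohorts are read back identically", {
  d <- small_design(n_probes = 300L, n_snp_probes = 5L,
                    n_spatial_patients = 2L, n_temporal_patients = 2L,
                    spatial_dmps_per_biopsy = 10L,
                    dmp_rate_per_day = 0.05,
                    interval_range_days = c(50, 200))
  co <- simulate_cohort(d)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_equal(read_beta_matrix(paths["beta"]), co$beta, tolerance = 1e-12)
  expect_equal(read_probe_manifest(paths["manifest"]), co$manifest)
  seg <- read_seg(paths["segments"])
  expect_equal(seg[order(seg$sample, seg$chrom, seg$start), ],
               co$segments[order(co$segments$sample, co$segments$chrom,
                                 co$segments$start), ],
               ignore_attr = TRUE)
})
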