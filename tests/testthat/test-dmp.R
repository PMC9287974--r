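test_that("copy-number filter removes deleted and SNP probes with a strict threshold", {
  man <- tiny_manifest()
  no_seg <- data.frame(sample = character(), chrom = character(),
                       start = integer(), end = integer(),
                       seg_mean = numeric())
  expect_setequal(apply_cna_filter(man, no_seg, "S1"),
                  man$probe_id[!man$is_snp])

  seg <- data.frame(sample = "S1", chrom = "chr1", start = 100L,
                    end = 200L, seg_mean = -0.6)
  kept <- apply_cna_filter(man, seg, "S1")
  expect_false("cg01" %in% kept)  # chr1:100
  expect_false("cg02" %in% kept)  # chr1:150
  expect_true("cg03" %in% kept)   # chr1:250
  expect_true("cg04" %in% kept)   # other chromosome

  # exactly at the threshold: retained (strict inequality)
  seg$seg_mean <- -0.4
  expect_true(all(c("cg01", "cg02") %in% apply_cna_filter(man, seg, "S1")))

  # segments of unlisted samples do not remove anything
  seg$seg_mean <- -0.9
  expect_true("cg01" %in% apply_cna_filter(man, seg, "S2"))
})

test_that("DMP calling applies a strict threshold on the beta difference", {
  beta <- make_beta(c(0, 0.5, 0.2, 1, 0.6, 0.5), c("p1", "p2", "p3"),
                    c("A", "B"))
  res <- call_dmps(beta, "A", "B", c("p1", "p2", "p3"), threshold = 0.3)
  expect_equal(res$dmp_probe_ids, "p1")   # p3 has delta exactly 0.30
  expect_equal(unname(res$delta), 1)
  expect_equal(res$retained_probe_count, 3L)

  same <- call_dmps(beta, "A", "A", c("p1", "p2", "p3"))
  expect_length(same$dmp_probe_ids, 0)
  expect_error(call_dmps(beta, "A", "nope", c("p1")), "unknown sample")
})

test_that("DMP calling matches an exhaustive scan, is symmetric and threshold-monotone", {
  for (seed in c(3, 17, 31)) {
    beta <- random_beta(300, c("A", "B"), seed = seed, na_frac = 0.05)
    retained <- sample(rownames(beta), 250)
    for (thr in c(0.2, 0.3, 0.5)) {
      res <- call_dmps(beta, "A", "B", retained, thr)
      expect_setequal(res$dmp_probe_ids,
                      bf_call_dmps(beta, "A", "B", retained, thr))
    }
    ab <- call_dmps(beta, "A", "B", retained)
    ba <- call_dmps(beta, "B", "A", retained)
    expect_setequal(ab$dmp_probe_ids, ba$dmp_probe_ids)
    expect_equal(ab$delta[ab$dmp_probe_ids], -ba$delta[ab$dmp_probe_ids])
    # raising the threshold never adds DMPs
    lo <- call_dmps(beta, "A", "B", retained, 0.25)$dmp_probe_ids
    hi <- call_dmps(beta, "A", "B", retained, 0.45)$dmp_probe_ids
    expect_true(all(hi %in% lo))
  }
})

test_that("spatial summaries aggregate pairs, multiplicities and percentages", {
  # probe X is a DMP in pairs (S1,S2) and (S1,S3) only
  beta <- matrix(c(0.9, 0.1, 0.1,
                   0.1, 0.1, 0.1,
                   0.5, 0.5, 0.5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("X", "Y", "Z"), c("S1", "S2", "S3")))
  s <- summarize_patient_spatial(beta, c("S1", "S2", "S3"),
                                 c("X", "Y", "Z"), patient_id = "P")
  expect_equal(s$union_dmp_ids, "X")
  expect_equal(unname(s$multiplicity["X"]), 2L)
  expect_equal(s$union_count, 1L)
  expect_equal(s$union_pct_of_retained, pct_of_retained(1, 3))
  expect_error(summarize_patient_spatial(beta, "S1", c("X")), "at least 2")

  # union equals brute-force union over pair scans on random data
  rb <- random_beta(200, c("a", "b", "c", "d"), seed = 8, na_frac = 0.03)
  retained <- rownames(rb)[1:180]
  su <- summarize_patient_spatial(rb, colnames(rb), retained)
  bf_union <- unique(unlist(lapply(utils::combn(colnames(rb), 2,
                                                simplify = FALSE),
                                   function(pr) bf_call_dmps(rb, pr[1], pr[2],
                                                             retained))))
  expect_setequal(su$union_dmp_ids, bf_union)
  expect_equal(sum(su$multiplicity), sum(su$pair_counts))
})

test_that("temporal summaries split direction and conserve counts", {
  beta <- make_beta(c(rep(0.8, 10), rep(0.3, 10)),
                    sprintf("p%02d", 1:10), c("P", "R"))
  res <- summarize_temporal(beta, "P", "R", rownames(beta))
  expect_equal(res$hypo_count, 10L)
  expect_equal(res$hyper_count, 0L)
  expect_equal(res$majority, "hypo")

  rb <- random_beta(400, c("P", "R"), seed = 12)
  r2 <- summarize_temporal(rb, "P", "R", rownames(rb))
  expect_equal(r2$hypo_count + r2$hyper_count, length(r2$dmp_probe_ids))
})

test_that("cross-patient sharing counts patients per probe", {
  expect_equal(
    cross_patient_sharing(list(P1 = c("a", "b"), P2 = c("c")))$multiplicity,
    c(a = 1L, b = 1L, c = 1L))
  sh <- cross_patient_sharing(list(P1 = c("a", "b"), P2 = c("b", "c"),
                                   P3 = c("b")))
  expect_equal(unname(sh$multiplicity["b"]), 3L)
  expect_equal(as.integer(sh$histogram), c(2L, 0L, 1L))

  # matches brute-force membership count
  set.seed(9)
  sets <- lapply(1:5, function(i) sample(letters, sample(3:10, 1)))
  names(sets) <- paste0("P", 1:5)
  sh2 <- cross_patient_sharing(sets)
  for (p in names(sh2$multiplicity))
    expect_equal(unname(sh2$multiplicity[p]),
                 sum(vapply(sets, function(s) p %in% s, logical(1))))
})

test_that("probes removed by the filter never reach a patient's DMP sets", {
  d <- small_design(noise_sd = 0.05)
  co <- simulate_cohort(d)
  for (pid in c("SP01", "SP02")) {
    pr <- co$truth$patients[[pid]]
    retained <- apply_cna_filter(co$manifest, co$segments, pr$samples)
    removed <- setdiff(co$manifest$probe_id, retained)
    s <- summarize_patient_spatial(co$beta, pr$samples, retained)
    expect_length(intersect(s$union_dmp_ids, removed), 0)
    expect_true(all(unlist(pr$deleted) %in% removed))
  }
})

test_that("noiseless pure cohorts are recovered with perfect sensitivity and specificity", {
  d <- small_design(noise_sd = 0, purity_range = c(1, 1),
                    spatial_dmps_per_biopsy = 50L,
                    n_temporal_patients = 0L)
  co <- simulate_cohort(d)
  for (pid in names(co$truth$patients)) {
    pr <- co$truth$patients[[pid]]
    retained <- apply_cna_filter(co$manifest, co$segments, pr$samples)
    s <- summarize_patient_spatial(co$beta, pr$samples, retained)
    injected <- unique(unlist(pr$injected))
    expect_setequal(s$union_dmp_ids, injected)  # sensitivity = specificity = 1
  }
})
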