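test_that("variable-probe selection ranks by variance with the reference excluded", {
  beta <- matrix(c(0.1, 0.3, 0.5,   # var 0.04
                   0.4, 0.5, 0.6,   # var 0.01
                   0.1, 0.4, 0.7),  # var 0.09
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("A", "B", "C")))
  expect_equal(select_top_variable_probes(beta, c("A", "B", "C"), 2),
               c("p3", "p1"))
  expect_equal(select_top_variable_probes(beta, c("A", "B", "C"), 3),
               c("p3", "p1", "p2"))
  expect_error(select_top_variable_probes(beta, c("A", "B", "C"), 4),
               "exceeds")

  # the reference sample influences candidacy but not the ranking
  beta2 <- cbind(beta, NORM = c(0.9, 0.5, NA))
  sel <- select_top_variable_probes(beta2, colnames(beta2), 2,
                                    exclude_from_selection = "NORM")
  expect_equal(sel, c("p1", "p2"))  # p3 dropped: missing in NORM

  # brute-force variance sort on random matrices
  rb <- random_beta(500, c("a", "b", "c", "d"), seed = 31)
  got <- select_top_variable_probes(rb, colnames(rb), 50)
  v <- apply(rb, 1, stats::var)
  expect_equal(got, names(sort(v, decreasing = TRUE))[1:50])
})

test_that("euclidean distances are exact and metric", {
  beta <- matrix(c(0, 0, 0.3, 0.4), nrow = 2,
                 dimnames = list(c("p1", "p2"), c("i", "j")))
  D <- euclidean_distances(beta, c("i", "j"), c("p1", "p2"))
  expect_equal(D["i", "j"], 0.5)
  expect_equal(D["i", "i"], 0)

  rb <- random_beta(60, c("a", "b", "c", "d", "e"), seed = 2)
  D2 <- euclidean_distances(rb, colnames(rb), rownames(rb))
  expect_equal(D2, t(D2))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(D2[i, j], D2[i, k] + D2[k, j] + 1e-12)

  rb[1, 1] <- NA
  expect_error(euclidean_distances(rb, colnames(rb), rownames(rb)),
               "missing")
})

test_that("three-leaf trees use the closed-form branch lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- build_me_tree(D)
  len <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(len, c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("additive five-leaf metrics are recovered exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.7):0.3,E:2);")
  D <- stats::cophenetic(true)
  fit <- build_me_tree(D)
  expect_equal(phangorn::RF.dist(ape::unroot(true), fit), 0)
  expect_equal(attr(fit, "total_length"), sum(true$edge.length),
               tolerance = 1e-9)
  expect_equal(stats::cophenetic(fit)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  expect_lt(attr(fit, "rss"), 1e-18)
})

test_that("the NNI search attains the exhaustive minimum for small trees", {
  for (seed in c(41, 42)) {
    for (n in c(5, 6)) {
      set.seed(seed)
      pts <- matrix(stats::runif(n * 4), n)
      D <- as.matrix(stats::dist(pts))
      dimnames(D) <- list(LETTERS[1:n], LETTERS[1:n])
      fit <- build_me_tree(D)
      expect_equal(attr(fit, "total_length_unclamped"),
                   oracle_exhaustive_me(D), tolerance = 1e-9,
                   info = paste("seed", seed, "n", n))
    }
  }
})

test_that("the NNI search never worsens the OLS criterion and is deterministic", {
  set.seed(55)
  pts <- matrix(stats::runif(7 * 3), 7)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(letters[1:7], letters[1:7])
  start <- ape::nj(stats::as.dist(D))
  start_rss <- methylhet:::.ols_fit(start, D)$rss
  fit <- build_me_tree(D)
  expect_lte(attr(fit, "rss"), start_rss + 1e-12)
  expect_true(all(fit$edge.length >= 0))
  expect_identical(write_newick(build_me_tree(D)), write_newick(fit))
})

test_that("rooting at the reference preserves structure and path lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- build_me_tree(D)
  rooted <- attach_reference_and_root(tree, "A")
  # B and C become siblings under the non-reference child
  bc <- ape::getMRCA(rooted, c("B", "C"))
  expect_false(bc == length(rooted$tip.label) + 1L)
  expect_equal(stats::cophenetic(rooted)[c("A", "B", "C"), c("A", "B", "C")],
               stats::cophenetic(tree)[c("A", "B", "C"), c("A", "B", "C")],
               tolerance = 1e-12)
  expect_error(attach_reference_and_root(tree, "Z"), "unknown reference")

  set.seed(8)
  pts <- matrix(stats::runif(12), 6)
  D6 <- as.matrix(stats::dist(pts)); dimnames(D6) <- list(LETTERS[1:6], LETTERS[1:6])
  t6 <- build_me_tree(D6)
  r6 <- attach_reference_and_root(t6, "F")
  expect_equal(stats::cophenetic(r6)[LETTERS[1:6], LETTERS[1:6]],
               stats::cophenetic(t6)[LETTERS[1:6], LETTERS[1:6]],
               tolerance = 1e-12)
})

test_that("hierarchical clustering matches naive agglomeration and separates groups", {
  for (linkage in c("complete", "average")) {
    set.seed(19)
    pts <- matrix(stats::runif(8 * 5), 8)
    D <- as.matrix(stats::dist(pts))
    dimnames(D) <- list(letters[1:8], letters[1:8])
    hc <- hierarchical_clustering(D, linkage)
    expect_true(!is.unsorted(hc$height))
    expect_equal(as.matrix(stats::cophenetic(hc))[letters[1:8], letters[1:8]],
                 bf_agglomerate_cophenetic(D, linkage), tolerance = 1e-12)
  }

  # two well-separated groups split first
  set.seed(4)
  grp <- rbind(matrix(stats::rnorm(12, 0, 0.05), 4),
               matrix(stats::rnorm(12, 5, 0.05), 4))
  Dg <- as.matrix(stats::dist(grp))
  dimnames(Dg) <- list(paste0("s", 1:8), paste0("s", 1:8))
  hcg <- hierarchical_clustering(Dg)
  expect_setequal(split(paste0("s", 1:8), stats::cutree(hcg, 2))[[1]],
                  paste0("s", 1:4))
})

test_that("classical MDS reproduces planar configurations and small exact cases", {
  set.seed(10)
  pts <- matrix(stats::runif(14), 7)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("s", 1:7), paste0("s", 1:7))
  emb <- classical_mds(D, 2)
  expect_lt(procrustes_error(pts, emb), 1e-8)
  expect_equal(colMeans(emb), c(0, 0), tolerance = 1e-12)

  # any 3-point metric embeds exactly in the plane
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  e3 <- classical_mds(D3, 2)
  expect_equal(as.matrix(stats::dist(e3)), D3, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(classical_mds(D3, 3), "rank")
})

test_that("SNP identity checking passes clean cohorts and flags exactly a label swap", {
  d <- small_design(seed = 29L)
  co <- simulate_cohort(d)
  clean <- verify_sample_identity(co$beta, co$sheet, co$manifest)
  expect_length(clean$violations, 0)

  # swap the patient labels of one SP01 and one SP02 sample
  sw <- co$sheet
  a <- which(sw$sample_id == "SP01_1")
  b <- which(sw$sample_id == "SP02_1")
  sw$patient_id[c(a, b)] <- sw$patient_id[c(b, a)]
  res <- verify_sample_identity(co$beta, sw, co$manifest)
  expect_setequal(res$violations, c("SP01_1", "SP02_1"))

  # single-sample patients (the normal reference) are never flagged
  expect_true(is.na(res$table$ok[res$table$sample_id == "NORM1"]))

  no_snp <- co$manifest[!co$manifest$is_snp, ]
  expect_error(verify_sample_identity(co$beta, co$sheet, no_snp),
               "no SNP probes")
})
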