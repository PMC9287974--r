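# Per-patient sample relationships: variable-probe selection, Euclidean
# distances, minimal-evolution trees (NJ start, OLS branch lengths, NNI
# hill climb on the OLS total tree length), cohort clustering, classical
# MDS, and SNP-probe sample-identity verification.

#' Select the most variable probes
#'
#' Ranks probes by sample variance (denominator n-1) across the
#' selection samples and returns the top `k`, with deterministic
#' lexicographic probe-id tie-breaking. Only probes non-missing in all
#' of `samples` are candidates, so downstream distance calculations see
#' no missing values. Samples in `exclude_from_selection` (typically the
#' normal reference) are part of the candidate filter but not of the
#' variance ranking.
#'
#' @param beta Beta matrix.
#' @param samples Sample ids that will enter the distance calculation.
#' @param k Number of probes to return.
#' @param exclude_from_selection Samples excluded from the variance
#'   ranking (but still required non-missing).
#' @return Character vector of `k` probe ids, ordered by decreasing
#'   variance.
#' @export
select_top_variable_probes <- function(beta, samples, k,
                                       exclude_from_selection = character()) {
  sel <- setdiff(samples, exclude_from_selection)
  if (length(sel) < 2) stop("need at least 2 samples for variance ranking")
  sub <- beta[, samples, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  if (k > sum(complete))
    stop("k = ", k, " exceeds the ", sum(complete),
         " probes non-missing across the samples")
  x <- beta[complete, sel, drop = FALSE]
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (ncol(x) - 1)
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(k)]
}

#' Euclidean distances between samples
#'
#' `d(i, j) = sqrt(sum_p (beta_ip - beta_jp)^2)` over the given probes.
#'
#' @param beta Beta matrix.
#' @param samples Sample ids.
#' @param probes Probe ids; must be non-missing in every sample.
#' @return Symmetric distance matrix with sample dimnames.
#' @export
euclidean_distances <- function(beta, samples, probes) {
  sub <- beta[probes, samples, drop = FALSE]
  if (anyNA(sub))
    stop("missing beta values among the selected probes; ",
         "probe selection should have excluded them")
  as.matrix(stats::dist(t(sub), method = "euclidean"))
}

# Tip sets below each edge (the child-side split), in tree$edge order.
.edge_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(tree$edge[, 2], function(ch) desc[[ch]])
}

# Ordinary-least-squares branch lengths for a fixed topology: minimises
# sum over leaf pairs of (tree path length - observed distance)^2.
.ols_fit <- function(tree, D) {
  ntip <- length(tree$tip.label)
  tip_idx <- match(tree$tip.label, rownames(D))
  pairs <- utils::combn(ntip, 2)
  npair <- ncol(pairs)
  splits <- .edge_splits(tree)
  A <- matrix(0, npair, nrow(tree$edge))
  for (e in seq_along(splits)) {
    inside <- logical(ntip)
    inside[splits[[e]]] <- TRUE
    A[, e] <- inside[pairs[1, ]] != inside[pairs[2, ]]
  }
  d <- D[cbind(tip_idx[pairs[1, ]], tip_idx[pairs[2, ]])]
  fit <- stats::.lm.fit(A, d)
  lengths <- fit$coefficients
  resid <- d - as.vector(A %*% lengths)
  list(edge_lengths = lengths, total = sum(lengths),
       rss = sum(resid^2))
}

.three_leaf_tree <- function(D) {
  lab <- rownames(D)
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  structure(list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2,
                               byrow = TRUE),
                 edge.length = c(a, b, c), tip.label = lab, Nnode = 1L),
            class = "phylo")
}

#' Minimal-evolution tree from a distance matrix
#'
#' Builds the neighbor-joining topology, fits ordinary-least-squares
#' branch lengths, and hill-climbs with nearest-neighbour interchanges:
#' candidate rearrangements are scanned in a fixed order and the first
#' move that strictly reduces the OLS total tree length is taken, until
#' no move improves. Negative OLS lengths are clamped to zero only after
#' the search has converged, so the minimisation criterion is evaluated
#' on unclamped fits.
#'
#' @param D Symmetric distance matrix (>= 3 samples) with dimnames.
#' @return An `ape` `phylo` (unrooted) with attributes `total_length`
#'   (sum of clamped branch lengths), `total_length_unclamped`, `rss`
#'   (OLS residual sum of squares) and `me_variant` (`"OLS+NNI"`).
#' @export
build_me_tree <- function(D) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("non-finite distances")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples")
  if (n == 3) {
    tree <- .three_leaf_tree(D)
    fit <- .ols_fit(tree, D)
  } else {
    tree <- ape::nj(stats::as.dist(D))
    fit <- .ols_fit(tree, D)
    repeat {
      improved <- FALSE
      neighbours <- phangorn::nni(tree)
      for (i in seq_along(neighbours)) {
        cand <- neighbours[[i]]  # [[ restores compressed tip labels
        cand_fit <- .ols_fit(cand, D)
        if (cand_fit$total < fit$total - 1e-10) {
          tree <- cand
          fit <- cand_fit
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  tree$edge.length <- pmax(fit$edge_lengths, 0)
  attr(tree, "total_length") <- sum(tree$edge.length)
  attr(tree, "total_length_unclamped") <- fit$total
  attr(tree, "rss") <- fit$rss
  attr(tree, "me_variant") <- "OLS+NNI"
  tree
}

#' Root a tree on the edge leading to the normal reference
#'
#' Re-renders an unrooted tree rooted at the reference leaf's edge,
#' leaving topology and pairwise path lengths unchanged.
#'
#' @param tree Unrooted `phylo`.
#' @param reference_id Leaf label of the normal reference sample.
#' @return Rooted `phylo`.
#' @export
attach_reference_and_root <- function(tree, reference_id) {
  if (!reference_id %in% tree$tip.label)
    stop("unknown reference sample: ", reference_id)
  ape::root(tree, outgroup = reference_id, resolve.root = TRUE)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering on a precomputed distance matrix.
#'
#' @param D Symmetric distance matrix.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return An `hclust` object.
#' @export
hierarchical_clustering <- function(D, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Classical multidimensional scaling
#'
#' Classical (Torgerson) scaling: double-centre `-D^2 / 2`, take the top
#' eigenpairs, and scale eigenvectors by the square root of their
#' eigenvalues. Negative eigenvalues (non-Euclidean distances) are
#' truncated with a warning.
#'
#' @param D Symmetric distance matrix.
#' @param dims Number of output dimensions (<= the rank of the centred
#'   Gram matrix).
#' @return Numeric matrix (samples x dims) with sample rownames; the
#'   eigenvalues are attached as attribute `eig`.
#' @export
classical_mds <- function(D, dims = 2) {
  D <- as.matrix(D)
  if (dims > nrow(D) - 1)
    stop("dims = ", dims, " exceeds the rank (at most ", nrow(D) - 1,
         ") of the centred Gram matrix")
  res <- stats::cmdscale(stats::as.dist(D), k = dims, eig = TRUE)
  tol <- 1e-9 * max(abs(res$eig), 1)
  rank <- sum(res$eig > tol)
  if (dims > rank)
    stop("dims = ", dims, " exceeds the rank (", rank,
         ") of the centred Gram matrix")
  if (any(res$eig < -tol))
    warning("negative eigenvalues truncated in classical MDS (",
            sum(res$eig < -tol), " of ", length(res$eig), ")")
  pts <- res$points[, seq_len(dims), drop = FALSE]
  rownames(pts) <- rownames(D)
  attr(pts, "eig") <- res$eig
  pts
}

#' Verify sample identity from SNP probes
#'
#' Computes Euclidean distances over the SNP genotyping probes only.
#' Because SNP-probe beta values are genotype-determined and shared by
#' every sample of a patient, a sample's genotype neighbourhood should
#' be its own patient. For each sample whose patient contributes `m >= 2`
#' samples, the check takes its `m - 1` nearest neighbours and flags the
#' sample when fewer than half of them carry its patient label (a
#' majority vote; the single-nearest-neighbour rule is the `m = 2`
#' special case). The vote makes a single mislabelled sample flag
#' itself, not the correctly labelled patient mates sitting next to it.
#' Samples of single-sample patients cannot be checked and are never
#' flagged.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet.
#' @param manifest Probe manifest with at least one SNP probe.
#' @return List with `table` (per-sample nearest neighbour, patients,
#'   intra/inter minimum distances and margin), `violations` (sample
#'   ids flagged), and `n_snp_probes` used.
#' @export
verify_sample_identity <- function(beta, sheet, manifest) {
  snp_ids <- intersect(manifest$probe_id[manifest$is_snp], rownames(beta))
  if (length(snp_ids) == 0) stop("no SNP probes available")
  samples <- sheet$sample_id
  missing <- setdiff(samples, colnames(beta))
  if (length(missing) > 0)
    stop("sheet samples absent from beta matrix: ",
         paste(missing, collapse = ", "))
  sub <- beta[snp_ids, samples, drop = FALSE]
  usable <- rowSums(is.na(sub)) == 0
  if (!any(usable)) stop("no SNP probes non-missing across all samples")
  D <- euclidean_distances(beta, samples, snp_ids[usable])
  patient <- stats::setNames(sheet$patient_id, sheet$sample_id)
  multi <- names(table(patient))[table(patient) >= 2]
  rows <- lapply(samples, function(s) {
    d <- sort(D[s, setdiff(samples, s)])
    nn <- names(d)[1]
    same <- patient[names(d)] == patient[s]
    intra <- if (any(same)) min(d[same]) else NA_real_
    inter <- if (any(!same)) min(d[!same]) else NA_real_
    checkable <- patient[s] %in% multi
    ok <- NA
    if (checkable) {
      k <- sum(sheet$patient_id == patient[s]) - 1L
      ok <- mean(patient[names(d)[seq_len(k)]] == patient[s]) >= 0.5
    }
    data.frame(sample_id = s, patient_id = unname(patient[s]),
               nearest = nn, nearest_patient = unname(patient[nn]),
               intra_min = intra, inter_min = inter,
               margin = inter - intra, ok = ok,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       violations = tab$sample_id[!is.na(tab$ok) & !tab$ok],
       n_snp_probes = sum(usable))
}
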