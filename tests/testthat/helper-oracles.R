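# Independent brute-force oracles. Each is deliberately naive (loops,
# full enumeration) and shares no code path with the implementation it
# checks.

bf_cna_filter <- function(manifest, segments, samples, threshold = -0.4) {
  kept <- character(0)
  for (i in seq_len(nrow(manifest))) {
    if (manifest$is_snp[i]) next
    removed <- FALSE
    for (j in seq_len(nrow(segments))) {
      if (!segments$sample[j] %in% samples) next
      if (segments$seg_mean[j] >= threshold) next
      if (manifest$chrom[i] == segments$chrom[j] &&
          manifest$pos[i] >= segments$start[j] &&
          manifest$pos[i] <= segments$end[j]) {
        removed <- TRUE
        break
      }
    }
    if (!removed) kept <- c(kept, manifest$probe_id[i])
  }
  kept
}

bf_call_dmps <- function(beta, a, b, retained, threshold = 0.3) {
  hits <- character(0)
  for (p in rownames(beta)) {
    if (!p %in% retained) next
    va <- beta[p, a]; vb <- beta[p, b]
    if (is.na(va) || is.na(vb)) next
    if (abs(vb - va) > threshold) hits <- c(hits, p)
  }
  hits
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# patterns (midranks for tied absolute values).
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    vs[mask + 1] <- sum(r[signs])
  }
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

welch_formula <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

pearson_formula <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), n - 2))
}

# Naive agglomerative clustering returning the cophenetic distance
# matrix (height at which each pair is first merged).
bf_agglomerate_cophenetic <- function(D, method = c("complete", "average")) {
  method <- match.arg(method)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  cluster_dist <- function(ci, cj) {
    ds <- as.vector(outer(ci, cj, Vectorize(function(i, j) D[i, j])))
    if (method == "complete") max(ds) else mean(ds)
  }
  while (length(members) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (j <= i) next
      dd <- cluster_dist(members[[i]], members[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    for (a in members[[best[1]]]) for (b in members[[best[2]]]) {
      coph[a, b] <- best_d; coph[b, a] <- best_d
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  coph
}

# OLS tree-length fit built independently of the package internals: the
# path indicator of each edge is obtained by setting that edge length to
# 1 (all others 0) and reading cophenetic distances.
oracle_ols_total <- function(tree, D) {
  ntip <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  pairs <- t(utils::combn(ntip, 2))
  A <- matrix(0, nrow(pairs), ne)
  for (e in seq_len(ne)) {
    tr <- tree
    tr$edge.length <- rep(0, ne)
    tr$edge.length[e] <- 1
    cp <- stats::cophenetic(tr)
    A[, e] <- cp[cbind(tree$tip.label[pairs[, 1]],
                       tree$tip.label[pairs[, 2]])]
  }
  d <- D[cbind(tree$tip.label[pairs[, 1]], tree$tip.label[pairs[, 2]])]
  fit <- stats::lsfit(A, d, intercept = FALSE)
  sum(fit$coefficients)
}

oracle_exhaustive_me <- function(D) {
  n <- nrow(D)
  topologies <- phangorn::allTrees(n, rooted = FALSE,
                                   tip.label = rownames(D))
  totals <- vapply(seq_along(topologies), function(i)
    oracle_ols_total(topologies[[i]], D), numeric(1))
  min(totals)
}

# Independent Breslow log partial likelihood (plain loops).
oracle_breslow_loglik <- function(beta, time, x, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Rigid-motion (rotation/reflection + translation) alignment residual.
procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(t(X) %*% Y)
  rot <- s$u %*% t(s$v)
  sqrt(sum((Y - X %*% rot)^2))
}
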