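# Over/under-representation of DMPs in gene-region and CGI categories
# relative to the array background (the retained probe set), tested per
# category with a one-sample two-sided Wilcoxon signed-rank over
# per-patient proportion differences.

#' Category distribution of a probe set
#'
#' Gene-region axis: proportion of probes whose annotation set contains
#' each category, with `IGR` for probes carrying no gene annotation
#' (multi-annotated probes count in every category they carry, so these
#' proportions may sum to more than 1). CGI axis: a partition whose
#' proportions sum to 1.
#'
#' @param manifest Probe manifest.
#' @param probe_set Character vector of probe ids (subset of the
#'   manifest).
#' @return List with named numeric vectors `gene_region` and `cgi`.
#' @export
category_distribution <- function(manifest, probe_set) {
  if (length(probe_set) == 0) stop("empty probe set")
  idx <- match(probe_set, manifest$probe_id)
  if (anyNA(idx)) stop("probe ids absent from manifest")
  n <- length(idx)
  gr_strings <- manifest$gene_regions[idx]
  gr_sets <- strsplit(gr_strings, ";", fixed = TRUE)
  gene_region <- vapply(GENE_REGION_LEVELS, function(cat) {
    sum(vapply(gr_sets, function(s) cat %in% s, logical(1))) / n
  }, numeric(1))
  gene_region <- c(gene_region, IGR = sum(gr_strings == "") / n)
  cgi <- vapply(CGI_LEVELS, function(cat)
    sum(manifest$cgi_relation[idx] == cat) / n, numeric(1))
  list(gene_region = gene_region, cgi = cgi)
}

#' One-sample two-sided Wilcoxon signed-rank test
#'
#' Tests symmetry of `d` about zero. Zero differences are dropped before
#' ranking. For `n <= exact_max` non-zero observations the null
#' distribution of the signed-rank statistic is computed exactly by
#' convolution over the (mid)ranks, which remains exact in the presence
#' of tied absolute values; above that, the normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param d Numeric vector of differences.
#' @param exact_max Largest n for which the exact null is enumerated.
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_used` (non-zero differences) and `method`.
#' @export
signed_rank_test <- function(d, exact_max = 25L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # Exact null by convolution: work on doubled ranks (integers even
    # with midranks); counts stay below 2^53 for n <= 25.
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1)  # index w2 + 1
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- round(2 * V)
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  list(statistic = V, p_value = p, n_used = n, method = method)
}

#' Gene-region / CGI enrichment of per-patient DMP sets
#'
#' For each annotation category, compares the per-patient proportion of
#' DMPs in that category with the proportion among all retained probes
#' (the array background after copy-number and SNP filtering), using a
#' two-sided one-sample Wilcoxon signed-rank on the per-patient
#' differences. A category is flagged `enriched` (median difference
#' positive) or `depleted` (negative) when p < `alpha`; no
#' multiple-testing correction is applied to the flags, but
#' Benjamini-Hochberg q-values are reported alongside.
#'
#' @param manifest Probe manifest.
#' @param retained Retained probe ids (the background).
#' @param patient_dmp_sets Named list of per-patient DMP probe-id
#'   vectors; patients with empty sets are excluded with a message.
#' @param alpha Flagging level (default 0.01).
#' @return `data.frame` with one row per category: `axis`, `category`,
#'   `array_proportion`, `median_difference`, `p_value`, `q_value`,
#'   `flag`. The per-patient proportion matrices are attached as
#'   attributes `patient_gene_region` and `patient_cgi`.
#' @export
enrichment_test <- function(manifest, retained, patient_dmp_sets,
                            alpha = 0.01) {
  sizes <- lengths(patient_dmp_sets)
  if (any(sizes == 0)) {
    message("enrichment_test: excluding ", sum(sizes == 0),
            " patient(s) with empty DMP sets: ",
            paste(names(patient_dmp_sets)[sizes == 0], collapse = ", "))
    patient_dmp_sets <- patient_dmp_sets[sizes > 0]
  }
  if (length(patient_dmp_sets) < 2)
    stop("need at least 2 patients with non-empty DMP sets")
  background <- category_distribution(manifest, retained)
  per_patient <- lapply(patient_dmp_sets, function(ids)
    category_distribution(manifest, ids))
  rows <- list()
  mats <- list()
  for (axis in c("gene_region", "cgi")) {
    mat <- do.call(rbind, lapply(per_patient, `[[`, axis))
    mats[[axis]] <- mat
    for (cat in colnames(mat)) {
      diffs <- mat[, cat] - background[[axis]][cat]
      test <- signed_rank_test(diffs)
      rows[[length(rows) + 1]] <- data.frame(
        axis = axis, category = cat,
        array_proportion = unname(background[[axis]][cat]),
        median_difference = stats::median(diffs),
        p_value = test$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$flag <- ifelse(out$p_value < alpha,
                     ifelse(out$median_difference > 0, "enriched",
                            "depleted"),
                     "ns")
  out$flag[out$p_value < alpha & out$median_difference == 0] <- "ns"
  attr(out, "patient_gene_region") <- mats[["gene_region"]]
  attr(out, "patient_cgi") <- mats[["cgi"]]
  attr(out, "n_patients") <- length(patient_dmp_sets)
  out
}
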