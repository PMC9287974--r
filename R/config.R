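#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults follow
#' standard practice for EPIC beta-value heterogeneity analyses: a CpG is
#' a DMP when the beta difference between two samples of one patient
#' exceeds 0.3; probes falling in homozygously deleted segments
#' (segmented log2 ratio below -0.4) are removed before DMP calling;
#' phylogenies use the top 5000 most variable probes, cohort clustering
#' the top 10000 and MDS the top 20000.
#'
#' @param dmp_delta_threshold Minimum absolute beta difference for a DMP
#'   (strict inequality), in (0, 1).
#' @param cna_del_threshold Segmented log2 ratio below which a segment is
#'   treated as a homozygous deletion (strict inequality); must be < 0.
#' @param phylo_top_k Number of most-variable probes for per-patient
#'   phylogenies.
#' @param cluster_top_k Number of most-variable probes for cohort
#'   hierarchical clustering.
#' @param mds_top_k Number of most-variable probes for cohort MDS.
#' @param enrich_alpha Significance level for enrichment flags.
#' @param random_seed Integer seed recorded with the configuration.
#' @return A list of class `methylhet_config`.
#' @export
analysis_config <- function(dmp_delta_threshold = 0.3,
                            cna_del_threshold = -0.4,
                            phylo_top_k = 5000,
                            cluster_top_k = 10000,
                            mds_top_k = 20000,
                            enrich_alpha = 0.01,
                            random_seed = 1L) {
  stopifnot(
    is.numeric(dmp_delta_threshold), length(dmp_delta_threshold) == 1,
    dmp_delta_threshold > 0, dmp_delta_threshold < 1,
    is.numeric(cna_del_threshold), cna_del_threshold < 0,
    phylo_top_k >= 2, cluster_top_k >= 2, mds_top_k >= 2,
    enrich_alpha > 0, enrich_alpha < 1
  )
  structure(list(
    dmp_delta_threshold = dmp_delta_threshold,
    cna_del_threshold = cna_del_threshold,
    phylo_top_k = as.integer(phylo_top_k),
    cluster_top_k = as.integer(cluster_top_k),
    mds_top_k = as.integer(mds_top_k),
    enrich_alpha = enrich_alpha,
    random_seed = as.integer(random_seed)
  ), class = "methylhet_config")
}

#' Percentage of retained probes, printed to one decimal
#'
#' Formats a DMP count as the percentage of the probes retained for
#' analysis, the unit in which per-tumour DMP burdens are reported.
#'
#' @param count DMP count (non-negative).
#' @param retained Number of retained probes (> 0).
#' @return Numeric percentage rounded to one decimal.
#' @export
pct_of_retained <- function(count, retained) {
  stopifnot(retained > 0, all(count >= 0))
  round(100 * count / retained, 1)
}
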