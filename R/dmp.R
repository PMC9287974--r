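# CNA-filtered pairwise DMP calling, per-tumour aggregation,
# directionality and sharing structure. A probe is a DMP for a sample
# pair when it is retained, non-missing in both samples, and its
# absolute beta difference strictly exceeds the threshold.

#' Probes retained after the copy-number filter
#'
#' Removes every probe whose position falls inside a segment with
#' segmented log2 ratio strictly below `threshold` (homozygous deletion)
#' in any of the listed samples, and all SNP probes. A beta difference
#' over a deleted region is meaningless, so deletion in either sample of
#' a pair invalidates the probe for the whole patient.
#'
#' @param manifest Probe manifest.
#' @param segments Segment `data.frame` (see [read_seg()]); samples with
#'   no segments contribute no removals.
#' @param samples Character vector of sample ids whose deletions apply.
#' @param threshold Deletion threshold on seg_mean (strict `<`), < 0.
#' @return Character vector of retained probe ids (manifest order).
#' @export
apply_cna_filter <- function(manifest, segments, samples,
                             threshold = -0.4) {
  stopifnot(threshold < 0)
  keep <- !manifest$is_snp
  del <- segments[segments$sample %in% samples &
                    segments$seg_mean < threshold, , drop = FALSE]
  for (i in seq_len(nrow(del))) {
    hit <- manifest$chrom == del$chrom[i] &
      manifest$pos >= del$start[i] & manifest$pos <= del$end[i]
    keep <- keep & !hit
  }
  retained <- manifest$probe_id[keep]
  if (length(retained) == 0)
    stop("copy-number filter removed every probe; nothing to analyse")
  retained
}

#' Call DMPs between two samples
#'
#' @param beta Beta matrix (probes x samples).
#' @param sample_a,sample_b Column ids; differences are `b - a`.
#' @param retained Retained probe ids from [apply_cna_filter()].
#' @param threshold DMP threshold on `|delta beta|` (strict `>`).
#' @return List of class `dmp_pair`: `sample_a`, `sample_b`,
#'   `retained_probe_count` (retained and non-missing in both),
#'   `dmp_probe_ids`, and `delta` (named signed differences at the
#'   DMPs).
#' @export
call_dmps <- function(beta, sample_a, sample_b, retained,
                      threshold = 0.3) {
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(beta)) stop("unknown sample id: ", s)
  if (length(retained) == 0) stop("empty retained probe set")
  probes <- intersect(rownames(beta), retained)
  a <- beta[probes, sample_a]
  b <- beta[probes, sample_b]
  usable <- !is.na(a) & !is.na(b)
  delta <- b[usable] - a[usable]
  is_dmp <- abs(delta) > threshold
  structure(list(
    sample_a = sample_a,
    sample_b = sample_b,
    retained_probe_count = sum(usable),
    dmp_probe_ids = probes[usable][is_dmp],
    delta = delta[is_dmp]
  ), class = "dmp_pair")
}

#' Spatial per-patient DMP summary
#'
#' Runs [call_dmps()] over every unordered biopsy pair and aggregates:
#' the union of all pair DMP sets (the per-tumour DMP count), per-probe
#' pair multiplicities (how many pairs each DMP appears in), and the
#' union as a percentage of the probes retained for this patient
#' (retained and non-missing in all its samples).
#'
#' @param beta Beta matrix.
#' @param samples Two or more biopsy sample ids of one patient.
#' @param retained Retained probe ids.
#' @param threshold DMP threshold.
#' @param patient_id Optional label carried into the result.
#' @return List of class `patient_dmp_summary` with elements `pairs`
#'   (list of `dmp_pair`), `pair_counts`, `union_dmp_ids`,
#'   `union_count`, `max_pair_count`, `multiplicity` (named integer per
#'   DMP), `multiplicity_histogram`, `retained_probe_count` and
#'   `union_pct_of_retained`.
#' @export
summarize_patient_spatial <- function(beta, samples, retained,
                                      threshold = 0.3, patient_id = NA) {
  if (length(samples) < 2) stop("need at least 2 samples per patient")
  idx <- utils::combn(length(samples), 2)
  pairs <- lapply(seq_len(ncol(idx)), function(j) {
    call_dmps(beta, samples[idx[1, j]], samples[idx[2, j]], retained,
              threshold)
  })
  names(pairs) <- apply(idx, 2, function(ij)
    paste(samples[ij[1]], samples[ij[2]], sep = "|"))
  all_ids <- unlist(lapply(pairs, `[[`, "dmp_probe_ids"), use.names = FALSE)
  multiplicity <- table(all_ids)
  union_ids <- names(multiplicity)
  probes <- intersect(rownames(beta), retained)
  complete <- rowSums(is.na(beta[probes, samples, drop = FALSE])) == 0
  retained_n <- sum(complete)
  structure(list(
    patient_id = patient_id,
    samples = samples,
    pairs = pairs,
    pair_counts = vapply(pairs, function(p) length(p$dmp_probe_ids),
                         integer(1)),
    union_dmp_ids = union_ids,
    union_count = length(union_ids),
    max_pair_count = if (length(pairs) > 0)
      max(vapply(pairs, function(p) length(p$dmp_probe_ids), integer(1)))
    else 0L,
    multiplicity = stats::setNames(as.integer(multiplicity), union_ids),
    multiplicity_histogram = table(factor(as.integer(multiplicity),
                                          levels = seq_len(ncol(idx)))),
    retained_probe_count = retained_n,
    union_pct_of_retained = pct_of_retained(length(union_ids), retained_n)
  ), class = "patient_dmp_summary")
}

#' Temporal (primary vs relapse) DMP summary
#'
#' As [call_dmps()] for the ordered primary-to-relapse pair, splitting
#' the DMPs into sites hypomethylated (`delta < -threshold`) and
#' hypermethylated (`delta > threshold`) in the relapse, and reporting
#' the majority direction.
#'
#' @param beta Beta matrix.
#' @param primary,relapse Sample ids, in that order.
#' @param retained Retained probe ids.
#' @param threshold DMP threshold.
#' @return `dmp_pair` list extended with `hypo_count`, `hyper_count`
#'   and `majority` (`"hypo"`, `"hyper"` or `"tie"`).
#' @export
summarize_temporal <- function(beta, primary, relapse, retained,
                               threshold = 0.3) {
  res <- call_dmps(beta, primary, relapse, retained, threshold)
  res$hypo_count <- sum(res$delta < -threshold)
  res$hyper_count <- sum(res$delta > threshold)
  res$majority <- if (res$hypo_count > res$hyper_count) "hypo"
  else if (res$hyper_count > res$hypo_count) "hyper" else "tie"
  class(res) <- c("dmp_pair_temporal", "dmp_pair")
  res
}

#' Cross-patient DMP sharing
#'
#' For every probe appearing in any patient's union DMP set, counts the
#' number of patients carrying it, plus a histogram of those
#' multiplicities.
#'
#' @param dmp_sets Named list (one element per patient) of DMP probe-id
#'   vectors, e.g. the `union_dmp_ids` of spatial summaries or
#'   `dmp_probe_ids` of temporal pairs.
#' @return List with `multiplicity` (named integer vector) and
#'   `histogram` (table over 1..n_patients).
#' @export
cross_patient_sharing <- function(dmp_sets) {
  if (length(dmp_sets) < 2) stop("need at least 2 patients")
  all_ids <- unlist(lapply(dmp_sets, unique), use.names = FALSE)
  mult <- table(all_ids)
  list(
    multiplicity = stats::setNames(as.integer(mult), names(mult)),
    histogram = table(factor(as.integer(mult),
                             levels = seq_along(dmp_sets)))
  )
}
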