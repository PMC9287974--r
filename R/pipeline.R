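# End-to-end orchestration: simulate or load a cohort, verify sample
# identity, call CNA-filtered DMPs per patient, test region enrichment,
# build per-patient phylogenies plus cohort clustering/MDS, run the
# association statistics, and write a JSON run manifest. All stage
# outputs depend only on config + inputs + seed.

.stage_seed <- function(seed, offset) (seed + offset) %% 2147483647L

#' Run the full heterogeneity pipeline
#'
#' Executes simulate/load -> identity check -> DMP calling -> enrichment
#' -> phylogenies -> association statistics, writing per-stage JSON
#' outputs, Newick trees and a run manifest under the configured output
#' directory. The YAML config holds `seed`, `output_dir`, either a
#' `simulate` block (overrides for [simulation_design()]) or an `inputs`
#' block (`beta`, `manifest`, `seg`, `sheet` paths), an optional
#' `analysis` block (overrides for [analysis_config()]) and
#' `allow_mismatch` (continue past identity violations; default FALSE).
#'
#' @param config Path to a YAML config file, or an equivalent list.
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly. Identity violations abort
#'   the run unless `allow_mismatch` is set.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output_dir))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[methylhet] ", ...)
  cfg <- do.call(analysis_config,
                 c(config$analysis %||% list(), list(random_seed = seed)))
  manifest_out <- list(seed = seed, config = config, stages = list(),
                       outputs = list())
  record <- function(stage, status, ...) {
    manifest_out$stages[[stage]] <<- c(list(status = status), list(...))
  }

  # -- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    say("simulating cohort")
    design <- do.call(simulation_design,
                      c(config$simulate, list(seed = .stage_seed(seed, 0L))))
    cohort <- simulate_cohort(design)
    paths <- write_cohort(cohort, file.path(out_dir, "cohort"))
    record("inputs", "ok", source = "simulated",
           files = as.list(paths))
    manifest <- cohort$manifest; beta <- cohort$beta
    sheet <- cohort$sheet; segments <- cohort$segments
  } else {
    inp <- config$inputs
    stopifnot(!is.null(inp$beta), !is.null(inp$manifest),
              !is.null(inp$sheet))
    say("loading inputs")
    manifest <- read_probe_manifest(inp$manifest)
    beta <- read_beta_matrix(inp$beta, manifest)
    sheet <- read_sample_sheet(inp$sheet)
    segments <- if (!is.null(inp$seg)) read_seg(inp$seg) else
      data.frame(sample = character(), chrom = character(),
                 start = integer(), end = integer(), seg_mean = numeric())
    record("inputs", "ok", source = "files", files = inp)
  }
  missing <- setdiff(sheet$sample_id, colnames(beta))
  if (length(missing) > 0)
    stop("sheet samples absent from beta matrix: ",
         paste(missing, collapse = ", "))

  # -- identity -------------------------------------------------------
  say("verifying sample identity from SNP probes")
  identity <- verify_sample_identity(beta, sheet, manifest)
  record("identity", if (length(identity$violations) == 0) "ok" else "violations",
         n_snp_probes = identity$n_snp_probes,
         violations = as.list(identity$violations))
  if (length(identity$violations) > 0 && !isTRUE(config$allow_mismatch)) {
    .write_report(manifest_out, out_dir)
    stop("sample identity violations: ",
         paste(identity$violations, collapse = ", "),
         " (set allow_mismatch to continue)")
  }

  ref_id <- sheet$sample_id[sheet$role == "normal_reference"][1]
  spatial_patients <- unique(sheet$patient_id[sheet$role == "spatial"])
  temporal_patients <- unique(sheet$patient_id[sheet$role == "relapse"])

  # -- dmp ------------------------------------------------------------
  say("calling DMPs (", length(spatial_patients), " spatial, ",
      length(temporal_patients), " temporal patients)")
  spatial <- lapply(spatial_patients, function(pid) {
    ss <- sheet$sample_id[sheet$patient_id == pid & sheet$role == "spatial"]
    retained <- apply_cna_filter(manifest, segments, ss,
                                 cfg$cna_del_threshold)
    summarize_patient_spatial(beta, ss, retained, cfg$dmp_delta_threshold,
                              patient_id = pid)
  })
  names(spatial) <- spatial_patients
  temporal <- lapply(temporal_patients, function(pid) {
    prim <- sheet$sample_id[sheet$patient_id == pid & sheet$role == "primary"]
    rel <- sheet$sample_id[sheet$patient_id == pid &
                             sheet$role %in% c("relapse", "metastasis")]
    retained <- apply_cna_filter(manifest, segments, c(prim, rel[1]),
                                 cfg$cna_del_threshold)
    summarize_temporal(beta, prim[1], rel[1], retained,
                       cfg$dmp_delta_threshold)
  })
  names(temporal) <- temporal_patients
  dmp_report <- list(
    spatial = lapply(spatial, function(s) list(
      patient_id = s$patient_id,
      pair_counts = as.list(s$pair_counts),
      union_count = s$union_count,
      max_pair_count = s$max_pair_count,
      retained_probe_count = s$retained_probe_count,
      union_pct_of_retained = s$union_pct_of_retained)),
    temporal = lapply(temporal, function(t) list(
      primary = t$sample_a, relapse = t$sample_b,
      dmp_count = length(t$dmp_probe_ids),
      hypo_count = t$hypo_count, hyper_count = t$hyper_count,
      majority = t$majority,
      retained_probe_count = t$retained_probe_count)))
  if (length(temporal) > 0) {
    majorities <- vapply(temporal, `[[`, character(1), "majority")
    dmp_report$temporal_hypo_majority_pct <-
      round(100 * mean(majorities == "hypo"))
  }
  if (length(spatial) >= 2)
    dmp_report$spatial_sharing_histogram <- as.list(
      cross_patient_sharing(lapply(spatial, `[[`, "union_dmp_ids"))$histogram)
  jsonlite::write_json(dmp_report, file.path(out_dir, "dmp_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  record("dmp", "ok", file = "dmp_report.json")

  # -- enrichment -----------------------------------------------------
  enrich_out <- list()
  for (arm in c("spatial", "temporal")) {
    sets <- if (arm == "spatial")
      lapply(spatial, `[[`, "union_dmp_ids")
    else lapply(temporal, `[[`, "dmp_probe_ids")
    sets <- sets[lengths(sets) > 0]
    if (length(sets) >= 2) {
      say("enrichment (", arm, ", ", length(sets), " patients)")
      all_samples <- sheet$sample_id[sheet$role != "normal_reference"]
      retained <- apply_cna_filter(manifest, segments, all_samples,
                                   cfg$cna_del_threshold)
      enr <- enrichment_test(manifest, retained, sets, cfg$enrich_alpha)
      enrich_out[[arm]] <- enr
    }
  }
  jsonlite::write_json(lapply(enrich_out, function(e)
    e[, c("axis", "category", "array_proportion", "median_difference",
          "p_value", "q_value", "flag")]),
    file.path(out_dir, "enrichment.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  record("enrichment", "ok", file = "enrichment.json")

  # -- phylo ----------------------------------------------------------
  tree_dir <- file.path(out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  tree_files <- character(0)
  for (pid in spatial_patients) {
    ss <- sheet$sample_id[sheet$patient_id == pid & sheet$role == "spatial"]
    if (length(ss) < 2 || (length(ss) < 3 && is.na(ref_id))) next
    all_s <- c(ss, if (!is.na(ref_id)) ref_id)
    k <- min(cfg$phylo_top_k,
             sum(rowSums(is.na(beta[, all_s, drop = FALSE])) == 0))
    probes <- select_top_variable_probes(beta, all_s, k,
                                         exclude_from_selection = ref_id)
    D <- euclidean_distances(beta, all_s, probes)
    tree <- build_me_tree(D)
    if (!is.na(ref_id)) tree <- attach_reference_and_root(tree, ref_id)
    f <- file.path(tree_dir, paste0(pid, ".nwk"))
    write_newick(tree, f)
    tree_files <- c(tree_files, f)
  }
  all_tumour <- sheet$sample_id[sheet$role != "normal_reference"]
  cohort_summary <- list()
  if (length(all_tumour) >= 3) {
    avail <- sum(rowSums(is.na(beta[, all_tumour, drop = FALSE])) == 0)
    pc <- select_top_variable_probes(beta, all_tumour,
                                     min(cfg$cluster_top_k, avail))
    Dc <- euclidean_distances(beta, all_tumour, pc)
    hc <- hierarchical_clustering(Dc)
    pm <- select_top_variable_probes(beta, all_tumour,
                                     min(cfg$mds_top_k, avail))
    Dm <- euclidean_distances(beta, all_tumour, pm)
    mds <- classical_mds(Dm, dims = 2)
    mds_df <- data.frame(sample_id = rownames(mds), dim1 = mds[, 1],
                         dim2 = mds[, 2], stringsAsFactors = FALSE)
    utils::write.csv(mds_df, file.path(out_dir, "mds_coordinates.csv"),
                     row.names = FALSE)
    cohort_summary <- list(clustering_order = hc$labels[hc$order],
                           mds_file = "mds_coordinates.csv")
  }
  record("phylo", "ok", trees = as.list(basename(tree_files)),
         cohort = cohort_summary)

  # -- association statistics -----------------------------------------
  say("association statistics")
  assoc <- list()
  if (length(temporal) > 0) {
    counts <- vapply(temporal, function(t) length(t$dmp_probe_ids),
                     numeric(1))
    intervals <- vapply(names(temporal), function(pid) {
      iv <- sheet$relapse_interval[sheet$patient_id == pid &
                                     !is.na(sheet$relapse_interval)]
      if (length(iv) > 0) iv[1] else NA_real_
    }, numeric(1))
    ok <- !is.na(intervals) & intervals > 0
    if (sum(ok) >= 3) {
      fit <- cox_relapse_vs_dmps(intervals[ok], counts[ok])
      assoc$cox <- fit[c("identifiable", "coefficient", "standard_error",
                         "wald_z", "p_value", "n", "n_events",
                         "iterations")]
    }
    groups <- vapply(names(temporal), function(pid) {
      g <- sheet$group_label[sheet$patient_id == pid]
      g <- g[!is.na(g)]
      if (length(g) > 0) g[1] else NA_character_
    }, character(1))
    glev <- names(table(groups))
    comps <- list()
    if (length(glev) >= 2) {
      gp <- utils::combn(glev, 2)
      for (j in seq_len(ncol(gp))) {
        cmp <- welch_t_test(counts[!is.na(groups) & groups == gp[1, j]],
                            counts[!is.na(groups) & groups == gp[2, j]],
                            gp[1, j], gp[2, j])
        comps[[paste(gp[1, j], gp[2, j], sep = "_vs_")]] <-
          cmp[c("labels", "n", "computable", "t", "df", "p_value")]
      }
    }
    assoc$group_comparisons <- comps
    tp <- tryCatch(purity_dmp_association(counts[ok], sheet, "temporal"),
                   warning = function(w) suppressWarnings(
                     purity_dmp_association(counts[ok], sheet, "temporal")))
    assoc$temporal_purity <- tp[c("defined", "r", "p_value", "n")]
  }
  if (length(spatial) >= 3) {
    sc <- vapply(spatial, `[[`, numeric(1), "union_count")
    sp <- tryCatch(purity_dmp_association(sc, sheet, "spatial"),
                   warning = function(w) suppressWarnings(
                     purity_dmp_association(sc, sheet, "spatial")))
    assoc$spatial_purity <- sp[c("defined", "r", "p_value", "n")]
  }
  jsonlite::write_json(assoc, file.path(out_dir, "assoc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  record("assoc", "ok", file = "assoc.json")

  manifest_out$outputs <- list(
    dmp = "dmp_report.json", enrichment = "enrichment.json",
    assoc = "assoc.json", trees = as.list(basename(tree_files)))
  .write_report(manifest_out, out_dir)
  say("done; run manifest at ", file.path(out_dir, "run_manifest.json"))
  invisible(manifest_out)
}

.write_report <- function(manifest_out, out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "run_manifest.json"]
  manifest_out$digests <- as.list(stats::setNames(
    unname(tools::md5sum(files)),
    sub(paste0("^", out_dir, "/?"), "", files)))
  manifest_out$version <- as.character(utils::packageVersion("methylhet"))
  jsonlite::write_json(manifest_out,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest_out)
}
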