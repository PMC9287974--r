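# Synthetic EPIC-like cohort generator. Encodes the statistical
# structure the analysis assumes: bimodal beta distributions with
# patient-specific baselines, biopsy-level site-specific shifts biased
# toward non-regulatory regions, linear purity mixing with a normal
# profile, homozygous deletions producing unreliable signal, Poisson
# accumulation of relapse alterations with a hypomethylation excess, and
# tri-modal SNP-probe genotypes shared within a patient.

#' Simulation design for an EPIC-like cohort
#'
#' Default values emulate the structure of a paediatric brain-tumour
#' heterogeneity study: 11 spatially sampled tumours with 3-7 biopsies
#' each, 33 primary/relapse pairs, site-specific beta shifts of
#' magnitude 0.5 against measurement noise of sd 0.02, a 60% excess of
#' hypomethylation among relapse alterations, relapse alterations
#' accumulating as a Poisson process in time, and 3-fold sampling bias
#' of altered sites toward OpenSea and intergenic probes.
#'
#' @param n_probes Number of regular CpG probes (the array background).
#' @param n_snp_probes Number of SNP genotyping probes (EPIC carries 59).
#' @param cgi_freqs Named probabilities over [CGI_LEVELS]; must sum to 1.
#' @param gene_region_freqs Named probabilities over the gene-region
#'   categories plus `IGR`; must sum to 1 (simulated probes carry a
#'   single gene-region annotation).
#' @param n_spatial_patients,biopsies_min,biopsies_max Spatial arm size.
#' @param n_temporal_patients Number of primary/relapse pairs.
#' @param spatial_dmps_per_biopsy Site-specific alterations injected
#'   privately into each spatial biopsy.
#' @param dmp_rate_per_day Cohort-level Poisson rate (alterations per
#'   day) for relapse accumulation; the expected relapse alteration
#'   count for a patient is `rate_i * relapse_interval` with
#'   `rate_i = dmp_rate_per_day * L_i`.
#' @param rate_sdlog Between-patient dispersion of accumulation rates:
#'   `L_i` is lognormal with mean 1 and log-sd `rate_sdlog`. Tumour
#'   types differ in how fast they accumulate alterations (high-grade
#'   embryonal tumours versus low-grade gliomas), so per-patient counts
#'   at similar intervals legitimately spread beyond Poisson variation;
#'   the default 0.5 gives roughly a 4-fold central 95% rate range,
#'   enough heterogeneity to be realistic while keeping the interval
#'   effect detectable at the default cohort size. Set to 0 for a
#'   homogeneous cohort.
#' @param interval_range_days Range (days) from which relapse intervals
#'   are drawn uniformly.
#' @param hypo_fraction Probability that a relapse alteration is
#'   hypomethylated (lower beta in the relapse).
#' @param dmp_effect_size Absolute beta shift at an injected site; kept
#'   above `0.3 + 3 * noise_sd` so injected sites are recoverable.
#' @param noise_sd Gaussian measurement noise sd on observed beta.
#' @param purity_range Range of tumour cell content; observed beta is
#'   `purity * tumour + (1 - purity) * normal`.
#' @param region_bias Multiplicative sampling weight applied to OpenSea
#'   probes and again to intergenic probes when drawing injected sites.
#' @param hd_per_patient Homozygous deletions per patient (each placed
#'   in one random tumour sample).
#' @param hd_n_probes Number of consecutive probes a deletion spans.
#' @param hd_seg_mean Segmented log2 ratio of deleted segments (< -0.4).
#' @param baseline_weights Mixture weights (low mode near 0.1, high mode
#'   near 0.9, intermediate mass) for baseline beta values.
#' @param seed Default seed used by the generator functions.
#' @return A list of class `sim_design`.
#' @export
simulation_design <- function(n_probes = 20000L,
                              n_snp_probes = 59L,
                              cgi_freqs = c(Island = 0.19, Shore = 0.21,
                                            Shelf = 0.10, OpenSea = 0.50),
                              gene_region_freqs = c(TSS200 = 0.07, TSS1500 = 0.10,
                                                    `5UTR` = 0.09, `1stExon` = 0.03,
                                                    ExonBnd = 0.02, Body = 0.36,
                                                    `3UTR` = 0.03, IGR = 0.30),
                              n_spatial_patients = 11L,
                              biopsies_min = 3L,
                              biopsies_max = 7L,
                              n_temporal_patients = 33L,
                              spatial_dmps_per_biopsy = 150L,
                              dmp_rate_per_day = 0.2,
                              rate_sdlog = 0.5,
                              interval_range_days = c(100, 1500),
                              hypo_fraction = 0.6,
                              dmp_effect_size = 0.5,
                              noise_sd = 0.02,
                              purity_range = c(0.7, 1),
                              region_bias = 3,
                              hd_per_patient = 1L,
                              hd_n_probes = 20L,
                              hd_seg_mean = -1,
                              baseline_weights = c(low = 0.45, high = 0.45,
                                                   mid = 0.10),
                              seed = 1L) {
  stopifnot(
    n_probes >= 10, n_snp_probes >= 0,
    abs(sum(cgi_freqs) - 1) < 1e-8,
    setequal(names(cgi_freqs), CGI_LEVELS),
    abs(sum(gene_region_freqs) - 1) < 1e-8,
    all(names(gene_region_freqs) %in% c(GENE_REGION_LEVELS, "IGR")),
    biopsies_min >= 2, biopsies_max >= biopsies_min,
    hypo_fraction >= 0, hypo_fraction <= 1,
    dmp_effect_size > 0, dmp_effect_size <= 1, noise_sd >= 0,
    length(purity_range) == 2, purity_range[1] <= purity_range[2],
    purity_range[1] >= 0, purity_range[2] <= 1,
    region_bias > 0, hd_seg_mean < -0.4,
    dmp_rate_per_day >= 0, rate_sdlog >= 0, all(interval_range_days > 0),
    interval_range_days[1] <= interval_range_days[2]
  )
  design <- list(
    n_probes = as.integer(n_probes), n_snp_probes = as.integer(n_snp_probes),
    cgi_freqs = cgi_freqs[CGI_LEVELS],
    gene_region_freqs = gene_region_freqs,
    n_spatial_patients = as.integer(n_spatial_patients),
    biopsies_min = as.integer(biopsies_min),
    biopsies_max = as.integer(biopsies_max),
    n_temporal_patients = as.integer(n_temporal_patients),
    spatial_dmps_per_biopsy = as.integer(spatial_dmps_per_biopsy),
    dmp_rate_per_day = dmp_rate_per_day,
    rate_sdlog = rate_sdlog,
    interval_range_days = interval_range_days,
    hypo_fraction = hypo_fraction,
    dmp_effect_size = dmp_effect_size,
    noise_sd = noise_sd,
    purity_range = purity_range,
    region_bias = region_bias,
    hd_per_patient = as.integer(hd_per_patient),
    hd_n_probes = as.integer(hd_n_probes),
    hd_seg_mean = hd_seg_mean,
    baseline_weights = baseline_weights / sum(baseline_weights),
    seed = as.integer(seed)
  )
  class(design) <- "sim_design"
  design
}

# Bimodal baseline beta: low mode ~Beta(2,18) (mean 0.1), high mode
# ~Beta(18,2) (mean 0.9), minor intermediate mass ~Beta(5,5).
.rbimodal <- function(n, weights) {
  comp <- sample.int(3L, n, replace = TRUE, prob = weights)
  out <- numeric(n)
  out[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 18)
  out[comp == 2] <- stats::rbeta(sum(comp == 2), 18, 2)
  out[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)
  out
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

# sample() that never interprets a length-1 x as 1:x
.resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

#' Simulate a probe annotation manifest
#'
#' Lays `n_probes` regular probes plus `n_snp_probes` SNP probes onto 22
#' synthetic chromosomes in sorted position order, with CGI and
#' gene-region categories drawn i.i.d. from the design frequencies.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed (defaults to the design's).
#' @return Manifest `data.frame` (see [read_probe_manifest()]).
#' @export
simulate_manifest <- function(design, seed = design$seed) {
  set.seed(seed)
  n_total <- design$n_probes + design$n_snp_probes
  snp_flag <- rep(FALSE, n_total)
  snp_flag[sample.int(n_total, design$n_snp_probes)] <- TRUE
  ids <- character(n_total)
  ids[!snp_flag] <- sprintf("cg%08d", seq_len(design$n_probes))
  ids[snp_flag] <- sprintf("rs%06d", seq_len(design$n_snp_probes))
  chrom_of <- sort(rep_len(seq_len(22L), n_total))
  pos <- unlist(lapply(split(seq_len(n_total), chrom_of), function(idx) {
    cumsum(sample(500:2000, length(idx), replace = TRUE))
  }), use.names = FALSE)
  cgi <- sample(names(design$cgi_freqs), n_total, replace = TRUE,
                prob = design$cgi_freqs)
  gr <- sample(names(design$gene_region_freqs), n_total, replace = TRUE,
               prob = design$gene_region_freqs)
  gr[gr == "IGR"] <- ""
  data.frame(probe_id = ids, chrom = paste0("chr", chrom_of), pos = pos,
             gene_regions = gr, cgi_relation = cgi, is_snp = snp_flag,
             stringsAsFactors = FALSE)
}

# Pick a homozygous-deletion window of consecutive regular probes whose
# genomic span contains no SNP probe (runs of consecutive regular
# indices within one chromosome cannot straddle a SNP probe). The
# window shrinks to the longest available run on very small layouts.
.pick_deletion <- function(manifest, width) {
  reg <- which(!manifest$is_snp)
  runs <- list()
  for (idx in split(reg, manifest$chrom[reg])) {
    brk <- cumsum(c(0, diff(idx) != 1))
    runs <- c(runs, unname(split(idx, brk)))
  }
  lens <- lengths(runs)
  w <- min(width, max(lens))
  if (w < 2) stop("no room for a deletion window in this layout")
  ok <- which(lens >= w)
  run <- runs[[ok[sample.int(length(ok), 1)]]]
  start <- sample.int(length(run) - w + 1L, 1)
  block <- run[start:(start + w - 1L)]
  list(probe_ids = manifest$probe_id[block],
       chrom = manifest$chrom[block[1]],
       start = min(manifest$pos[block]),
       end = max(manifest$pos[block]))
}

# Region-bias sampling weights for injecting alterations: multiplied by
# `bias` for OpenSea probes and again for intergenic probes.
.region_weights <- function(manifest, bias) {
  w <- rep(1, nrow(manifest))
  w[manifest$cgi_relation == "OpenSea"] <- w[manifest$cgi_relation == "OpenSea"] * bias
  w[manifest$gene_regions == ""] <- w[manifest$gene_regions == ""] * bias
  w
}

#' Simulate a full cohort with ground truth
#'
#' Generates the beta matrix, sample sheet, copy-number segments and
#' ground truth for a cohort under a [simulation_design()]. Each patient
#' has a private bimodal baseline; each biopsy (or the relapse) receives
#' private site-specific shifts of magnitude `dmp_effect_size` directed
#' toward the opposite methylation mode (relapse shifts are
#' hypomethylating with probability `hypo_fraction`); observed values are
#' purity-mixed with a shared normal profile and perturbed with Gaussian
#' noise; deleted regions yield Uniform(0,1) noise; SNP probes carry the
#' patient's tri-modal genotype in every sample.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed (defaults to the design's).
#' @return List with elements `manifest`, `beta` (matrix), `sheet`,
#'   `segments`, `truth` and `design`.
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  set.seed(seed)
  child <- sample.int(2147483646L, 2)
  manifest <- simulate_manifest(design, seed = child[1])
  set.seed(child[2])

  nP <- nrow(manifest)
  reg_idx <- which(!manifest$is_snp)
  snp_idx <- which(manifest$is_snp)
  probe_ids <- manifest$probe_id
  eff <- design$dmp_effect_size
  geno_levels <- c(0.05, 0.5, 0.95)

  normal_profile <- numeric(nP)
  normal_profile[reg_idx] <- .rbimodal(length(reg_idx), design$baseline_weights)
  normal_profile[snp_idx] <- sample(geno_levels, length(snp_idx), replace = TRUE)

  beta_cols <- list()
  sheet_rows <- list()
  seg_rows <- list()
  truth <- list(patients = list(), truncated_shifts = 0L)
  group_pool <- c("LGG", "MB", "EPN", "HGG", "ATRT")

  make_observed <- function(tumour, purity, deleted_idx, genotype) {
    obs <- numeric(nP)
    obs[reg_idx] <- .clamp01(purity * tumour[reg_idx] +
                               (1 - purity) * normal_profile[reg_idx])
    obs[snp_idx] <- genotype
    if (design$noise_sd > 0)
      obs <- .clamp01(obs + stats::rnorm(nP, 0, design$noise_sd))
    if (length(deleted_idx) > 0)
      obs[deleted_idx] <- stats::runif(length(deleted_idx))
    obs
  }

  simulate_patient <- function(pid, sample_ids, roles, biopsy_index,
                               n_relapse_dmps = NULL, interval = NULL,
                               rate = NULL) {
    ns <- length(sample_ids)
    baseline <- numeric(nP)
    baseline[reg_idx] <- .rbimodal(length(reg_idx), design$baseline_weights)
    genotype <- numeric(nP)
    genotype[snp_idx] <- sample(geno_levels, length(snp_idx), replace = TRUE)

    deleted <- stats::setNames(vector("list", ns), sample_ids)
    for (d in seq_len(design$hd_per_patient)) {
      del <- .pick_deletion(manifest, design$hd_n_probes)
      target <- .resample(sample_ids, 1)
      deleted[[target]] <- union(deleted[[target]], del$probe_ids)
      seg_rows[[length(seg_rows) + 1]] <<- data.frame(
        sample = target, chrom = del$chrom, start = del$start,
        end = del$end, seg_mean = design$hd_seg_mean,
        stringsAsFactors = FALSE)
    }
    deleted_all <- unique(unlist(deleted))
    eligible <- setdiff(reg_idx, match(deleted_all, probe_ids))

    injected <- stats::setNames(vector("list", ns), sample_ids)
    direction <- stats::setNames(vector("list", ns), sample_ids)
    profiles <- stats::setNames(vector("list", ns), sample_ids)
    pool <- eligible
    for (s in seq_len(ns)) {
      profile <- baseline
      if (roles[s] == "spatial") {
        k <- design$spatial_dmps_per_biopsy
        if (k > length(pool)) stop("more injected alterations than eligible probes")
        w <- .region_weights(manifest, design$region_bias)[pool]
        inj <- .resample(pool, k, prob = w)
        pool <- setdiff(pool, inj)
        dir <- ifelse(baseline[inj] > 0.5, -1, 1)
      } else if (roles[s] == "relapse") {
        k <- n_relapse_dmps
        dir_draw <- ifelse(stats::runif(k) < design$hypo_fraction, -1, 1)
        hypo_pool <- pool[baseline[pool] >= eff]
        hyper_pool <- pool[baseline[pool] <= 1 - eff]
        n_hypo <- sum(dir_draw == -1)
        n_hyper <- k - n_hypo
        if (n_hypo > length(hypo_pool) || n_hyper > length(hyper_pool))
          stop("accumulation rate produced more alterations than eligible probes")
        wts <- .region_weights(manifest, design$region_bias)
        inj_hypo <- if (n_hypo > 0)
          .resample(hypo_pool, n_hypo, prob = wts[hypo_pool]) else integer(0)
        hyper_pool <- setdiff(hyper_pool, inj_hypo)
        inj_hyper <- if (n_hyper > 0)
          .resample(hyper_pool, n_hyper, prob = wts[hyper_pool]) else integer(0)
        inj <- c(inj_hypo, inj_hyper)
        dir <- c(rep(-1, n_hypo), rep(1, n_hyper))
        pool <- setdiff(pool, inj)
      } else {  # primary: the baseline itself
        inj <- integer(0)
        dir <- numeric(0)
      }
      shifted <- baseline[inj] + dir * eff
      truth$truncated_shifts <<- truth$truncated_shifts +
        sum(shifted < 0 | shifted > 1)
      profile[inj] <- .clamp01(shifted)
      injected[[s]] <- probe_ids[inj]
      direction[[s]] <- dir
      profiles[[s]] <- profile
    }

    purity <- stats::runif(ns, design$purity_range[1], design$purity_range[2])
    names(purity) <- sample_ids
    for (s in seq_len(ns)) {
      del_idx <- match(deleted[[sample_ids[s]]], probe_ids)
      beta_cols[[sample_ids[s]]] <<- make_observed(profiles[[s]], purity[s],
                                                   del_idx, genotype[snp_idx])
    }
    group <- sample(group_pool, 1)
    sheet_rows[[length(sheet_rows) + 1]] <<- data.frame(
      sample_id = sample_ids, patient_id = pid, role = roles,
      biopsy_index = biopsy_index, purity = purity,
      relapse_interval = ifelse(roles == "relapse", interval %||% NA_real_,
                                NA_real_),
      group_label = group, stringsAsFactors = FALSE)
    truth$patients[[pid]] <<- list(
      patient_id = pid,
      arm = if (all(roles == "spatial")) "spatial" else "temporal",
      samples = sample_ids,
      injected = injected,
      direction = direction,
      deleted = deleted,
      purity = as.list(purity),
      relapse_interval = interval,
      accumulation_rate = rate,
      n_injected_relapse = n_relapse_dmps,
      genotypes = stats::setNames(as.list(genotype[snp_idx]),
                                  probe_ids[snp_idx]))
    invisible(NULL)
  }

  for (i in seq_len(design$n_spatial_patients)) {
    pid <- sprintf("SP%02d", i)
    n_b <- .resample(design$biopsies_min:design$biopsies_max, 1)
    ids <- sprintf("%s_%d", pid, seq_len(n_b))
    simulate_patient(pid, ids, rep("spatial", n_b), seq_len(n_b))
  }
  for (j in seq_len(design$n_temporal_patients)) {
    pid <- sprintf("TP%02d", j)
    interval <- round(stats::runif(1, design$interval_range_days[1],
                                   design$interval_range_days[2]))
    rate <- design$dmp_rate_per_day *
      stats::rlnorm(1, -design$rate_sdlog^2 / 2, design$rate_sdlog)
    k <- stats::rpois(1, rate * interval)
    simulate_patient(pid, c(paste0(pid, "_P"), paste0(pid, "_R")),
                     c("primary", "relapse"), c(1L, 1L),
                     n_relapse_dmps = k, interval = interval, rate = rate)
  }

  # Normal reference: pure normal profile, its own genotype.
  norm_beta <- normal_profile
  if (design$noise_sd > 0)
    norm_beta <- .clamp01(norm_beta + stats::rnorm(nP, 0, design$noise_sd))
  beta_cols[["NORM1"]] <- norm_beta
  sheet_rows[[length(sheet_rows) + 1]] <- data.frame(
    sample_id = "NORM1", patient_id = "NORM", role = "normal_reference",
    biopsy_index = 1L, purity = NA_real_, relapse_interval = NA_real_,
    group_label = NA_character_, stringsAsFactors = FALSE)

  beta <- do.call(cbind, beta_cols)
  rownames(beta) <- probe_ids
  segments <- if (length(seg_rows) > 0) do.call(rbind, seg_rows) else
    data.frame(sample = character(), chrom = character(), start = integer(),
               end = integer(), seg_mean = numeric(), stringsAsFactors = FALSE)
  sheet <- do.call(rbind, sheet_rows)
  rownames(sheet) <- NULL
  if (truth$truncated_shifts > 0)
    message("simulate_cohort: ", truth$truncated_shifts,
            " injected shifts were truncated to [0,1]")
  list(manifest = manifest, beta = beta, sheet = sheet, segments = segments,
       truth = truth, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to disk
#'
#' Emits exactly the files the readers consume (`beta.tsv`,
#' `manifest.tsv`, `segments.seg`, `samples.csv`) plus the ground truth
#' as `ground_truth.json`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             segments = file.path(dir, "segments.seg"),
             sheet = file.path(dir, "samples.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_beta_matrix(cohort$beta, paths["beta"])
  write_probe_manifest(cohort$manifest, paths["manifest"])
  write_seg(cohort$segments, paths["segments"])
  write_sample_sheet(cohort$sheet, paths["sheet"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
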