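# External representations: beta matrix, probe manifest, SEG segments,
# sample sheet, Newick trees. All readers validate and reject malformed
# input rather than repairing it. Coordinates are 1-based inclusive.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a beta-value matrix
#'
#' Reads a tab- or comma-delimited probes-by-samples matrix of
#' methylation beta values. The first column holds probe ids, the header
#' row sample ids; empty cells or `NA` mark missing values.
#'
#' @param path Path to the delimited file.
#' @param manifest Optional probe manifest (see [read_probe_manifest()]);
#'   when supplied, every probe in the matrix must be annotated in it.
#' @return Numeric matrix (probes x samples) with `NA` for missing
#'   values, rownames = probe ids, colnames = sample ids.
#' @export
read_beta_matrix <- function(path, manifest = NULL) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("beta matrix needs a probe id column and at least one sample")
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes))
    stop("duplicate probe ids in beta matrix: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in beta matrix: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    m <- suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))
    bad <- which(is.na(m) & !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric beta value at probe ", probes[bad[1, 1]],
           ", sample ", samples[bad[1, 2]])
  }
  dimnames(m) <- list(probes, samples)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("beta value outside [0,1] at probe ", probes[bad[1, 1]],
         ", sample ", samples[bad[1, 2]], " (value ", m[bad[1, , drop = FALSE]], ")")
  if (!is.null(manifest)) {
    unknown <- setdiff(probes, manifest$probe_id)
    if (length(unknown) > 0)
      stop("probes absent from manifest: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  m
}

#' Write a beta-value matrix
#'
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @export
write_beta_matrix <- function(beta, path, sep = "\t") {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fold_cgi <- function(x) {
  x <- sub("^[NS]_", "", x)
  bad <- setdiff(unique(x), CGI_LEVELS)
  if (length(bad) > 0)
    stop("unknown CGI relation value(s): ", paste(bad, collapse = ", "))
  x
}

#' Read a probe annotation manifest
#'
#' Tab-separated with columns `probe_id`, `chrom`, `pos`, `strand`
#' (ignored), `gene_regions` (semicolon-separated subset of
#' [GENE_REGION_LEVELS]; empty = intergenic), `cgi_relation` (one of
#' [CGI_LEVELS], optionally with `N_`/`S_` orientation prefixes which are
#' folded), and `is_snp` (logical flag for SNP genotyping probes).
#'
#' @param path Path to the TSV manifest.
#' @return `data.frame` with columns probe_id, chrom, pos, gene_regions
#'   (semicolon string, "" = IGR), cgi_relation, is_snp.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA", quote = "\"", comment.char = "",
                          colClasses = "character")
  need <- c("probe_id", "chrom", "pos", "gene_regions", "cgi_relation", "is_snp")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in manifest")
  pos <- as.integer(df$pos)
  if (any(is.na(pos)) || any(pos < 1))
    stop("manifest positions must be integers >= 1")
  gr <- vapply(strsplit(ifelse(is.na(df$gene_regions), "", df$gene_regions), ";",
                        fixed = TRUE),
               function(parts) {
                 parts <- unique(parts[nzchar(parts)])
                 bad <- setdiff(parts, GENE_REGION_LEVELS)
                 if (length(bad) > 0)
                   stop("unknown gene region value(s): ", paste(bad, collapse = ", "))
                 paste(parts, collapse = ";")
               }, character(1))
  out <- data.frame(
    probe_id = df$probe_id,
    chrom = df$chrom,
    pos = pos,
    gene_regions = gr,
    cgi_relation = .fold_cgi(df$cgi_relation),
    is_snp = as.logical(toupper(df$is_snp) %in% c("TRUE", "T", "1")) |
      df$is_snp == "1",
    stringsAsFactors = FALSE
  )
  out
}

#' Write a probe manifest
#' @param manifest Manifest data.frame as returned by
#'   [read_probe_manifest()] or [simulate_manifest()].
#' @param path Output path (TSV).
#' @export
write_probe_manifest <- function(manifest, path) {
  df <- data.frame(probe_id = manifest$probe_id, chrom = manifest$chrom,
                   pos = manifest$pos, strand = "*",
                   gene_regions = manifest$gene_regions,
                   cgi_relation = manifest$cgi_relation,
                   is_snp = manifest$is_snp, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments (IGV SEG format)
#'
#' Expects the standard SEG columns `ID`, `chrom`, `loc.start`,
#' `loc.end`, optionally `num.mark`, and `seg.mean` (tab-separated,
#' 1-based inclusive coordinates). Segments of one sample on one
#' chromosome must not overlap.
#'
#' @param path Path to the SEG file.
#' @return `data.frame` with columns sample, chrom, start, end, seg_mean.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      seg_mean = numeric(), stringsAsFactors = FALSE))
  }
  cn <- tolower(colnames(df))
  pick <- function(alts) {
    i <- which(cn %in% alts)[1]
    if (is.na(i)) stop("SEG file missing column: ", alts[1])
    df[[i]]
  }
  out <- data.frame(
    sample = as.character(pick(c("id", "sample"))),
    chrom = as.character(pick("chrom")),
    start = as.integer(pick(c("loc.start", "start"))),
    end = as.integer(pick(c("loc.end", "end"))),
    seg_mean = as.numeric(pick(c("seg.mean", "seg_mean"))),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end))
    stop("SEG segment with start > end")
  sp <- split(out, paste(out$sample, out$chrom, sep = "\r"))
  for (g in sp) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    if (any(g$start[-1] <= g$end[-nrow(g)]))
      stop("overlapping segments for sample ", g$sample[1],
           " on ", g$chrom[1])
  }
  out
}

#' Write copy-number segments in IGV SEG format
#' @param segments Segment data.frame (sample, chrom, start, end,
#'   seg_mean).
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(ID = segments$sample, chrom = segments$chrom,
                   loc.start = segments$start, loc.end = segments$end,
                   num.mark = if ("num_mark" %in% names(segments))
                     segments$num_mark else NA_integer_,
                   seg.mean = segments$seg_mean,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `patient_id`, `role` (one of
#' [SAMPLE_ROLES]), `biopsy_index`, and optional `purity` (fraction of
#' tumour cells, in \[0,1\]), `relapse_interval` (days from primary to
#' relapse surgery, on relapse rows) and `group_label` (free grouping
#' label such as a methylation superfamily, used only by the statistics
#' stage).
#'
#' @param path Path to the CSV.
#' @return `data.frame` with the columns above.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "patient_id", "role", "biopsy_index")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(df$role), SAMPLE_ROLES)
  if (length(bad) > 0)
    stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  if (!"purity" %in% colnames(df)) df$purity <- NA_real_
  if (!"relapse_interval" %in% colnames(df)) df$relapse_interval <- NA_real_
  if (!"group_label" %in% colnames(df)) df$group_label <- NA_character_
  df$purity <- as.numeric(df$purity)
  if (any(!is.na(df$purity) & (df$purity < 0 | df$purity > 1)))
    stop("purity must lie in [0,1]")
  df$relapse_interval <- as.numeric(df$relapse_interval)
  if (any(!is.na(df$relapse_interval) & df$relapse_interval < 0))
    stop("relapse_interval must be >= 0")
  df$biopsy_index <- as.integer(df$biopsy_index)
  if (any(is.na(df$biopsy_index) | df$biopsy_index < 1))
    stop("biopsy_index must be an integer >= 1")
  df
}

#' Write a sample sheet
#' @param sheet Sample sheet data.frame.
#' @param path Output CSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.quote_newick_label <- function(x) {
  needs <- grepl("[]['():;,[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs], fixed = TRUE), "'")
  x
}

.newick_subtree <- function(tree, node, labels) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    return(list(text = labels[node], min_leaf = tree$tip.label[node]))
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  parts <- lapply(kids, function(k) {
    sub <- .newick_subtree(tree, k, labels)
    ei <- which(tree$edge[, 1] == node & tree$edge[, 2] == k)
    len <- if (!is.null(tree$edge.length))
      paste0(":", format(tree$edge.length[ei], digits = 15)) else ""
    list(text = paste0(sub$text, len), min_leaf = sub$min_leaf)
  })
  ord <- order(vapply(parts, `[[`, character(1), "min_leaf"))
  list(text = paste0("(", paste(vapply(parts[ord], `[[`, character(1), "text"),
                                collapse = ","), ")"),
       min_leaf = min(vapply(parts, `[[`, character(1), "min_leaf")))
}

#' Serialize a phylogenetic tree to a Newick string
#'
#' Deterministic serializer: at every internal node children are ordered
#' by the lexicographically smallest leaf label in their subtree, so
#' equal trees always produce identical text. Labels containing Newick
#' metacharacters are single-quoted with internal quotes doubled.
#'
#' @param tree An `ape` `phylo` object with unique tip labels.
#' @param path Optional path; when given the string is also written
#'   there.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  labels <- .quote_newick_label(tree$tip.label)
  root <- length(tree$tip.label) + 1L
  txt <- paste0(.newick_subtree(tree, root, labels)$text, ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
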