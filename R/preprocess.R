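#' Zero out sub-threshold read counts within each sample
#'
#' Counts below `min_rel` of a sample's total reads are set to zero.  The
#' rationale is tag jumping / low-level cross-contamination on pooled
#' sequencing runs, which deposits a small fraction of a sample's reads into
#' other samples; the artefact is per sample, so the default scope zeroes
#' entries per sample rather than removing whole OTUs.  The strict `<`
#' matches the usual statement of the rule: an entry at exactly 0.03% of the
#' sample total is retained.
#'
#' @param counts samples x OTUs non-negative integer matrix.
#' @param min_rel relative-abundance threshold (default 0.0003 = 0.03%).
#' @param scope `"sample"` (zero entries per sample) or `"table"` (remove an
#'   OTU everywhere if it fails the threshold in every sample where present).
#' @return The filtered count matrix (attributes preserved).
#' @export
filter_low_abundance <- function(counts, min_rel = 0.0003,
                                 scope = c("sample", "table")) {
  scope <- match.arg(scope)
  if (length(counts) == 0 || nrow(counts) == 0 || ncol(counts) == 0)
    stop("empty read-count table")
  if (min_rel < 0) stop("configuration error: negative min_rel")
  if (min_rel == 0) return(counts)
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("samples with zero reads: ",
                          paste(rownames(counts)[tot <= 0], collapse = ", "))
  rel <- counts / tot
  if (scope == "sample") {
    counts[rel < min_rel & counts > 0] <- 0L
  } else {
    fail <- vapply(seq_len(ncol(counts)), function(j) {
      pres <- counts[, j] > 0
      all(rel[pres, j] < min_rel) && any(pres)
    }, logical(1))
    counts[, fail] <- 0L
  }
  counts
}

#' Drop samples with insufficient sequencing depth
#'
#' @param counts samples x OTUs count matrix.
#' @param min_reads retention threshold; samples with total reads strictly
#'   below it are removed (default 3000).
#' @return Filtered matrix; dropped sample ids in attribute
#'   `"dropped_samples"`.
#' @export
drop_low_depth_samples <- function(counts, min_reads = 3000) {
  tot <- rowSums(counts)
  drop <- tot < min_reads
  if (all(drop)) stop("pipeline error: all samples below ", min_reads,
                      " reads")
  if (any(drop))
    message("dropping ", sum(drop), " sample(s) with < ", min_reads,
            " reads: ", paste(rownames(counts)[drop], collapse = ", "))
  out <- counts[!drop, , drop = FALSE]
  attr(out, "dropped_samples") <- rownames(counts)[drop]
  attr(out, "design") <- {
    d <- attr(counts, "design")
    if (!is.null(d)) d[!drop, , drop = FALSE] else NULL
  }
  out
}

#' Merge replicate samples into composite samples
#'
#' Read counts are summed within each group (the union of presences is the
#' binary consequence); a group of size one passes through unchanged.
#'
#' @param counts samples x OTUs count matrix.
#' @param grouping named character vector mapping sample id to composite id,
#'   or a data frame with columns `sample_id` and `composite_id`.
#' @param mode `"sum"` (default) or `"union"` (binarise then take max).
#' @return Composite x OTUs matrix, rows ordered by first appearance.
#' @export
merge_replicates <- function(counts, grouping, mode = c("sum", "union")) {
  mode <- match.arg(mode)
  if (is.data.frame(grouping))
    grouping <- setNames(as.character(grouping$composite_id),
                         grouping$sample_id)
  miss <- setdiff(rownames(counts), names(grouping))
  if (length(miss))
    stop("samples missing from grouping: ", paste(miss, collapse = ", "))
  g <- grouping[rownames(counts)]
  m <- if (mode == "union") (counts > 0) + 0L else counts
  out <- rowsum(m, group = g, reorder = FALSE)
  if (mode == "union") out <- (out > 0) + 0L
  out
}

#' Assign a taxonomic rank from a best-hit identity percentage
#'
#' Strict thresholds: >97% species, >95% genus, >90% family, >85% order;
#' at or below 85% the OTU is unassigned (and excluded downstream).
#'
#' @param best_identity_pct numeric vector in \[0, 100\].
#' @return Character vector of ranks.
#' @export
assign_rank <- function(best_identity_pct) {
  p <- best_identity_pct
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("best_identity_pct outside [0, 100]")
  ifelse(p > 97, "species",
         ifelse(p > 95, "genus",
                ifelse(p > 90, "family",
                       ifelse(p > 85, "order", "unassigned"))))
}

#' Build the presence/absence community matrix
#'
#' From a composite-level count table: removes OTUs that are unassigned
#' (<=85% identity) or flagged non-meiofauna, binarises the remaining counts,
#' drops OTUs present in fewer than `min_occupancy` composites (joint models
#' of occurrence are sensitive to false-negative-ridden rare OTUs), and drops
#' any composite left without OTUs.
#'
#' @param counts composite x OTUs count matrix (already merged).
#' @param taxonomy data frame with `otu_id`, `best_identity_pct`,
#'   `group`, `is_meiofauna` (rank recomputed via [assign_rank()]).
#' @param min_occupancy minimum number of composites an OTU must occupy.
#' @return `pa_table` binary matrix with attributes `"groups"` (named
#'   higher-taxon labels for retained OTUs) and `"summary"` (tallies).
#' @export
build_community_matrix <- function(counts, taxonomy, min_occupancy = 10) {
  tax <- taxonomy[match(colnames(counts), taxonomy$otu_id), , drop = FALSE]
  if (any(is.na(tax$otu_id)))
    stop("taxonomy missing for OTUs: ",
         paste(colnames(counts)[is.na(tax$otu_id)], collapse = ", "))
  rank <- assign_rank(tax$best_identity_pct)
  keep_tax <- rank != "unassigned" & tax$is_meiofauna
  y <- (counts[, keep_tax, drop = FALSE] > 0) + 0L
  occ <- colSums(y)
  y <- y[, occ >= min_occupancy, drop = FALSE]
  if (ncol(y) == 0) stop("zero OTUs retained after filters")
  empty <- rowSums(y) == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " composite(s) with no retained OTUs")
    y <- y[!empty, , drop = FALSE]
  }
  grp <- setNames(tax$group[keep_tax][match(colnames(y),
                                            tax$otu_id[keep_tax])],
                  colnames(y))
  structure(y, class = c("pa_table", class(y)), groups = grp,
            summary = list(n_samples = nrow(y), n_otus = ncol(y),
                           n_groups = length(unique(grp)),
                           group_tally = sort(table(grp), decreasing = TRUE)))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: per-sample low-abundance zeroing, low-depth sample
#' removal, replicate merging to composites, and the taxonomy/occupancy
#' community-matrix construction.
#'
#' @param counts physical-sample x OTUs count matrix.
#' @param taxonomy taxonomy data frame (see [build_community_matrix()]).
#' @param grouping sample to composite mapping (see [merge_replicates()]).
#' @param min_rel,min_reads,min_occupancy stage thresholds.
#' @param scope,merge_mode stage options.
#' @return The final `pa_table`.
#' @export
preprocess_community <- function(counts, taxonomy, grouping,
                                 min_rel = 0.0003, min_reads = 3000,
                                 min_occupancy = 10,
                                 scope = "sample", merge_mode = "sum") {
  x <- filter_low_abundance(counts, min_rel = min_rel, scope = scope)
  x <- drop_low_depth_samples(x, min_reads = min_reads)
  x <- merge_replicates(x, grouping, mode = merge_mode)
  build_community_matrix(x, taxonomy, min_occupancy = min_occupancy)
}
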