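#' Coverage filter on raw counts
#'
#' Keeps positions whose raw first-base-in-read coverage reaches `min_cov`
#' in at least one library; everything else is removed before testing. With
#' the default of 10 this is the funnel's first stage.
#'
#' @param table A `position_table`.
#' @param min_cov Minimum raw count in at least one library (>= 1).
#' @return Filtered `position_table`.
#' @export
filter_low_coverage <- function(table, min_cov = 10) {
  stopifnot(min_cov >= 1)
  if (!nrow(table$key))
    return(table)
  keep <- apply(table$counts, 1, max) >= min_cov
  position_table(table$key[keep, , drop = FALSE],
                 table$counts[keep, , drop = FALSE],
                 table$libraries)
}

#' Select candidate 5' ends
#'
#' A position is a cleavage-site candidate when its normalized coverage
#' fold change (wild type over mutant) is at least `fc_min` with
#' padj < `alpha` — the signal is depleted when the nuclease is inactive.
#' It is an enriched-site candidate when the mutant shows at least the same
#' fold enrichment (a primary or upstream-nuclease 5' end stabilized in the
#' mutant). The two sets are disjoint by construction.
#'
#' @param results A `test_result` data frame (see [run_difftest()]).
#' @param fc_min Minimum linear fold change; must be > 1 (default 2, i.e.
#'   |log2fc| >= 1).
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @return Subset of `results` with a `class` column in
#'   `{cleavage, enriched}`.
#' @export
classify_candidates <- function(results, fc_min = 2, alpha = 0.05) {
  if (fc_min <= 1) stop("fc_min must be > 1")
  lfc <- log2(fc_min)
  sig <- results$padj < alpha
  cls <- rep(NA_character_, nrow(results))
  cls[sig & results$log2fc >= lfc] <- "cleavage"
  cls[sig & results$log2fc <= -lfc] <- "enriched"
  out <- results[!is.na(cls), , drop = FALSE]
  out$class <- cls[!is.na(cls)]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

# center of one cluster: member nearest the arithmetic mean of members;
# ties by larger base_mean, then leftmost
cluster_center <- function(positions, base_mean) {
  mu <- mean(positions)
  d <- abs(positions - mu)
  cand <- which(d <= min(d) + 1e-9)
  if (length(cand) > 1L)
    cand <- cand[base_mean[cand] >= max(base_mean[cand]) - 1e-12]
  positions[cand[1L]]   # members sorted, so [1] is leftmost among ties
}

#' Merge neighbouring candidate positions into sites
#'
#' Endoribonucleases rarely cut at one exact phosphodiester bond, so
#' adjacent significant 5' ends are treated as a single site: candidates on
#' the same replicon, strand and of the same class are chained whenever
#' consecutive positions are at most `proximity` nt apart (single linkage,
#' i.e. `bedtools cluster -d` semantics), and each chain is represented by
#' its center position downstream.
#'
#' @param candidates Output of [classify_candidates()], restricted to one
#'   class.
#' @param proximity Maximum distance (nt) joining two candidates (default 3).
#' @return Data frame of `site_cluster`s: `replicon`, `strand`, `class`,
#'   `start`, `end`, `n_members`, `center`, `center_base_mean`, `padj_min`,
#'   `log2fc_center`, `members` (comma-separated positions).
#' @export
cluster_candidates <- function(candidates, proximity = 3) {
  if (!nrow(candidates)) {
    return(data.frame(replicon = character(), strand = character(),
                      class = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      center = integer(), center_base_mean = numeric(),
                      padj_min = numeric(), log2fc_center = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  }
  if (length(unique(candidates$class)) > 1L)
    stop("cluster_candidates() takes candidates of a single class; ",
         "cluster cleavage and enriched sites independently")
  out <- list()
  grp <- split(candidates,
               paste(candidates$replicon, candidates$strand))
  for (g in grp) {
    g <- g[order(g$position), , drop = FALSE]
    brk <- c(0, cumsum(diff(g$position) > proximity))
    for (cl in split(seq_len(nrow(g)), brk)) {
      pos <- g$position[cl]
      bm <- g$base_mean[cl]
      ctr <- cluster_center(pos, bm)
      ci <- cl[match(ctr, pos)]
      out[[length(out) + 1L]] <- data.frame(
        replicon = g$replicon[1], strand = g$strand[1],
        class = g$class[1], start = min(pos), end = max(pos),
        n_members = length(pos), center = ctr,
        center_base_mean = g$base_mean[ci],
        padj_min = min(g$padj[cl]),
        log2fc_center = g$log2fc[ci],
        members = paste(pos, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$strand, res$center), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Candidate selection and clustering in one call
#'
#' Runs [classify_candidates()] and clusters each class independently, even
#' where wild-type- and mutant-enriched ends interleave at neighbouring
#' nucleotides.
#'
#' @inheritParams classify_candidates
#' @inheritParams cluster_candidates
#' @return Combined cluster data frame for both classes.
#' @export
call_sites <- function(results, fc_min = 2, alpha = 0.05, proximity = 3) {
  cands <- classify_candidates(results, fc_min = fc_min, alpha = alpha)
  rbind(cluster_candidates(cands[cands$class == "cleavage", , drop = FALSE],
                           proximity),
        cluster_candidates(cands[cands$class == "enriched", , drop = FALSE],
                           proximity))
}

#' Export site clusters as BED6
#'
#' One record per cluster at its center position, converted to the BED
#' 0-based half-open convention at the writer only. The score is the capped
#' Phred-scaled minimum adjusted p-value of the cluster's members.
#'
#' @param clusters Cluster data frame from [cluster_candidates()].
#' @param path Optional output path; when given, a BED6 file is written.
#' @return Data frame with BED columns `chrom`, `chromStart`, `chromEnd`,
#'   `name`, `score`, `strand` (invisibly when writing).
#' @export
export_sites <- function(clusters, path = NULL) {
  score <- round(pmin(1000, -10 * log10(pmax(clusters$padj_min, 1e-300))))
  bed <- data.frame(
    chrom = clusters$replicon,
    chromStart = clusters$center - 1L,
    chromEnd = clusters$center,
    name = sprintf("%s_%05d", clusters$class, seq_len(nrow(clusters))),
    score = if (nrow(clusters)) as.integer(score) else integer(0),
    strand = clusters$strand,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
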