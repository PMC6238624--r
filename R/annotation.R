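FEATURE_TYPES <- c("CDS", "five_prime_UTR", "three_prime_UTR",
                   "rRNA", "tRNA", "sRNA", "other")

# structural RNAs before CDS before UTRs; a site inside both an sRNA and
# the 3' UTR it is processed from counts as sRNA
CATEGORY_PRECEDENCE <- c(rRNA = 1, tRNA = 2, sRNA = 3, CDS = 4,
                         five_prime_UTR = 5, three_prime_UTR = 6, other = 7)

DEFAULT_TYPE_ALIASES <- c("5UTR" = "five_prime_UTR",
                          "3UTR" = "three_prime_UTR",
                          "UTR5" = "five_prime_UTR",
                          "UTR3" = "three_prime_UTR",
                          "ncRNA" = "sRNA",
                          "small_regulatory_ncRNA" = "sRNA")

#' Parse a GFF3 annotation into a feature table
#'
#' Features are typed by GFF column 3 through a configurable alias map;
#' unknown types become `"other"`. The gene identifier is taken from the
#' `ID` attribute, falling back to `locus_tag`. Container records
#' (`gene`, `region`, `exon`, `chromosome`) are dropped by default so they
#' do not shadow the typed child features.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param aliases Named character vector mapping nonstandard type strings
#'   onto the canonical set `r paste(FEATURE_TYPES, collapse = ", ")`.
#' @param drop_types GFF types skipped entirely.
#' @return A `feature_set` data frame: `replicon`, `type`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @export
parse_gff <- function(path, aliases = DEFAULT_TYPE_ALIASES,
                      drop_types = c("gene", "region", "exon",
                                     "chromosome")) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end < df$start))
    stop("feature with end < start at line(s): ",
         paste(which(df$end < df$start), collapse = ", "))
  df <- df[!df$type %in% drop_types, , drop = FALSE]
  ty <- as.character(df$type)
  ali <- !is.na(aliases[ty])
  ty[ali] <- aliases[ty[ali]]
  ty[!ty %in% FEATURE_TYPES] <- "other"
  gene_id <- if ("ID" %in% names(df)) as.character(df$ID)
             else rep(NA_character_, nrow(df))
  if ("locus_tag" %in% names(df)) {
    miss <- is.na(gene_id) | gene_id == ""
    gene_id[miss] <- as.character(df$locus_tag[miss])
  }
  if (anyNA(gene_id) || any(gene_id == ""))
    stop("feature(s) without ID or locus_tag attribute: record(s) ",
         paste(utils::head(which(is.na(gene_id) | gene_id == ""), 5),
               collapse = ", "))
  if (nrow(df) && !all(as.character(df$strand) %in% c("+", "-")))
    stop("all features must carry an explicit +/- strand")
  out <- data.frame(replicon = as.character(df$seqnames), type = ty,
                    start = df$start, end = df$end,
                    strand = as.character(df$strand), gene_id = gene_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Write a feature table as GFF3
#' @param features A `feature_set` data frame.
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    lines <- sprintf("%s\ttierseq\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$replicon, features$type, features$start,
                     features$end, features$strand, features$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

features_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$replicon,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
}

sites_granges <- function(clusters) {
  GenomicRanges::GRanges(
    seqnames = clusters$replicon,
    ranges = IRanges::IRanges(clusters$center, clusters$center),
    strand = clusters$strand)
}

#' Assign site clusters to RNA categories
#'
#' A site matches a feature when its center position lies within the
#' feature span on the same strand; when several features overlap, one
#' category wins by precedence rRNA > tRNA > sRNA > CDS > 5'UTR > 3'UTR >
#' other. Sites matching nothing are `"intergenic"`. Every site gets
#' exactly one label, so category counts sum to the number of sites.
#'
#' @param clusters Cluster data frame (needs `replicon`, `strand`,
#'   `center`).
#' @param features A `feature_set`.
#' @return List: `sites` (clusters plus `category` and `feature_id`
#'   columns) and `category_counts` (data frame `category`, `n`, by class
#'   if a `class` column is present).
#' @export
assign_sites <- function(clusters, features) {
  cat_lab <- rep("intergenic", nrow(clusters))
  feat_id <- rep(NA_character_, nrow(clusters))
  if (nrow(clusters) && nrow(features)) {
    hits <- GenomicRanges::findOverlaps(sites_granges(clusters),
                                        features_granges(features),
                                        ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      prec <- CATEGORY_PRECEDENCE[features$type[sh]]
      # stable order: by site, then precedence, then feature order
      o <- order(qh, prec, sh)
      first <- !duplicated(qh[o])
      cat_lab[qh[o][first]] <- features$type[sh[o][first]]
      feat_id[qh[o][first]] <- features$gene_id[sh[o][first]]
    }
  }
  sites <- clusters
  sites$category <- factor(cat_lab,
                           levels = c(FEATURE_TYPES, "intergenic"))
  sites$feature_id <- feat_id
  cc <- as.data.frame(table(category = sites$category),
                      stringsAsFactors = FALSE)
  names(cc)[2] <- "n"
  list(sites = sites, category_counts = cc)
}

#' Per-feature site density (sites per kilobase)
#'
#' Counts, for every annotated feature, the site centers falling inside it
#' on the same strand (each site may contribute to every feature containing
#' it here — precedence applies to category tallies, not densities) and
#' reports density = n_sites / length * 1000. Features without any site are
#' kept: the zero class is part of the reported distribution.
#'
#' @param clusters Cluster data frame.
#' @param features A `feature_set`.
#' @return List: `records` (per feature: `gene_id`, `type`, `n_sites`,
#'   `length_nt`, `density`) and `summary` (per type: quartiles of density,
#'   `n_genes`, `n_zero`).
#' @export
site_density <- function(clusters, features) {
  n_sites <- integer(nrow(features))
  if (nrow(clusters) && nrow(features)) {
    hits <- GenomicRanges::findOverlaps(sites_granges(clusters),
                                        features_granges(features),
                                        ignore.strand = FALSE)
    tab <- table(S4Vectors::subjectHits(hits))
    n_sites[as.integer(names(tab))] <- as.integer(tab)
  }
  len <- features$end - features$start + 1L
  records <- data.frame(gene_id = features$gene_id, type = features$type,
                        n_sites = n_sites, length_nt = len,
                        density = n_sites / len * 1000,
                        stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(records, records$type), function(r) {
    q <- stats::quantile(r$density, c(0.25, 0.5, 0.75))
    data.frame(type = r$type[1], n_genes = nrow(r),
               n_zero = sum(r$n_sites == 0),
               q1 = q[[1]], median = q[[2]], q3 = q[[3]],
               max = max(r$density), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}

#' Site frequency relative to start and stop codons
#'
#' For every (site, CDS) pair within `window` nt, the offset is the signed
#' distance from the site center to the first base of the start codon
#' (respectively the first base of the stop codon), measured 5'->3' in
#' transcript orientation: on the `-` strand the start codon sits at the
#' feature's `end` coordinate and distances are negated. Offset 0 means the
#' site coincides with the A of AUG (or the first base of the stop codon).
#'
#' @param clusters Cluster data frame.
#' @param cds_features A `feature_set` (rows with `type == "CDS"` are
#'   used).
#' @param window Half-width of the offset window in nt (default 100).
#' @return List of two data frames `start` and `stop`, each with columns
#'   `offset` (-window..window) and `count`.
#' @export
codon_relative_frequency <- function(clusters, cds_features, window = 100) {
  cds <- cds_features[cds_features$type == "CDS", , drop = FALSE]
  count_around <- function(anchor_pos) {
    counts <- stats::setNames(integer(2 * window + 1),
                              -window:window)
    if (nrow(cds) && nrow(clusters)) {
      anchors <- GenomicRanges::GRanges(
        seqnames = cds$replicon,
        ranges = IRanges::IRanges(pmax(1L, anchor_pos - window),
                                  anchor_pos + window),
        strand = cds$strand)
      hits <- GenomicRanges::findOverlaps(sites_granges(clusters), anchors,
                                          ignore.strand = FALSE)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      off <- clusters$center[qh] - anchor_pos[sh]
      off <- ifelse(cds$strand[sh] == "-", -off, off)
      off <- off[abs(off) <= window]
      tab <- table(off)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
    data.frame(offset = -window:window, count = as.integer(counts))
  }
  start_anchor <- ifelse(cds$strand == "+", cds$start, cds$end)
  stop_anchor <- ifelse(cds$strand == "+", cds$end - 2L, cds$start + 2L)
  list(start = count_around(start_anchor),
       stop = count_around(stop_anchor))
}
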