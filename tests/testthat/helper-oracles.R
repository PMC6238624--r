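# Independent brute-force oracles and tiny fixture builders used across
# the suite. Oracles are written from the definitions, not from the
# package code paths they check.

# step-up BH from the definition: padj_(k) = min_{l >= k} m p_(l) / l,
# capped at 1, mapped back to input order
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  padj_sorted <- vapply(seq_len(m), function(k)
    min(1, min(m * ps[k:m] / (k:m))), numeric(1))
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# transitive closure of the "distance <= proximity" relation: connected
# components by repeated expansion over the full adjacency matrix
cluster_bruteforce <- function(positions, proximity = 3) {
  n <- length(positions)
  adj <- abs(outer(positions, positions, "-")) <= proximity
  comp <- seq_len(n)
  repeat {
    new_comp <- vapply(seq_len(n), function(i)
      min(comp[adj[i, ]]), numeric(1))
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  comp
}

# center rule restated: member nearest the arithmetic mean, ties by
# larger base_mean, remaining ties leftmost
center_bruteforce <- function(positions, base_mean) {
  mu <- mean(positions)
  d <- abs(positions - mu)
  best <- which(abs(d - min(d)) < 1e-9)
  if (length(best) > 1) {
    bm <- base_mean[best]
    best <- best[abs(bm - max(bm)) < 1e-12]
  }
  min(positions[best])
}

toy_genome <- function(seqs = c(chr1 = strrep("ACGT", 50))) {
  genome_index(seqs)
}

# minimal position table: counts is a matrix, one column per library
toy_table <- function(counts, positions = NULL, strand = "+",
                      replicon = "chr1",
                      conditions = rep(c("wild_type", "mutant"),
                                       each = ncol(counts) / 2)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(positions)) positions <- seq_len(nrow(counts)) * 10L
  libs <- data.frame(
    library_id = sprintf("lib%d", seq_len(ncol(counts))),
    condition = conditions, stringsAsFactors = FALSE)
  colnames(counts) <- libs$library_id
  position_table(
    data.frame(replicon = rep_len(replicon, length(positions)),
               strand = rep_len(strand, length(positions)),
               position = positions, stringsAsFactors = FALSE),
    counts, libs)
}

# candidate data frame as produced by classify_candidates()
toy_candidates <- function(positions, class = "cleavage",
                           base_mean = NULL, strand = "+",
                           replicon = "chr1") {
  if (is.null(base_mean)) base_mean <- rep(100, length(positions))
  data.frame(replicon = replicon, strand = strand, position = positions,
             base_mean = base_mean, log2fc = 2, se = 0.3,
             p_value = 1e-6, padj = 1e-4, class = class,
             stringsAsFactors = FALSE)
}

toy_features <- function(...) {
  df <- rbind(...)
  class(df) <- c("feature_set", "data.frame")
  df
}

feat <- function(type, start, end, strand = "+", gene_id = NULL,
                 replicon = "chr1") {
  data.frame(replicon = replicon, type = type, start = start, end = end,
             strand = strand,
             gene_id = gene_id %||% paste0(type, "_", start),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mirror transformation: reverse-complement world with pos -> L + 1 - pos
mirror_table <- function(tab, L) {
  key <- tab$key
  key$position <- L + 1L - key$position
  key$strand <- ifelse(key$strand == "+", "-", "+")
  o <- order(key$replicon, key$strand, key$position)
  position_table(key[o, , drop = FALSE],
                 tab$counts[o, , drop = FALSE], tab$libraries)
}

mirror_features <- function(features, L) {
  out <- features
  out$start <- L + 1L - features$end
  out$end <- L + 1L - features$start
  out$strand <- ifelse(features$strand == "+", "-", "+")
  out
}

mirror_genome <- function(genome) {
  genome_index(Biostrings::reverseComplement(genome$seqs))
}
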