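MOTIF_BASES <- c("A", "C", "G", "T")

#' Mononucleotide background composition of a genome
#'
#' In a GC-rich genome (~68.8% GC for the organism this analysis targets) a
#' uniform background would fabricate AU enrichment, so motif statistics
#' default to the genome's own composition.
#'
#' @param genome A [genome_index].
#' @return Named numeric 4-vector (A, C, G, T) summing to 1.
#' @export
genome_background <- function(genome) {
  freq <- colSums(Biostrings::alphabetFrequency(genome$seqs)[, MOTIF_BASES,
                                                             drop = FALSE])
  freq / sum(freq)
}

#' Extract sequence windows around site centers
#'
#' For a `+` strand site the window is `genome[center - flank, center +
#' flank]`; for a `-` strand site its reverse complement, so windows always
#' read 5'->3' in transcript orientation with the site base at (1-based)
#' window position `flank + 1`. Sites closer than `flank` to a replicon
#' edge are skipped and counted.
#'
#' @param clusters Cluster data frame (`replicon`, `strand`, `center`).
#' @param genome A [genome_index].
#' @param flank Bases on each side of the center (default 5; use >= 6 when
#'   the windows feed [shift_align()]).
#' @return Data frame `replicon`, `strand`, `center`, `seq`, `shift` (0);
#'   attribute `n_skipped` gives the number of edge-dropped sites.
#' @export
extract_windows <- function(clusters, genome, flank = 5) {
  lens <- genome$lengths[clusters$replicon]
  ok <- clusters$center > flank & clusters$center + flank <= lens
  n_skip <- sum(!ok)
  if (n_skip) warning(n_skip, " site(s) within ", flank,
                      " nt of a replicon edge skipped")
  cl <- clusters[ok, , drop = FALSE]
  seqs <- character(nrow(cl))
  for (rep_id in unique(cl$replicon)) {
    sel <- cl$replicon == rep_id
    v <- Biostrings::Views(genome$seqs[[rep_id]],
                           start = cl$center[sel] - flank,
                           end = cl$center[sel] + flank)
    s <- as.character(Biostrings::DNAStringSet(v))
    rev <- cl$strand[sel] == "-"
    if (any(rev))
      s[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s[rev])))
    seqs[sel] <- s
  }
  out <- data.frame(replicon = cl$replicon, strand = cl$strand,
                    center = cl$center, seq = seqs, shift = 0L,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skip
  attr(out, "flank") <- flank
  out
}

window_core <- function(windows, width, max_shift) {
  # central `width` nt of each window sequence, offset by the window shift
  left <- (nchar(windows$seq) - width) %/% 2 + 1L
  substr(windows$seq, left + windows$shift,
         left + windows$shift + width - 1L)
}

#' Position frequency / information-content matrix
#'
#' Column-wise base counts over aligned windows, frequencies, and per
#' column information content computed as the relative entropy (bits) of
#' the observed frequencies versus the background: IC = sum_b f_b *
#' log2(f_b / q_b), with 0 * log(0) = 0. `N` bases are excluded from the
#' affected column's frequencies.
#'
#' @param windows Window data frame from [extract_windows()] (any `shift`
#'   column is honoured).
#' @param background Strictly positive 4-vector (A, C, G, T); see
#'   [genome_background()]. Default: uniform.
#' @param width Number of matrix columns (default 11 = 5 + site + 5; must
#'   fit inside the window sequences at the maximal |shift|).
#' @return A `motif_matrix`: list with `counts` (4 x width), `frequencies`
#'   (column-stochastic), `ic` (bits per column), `background`, `n`.
#' @export
build_matrix <- function(windows, background = NULL, width = 11) {
  if (!nrow(windows)) stop("empty window set")
  if (is.null(background)) background <- rep(0.25, 4)
  background <- background / sum(background)
  if (any(background <= 0)) stop("background must be strictly positive")
  names(background) <- MOTIF_BASES
  max_shift <- max(abs(windows$shift))
  if (any(nchar(windows$seq) < width + 2 * max_shift))
    stop("window sequences too short for width ", width,
         " with |shift| up to ", max_shift)
  core <- window_core(windows, width, max_shift)
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(core))
  counts <- matrix(0L, 4, width, dimnames = list(MOTIF_BASES, NULL))
  present <- intersect(rownames(mat), MOTIF_BASES)
  counts[present, ] <- mat[present, , drop = FALSE]
  freq <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  ic <- apply(freq, 2, function(f) {
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / background[nz]))
  })
  structure(list(counts = counts, frequencies = freq, ic = ic,
                 background = background, n = nrow(windows)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %d windows x %d columns; total IC %.2f bits\n",
              x$n, ncol(x$counts), sum(x$ic)))
  invisible(x)
}

# log2 likelihood-ratio score of core sequences under a (pseudocounted)
# frequency matrix versus the background
score_cores <- function(cores, freq_pc, background) {
  vapply(strsplit(cores, ""), function(b) {
    idx <- match(b, MOTIF_BASES)
    keep <- !is.na(idx)
    sum(log2(freq_pc[cbind(idx[keep], which(keep))] /
               background[idx[keep]]))
  }, numeric(1))
}

#' Align windows with one base of shifting allowed
#'
#' Iterative refinement: build the matrix from the current shifts, then
#' re-assign every window the shift in `-max_shift..max_shift` maximizing
#' its log2 likelihood ratio against the background (ties broken toward
#' smaller |shift|, then the negative shift), until no assignment changes
#' or `max_iter` is reached. Iterations that would decrease the total
#' objective are rejected, so the objective trace is non-decreasing and the
#' procedure is deterministic given the input order.
#'
#' @param windows Window data frame; sequences must be at least
#'   `width + 2 * max_shift` nt (extract with `flank >= 6` for the
#'   defaults).
#' @param background Background composition (default uniform).
#' @param max_shift Maximal |shift| in nt (default 1).
#' @param max_iter Iteration cap (default 20).
#' @param width Matrix width (default 11).
#' @return List: `windows` (with updated `shift`), `matrix`
#'   (`motif_matrix` of the aligned windows), `iterations`, `converged`,
#'   `objective` (per-iteration trace).
#' @export
shift_align <- function(windows, background = NULL, max_shift = 1,
                        max_iter = 20, width = 11) {
  if (!nrow(windows)) stop("empty window set")
  if (is.null(background)) background <- rep(0.25, 4)
  background <- stats::setNames(background / sum(background), MOTIF_BASES)
  if (any(nchar(windows$seq) < width + 2 * max_shift))
    stop("extract windows with flank >= ",
         (width - 1) / 2 + max_shift, " for max_shift = ", max_shift)
  shifts <- -max_shift:max_shift
  pc_matrix <- function(w) {
    m <- build_matrix(w, background, width)
    sweep(m$counts + background, 2, colSums(m$counts + background), "/")
  }
  total_obj <- function(w, fpc) {
    sum(score_cores(window_core(w, width, max_shift), fpc, background))
  }
  objective <- total_obj(windows, pc_matrix(windows))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fpc <- pc_matrix(windows)
    # score every candidate shift for every window against the current matrix
    sc <- vapply(shifts, function(s) {
      w <- windows; w$shift <- rep(as.integer(s), nrow(windows))
      score_cores(window_core(w, width, max_shift), fpc, background)
    }, numeric(nrow(windows)))
    sc <- matrix(sc, nrow = nrow(windows))
    # best shift per window; ties toward smaller |shift|, then negative
    best <- vapply(seq_len(nrow(windows)), function(i) {
      row <- sc[i, ]
      cand <- shifts[row >= max(row) - 1e-12]
      cand[order(abs(cand), cand)][1]
    }, numeric(1))
    new <- windows; new$shift <- as.integer(best)
    obj_new <- total_obj(new, pc_matrix(new))
    if (obj_new < utils::tail(objective, 1) - 1e-9) {
      converged <- TRUE   # stop rather than degrade the objective
      break
    }
    changed <- !identical(new$shift, windows$shift)
    windows <- new
    objective <- c(objective, obj_new)
    if (!changed) { converged <- TRUE; break }
  }
  list(windows = windows,
       matrix = build_matrix(windows, background, width),
       iterations = length(objective) - 1L,
       converged = converged,
       objective = objective)
}

#' Per-column AU enrichment
#'
#' The AU fraction per matrix column (f_A + f_U) with a two-sided exact
#' binomial test against the background AU probability — the statistic
#' behind the AU-rich cleavage consensus in a GC-rich genome.
#'
#' @param matrix A `motif_matrix`.
#' @return Data frame: `column`, `au_fraction`, `p_value`.
#' @export
au_enrichment <- function(matrix) {
  q_au <- sum(matrix$background[c("A", "T")])
  n_col <- colSums(matrix$counts)
  au <- matrix$counts["A", ] + matrix$counts["T", ]
  p <- vapply(seq_along(au), function(j) {
    if (n_col[j] == 0) return(NA_real_)
    stats::binom.test(au[j], n_col[j], p = q_au)$p.value
  }, numeric(1))
  data.frame(column = seq_along(au), au_fraction = au / pmax(n_col, 1L),
             p_value = p)
}

#' Export windows as FASTA for external motif tools
#'
#' One record per window; headers `replicon:strand:center` are unique even
#' for coincident centers on opposite strands.
#'
#' @param windows Window data frame.
#' @param path Output path.
#' @export
export_windows_fasta <- function(windows, path) {
  seqs <- Biostrings::DNAStringSet(windows$seq)
  names(seqs) <- sprintf("%s:%s:%d", windows$replicon, windows$strand,
                         windows$center)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Dump a motif matrix as TSV (counts, frequencies, information content)
#' @param matrix A `motif_matrix`.
#' @param path Output path.
#' @export
write_motif_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_windows\t%d", matrix$n), con)
  writeLines(paste0("# background\t",
                    paste(sprintf("%s=%.6f", names(matrix$background),
                                  matrix$background), collapse = "\t")),
             con)
  dump_block <- function(label, m) {
    writeLines(paste0("# ", label), con)
    utils::write.table(m, con, sep = "\t", quote = FALSE,
                       col.names = FALSE)
  }
  dump_block("counts", matrix$counts)
  dump_block("frequencies", round(matrix$frequencies, 6))
  writeLines(paste(c("# IC", round(matrix$ic, 6)), collapse = "\t"), con)
  invisible(path)
}

#' Export a motif matrix in MEME minimal format
#' @param matrix A `motif_matrix`.
#' @param path Output path.
#' @param name Motif name in the file.
#' @export
write_meme_minimal <- function(matrix, path, name = "tierseq_motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               paste("Background letter frequencies"),
               paste(sprintf("%s %.5f", names(matrix$background),
                             matrix$background), collapse = " "),
               "",
               paste("MOTIF", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                 ncol(matrix$frequencies), matrix$n)), con)
  utils::write.table(t(round(matrix$frequencies, 6)), con, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
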