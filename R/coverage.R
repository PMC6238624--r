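#' Genome index
#'
#' Light wrapper around a [Biostrings::DNAStringSet] holding one entry per
#' replicon. All coordinates in the package are 1-based inclusive.
#'
#' @param seqs A `DNAStringSet` or named character vector of nucleotide
#'   sequences over `{A,C,G,T,N}`; names are replicon identifiers.
#' @return An object of class `genome_index` with elements `ids`, `lengths`
#'   (named integer vector) and `seqs` (`DNAStringSet`).
#' @export
genome_index <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (!methods::is(seqs, "DNAStringSet"))
    stop("`seqs` must be a DNAStringSet or named character vector")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all replicon sequences must be named")
  if (anyDuplicated(ids)) stop("replicon ids must be unique")
  lens <- stats::setNames(Biostrings::width(seqs), ids)
  structure(list(ids = ids, lengths = lens, seqs = seqs),
            class = "genome_index")
}

#' Read a genome FASTA into a genome index
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [genome_index].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; the replicon id is the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_index(seqs)
}

#' Write a genome index to FASTA
#' @param genome A [genome_index].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index>", length(x$ids), "replicon(s),",
      sum(x$lengths), "nt total\n")
  invisible(x)
}

track_key <- function(replicon, strand) paste(replicon, strand, sep = "|")

new_coverage_track <- function(library_id, replicon, strand,
                               positions = integer(), counts = integer()) {
  stopifnot(strand %in% c("+", "-"), length(positions) == length(counts))
  o <- order(positions)
  structure(list(library_id = library_id, replicon = replicon,
                 strand = strand,
                 positions = as.integer(positions[o]),
                 counts = as.integer(counts[o])),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s %s(%s): %d positions, %d reads\n",
              x$library_id, x$replicon, x$strand,
              length(x$positions), sum(x$counts)))
  invisible(x)
}

#' Single-nucleotide 5'-end (first-base-in-read) coverage
#'
#' Counts, for every genomic position, the reads whose biological 5' end maps
#' there: the leftmost aligned coordinate for a `+` strand read and the
#' rightmost for a `-` strand read. This per-nucleotide 5'-end signal is the
#' primary observable of the analysis.
#'
#' @param reads A data frame with columns `replicon`, `start`, `end`
#'   (1-based inclusive) and `strand` (`"+"`/`"-"`).
#' @param genome A [genome_index]; reads are validated against its bounds.
#' @param library_id Identifier stored on the resulting tracks.
#' @return A named list of `coverage_track` objects, one per
#'   (replicon, strand) of the genome (empty tracks included), keyed
#'   `"<replicon>|<strand>"`.
#' @export
five_prime_coverage <- function(reads, genome, library_id = "lib") {
  req <- c("replicon", "start", "end", "strand")
  if (!all(req %in% names(reads)))
    stop("`reads` needs columns: ", paste(req, collapse = ", "))
  bad <- !reads$replicon %in% genome$ids
  if (any(bad))
    stop("unknown replicon in reads: ",
         paste(unique(reads$replicon[bad]), collapse = ", "))
  if (!all(reads$strand %in% c("+", "-")))
    stop("read strand must be '+' or '-'")
  lens <- genome$lengths[reads$replicon]
  oob <- reads$start < 1L | reads$end > lens | reads$start > reads$end
  if (any(oob)) {
    i <- which(oob)[1]
    stop(sprintf("read %d outside replicon bounds: %s:%d-%d (%s)",
                 i, reads$replicon[i], reads$start[i], reads$end[i],
                 reads$strand[i]))
  }
  five <- ifelse(reads$strand == "+", reads$start, reads$end)
  out <- list()
  for (rep_id in genome$ids) {
    for (st in c("+", "-")) {
      sel <- reads$replicon == rep_id & reads$strand == st
      tab <- table(five[sel])
      out[[track_key(rep_id, st)]] <- new_coverage_track(
        library_id, rep_id, st,
        positions = as.integer(names(tab)), counts = as.integer(tab))
    }
  }
  out
}

#' Write coverage tracks as a variableStep wiggle file
#'
#' One file holds one (library, strand) track, possibly spanning several
#' replicons (one `variableStep` block each). The strand is encoded in the
#' track name suffix `"_forward"` / `"_reverse"`, the dRNA-seq convention
#' also used for the deposited coverage files this format emulates. Values
#' are written as non-negative integers.
#'
#' @param tracks A single `coverage_track` or list of tracks sharing one
#'   library and strand.
#' @param path Output path.
#' @export
write_wiggle <- function(tracks, path) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  lib <- unique(vapply(tracks, `[[`, "", "library_id"))
  st  <- unique(vapply(tracks, `[[`, "", "strand"))
  if (length(lib) != 1L || length(st) != 1L)
    stop("all tracks in one wiggle file must share library_id and strand")
  suffix <- if (st == "+") "_forward" else "_reverse"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s%s"', lib, suffix), con)
  for (tr in tracks) {
    writeLines(sprintf("variableStep chrom=%s span=1", tr$replicon), con)
    if (length(tr$positions))
      writeLines(paste(tr$positions, tr$counts), con)
  }
  invisible(path)
}

#' Read a variableStep wiggle file into coverage tracks
#'
#' Inverse of [write_wiggle()]: positions are 1-based, the strand is taken
#' from the `_forward`/`_reverse` track-name suffix, and negative values are
#' interpreted as reverse-strand magnitudes (their absolute value is kept) so
#' that sign-encoded reverse tracks from dRNA-seq pipelines load correctly.
#' `fixedStep` input is rejected as an unsupported dialect.
#'
#' @param path Path to a wiggle file.
#' @param library_id Optional override; defaults to the track name with the
#'   strand suffix stripped.
#' @return Named list of `coverage_track`s keyed `"<replicon>|<strand>"`.
#' @export
read_wiggle <- function(path, library_id = NULL) {
  lines <- readLines(path)
  lib <- library_id
  strand <- NULL
  chrom <- NULL
  out <- list()
  pos <- integer(0); val <- integer(0)
  flush <- function() {
    if (!is.null(chrom)) {
      if (is.null(strand)) stop("track line with strand suffix required")
      out[[track_key(chrom, strand)]] <<- new_coverage_track(
        if (is.null(lib)) "lib" else lib, chrom, strand, pos, val)
    }
    pos <<- integer(0); val <<- integer(0)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "fixedStep"))
      stop(sprintf("line %d: fixedStep wiggle is an unsupported dialect", i))
    if (startsWith(ln, "track")) {
      nm <- sub('.*name="?([^" ]+)"?.*', "\\1", ln)
      if (grepl("_forward$", nm)) {
        strand <- "+"
      } else if (grepl("_reverse$", nm)) {
        strand <- "-"
      } else stop(sprintf(
        "line %d: track name '%s' lacks _forward/_reverse strand suffix",
        i, nm))
      if (is.null(library_id)) lib <- sub("_(forward|reverse)$", "", nm)
      next
    }
    if (startsWith(ln, "variableStep")) {
      flush()
      chrom <- sub(".*chrom=([^ ]+).*", "\\1", ln)
      next
    }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) != 2L)
      stop(sprintf("line %d: expected 'position value', got '%s'", i, ln))
    p <- suppressWarnings(as.numeric(f[1]))
    v <- suppressWarnings(as.numeric(f[2]))
    if (is.na(p) || is.na(v) || p != round(p) || v != round(v))
      stop(sprintf("line %d: non-integer position or value: '%s'", i, ln))
    if (is.null(chrom))
      stop(sprintf("line %d: data before any variableStep declaration", i))
    pos <- c(pos, as.integer(p))
    val <- c(val, abs(as.integer(v)))   # sign encodes strand, not count
  }
  flush()
  out
}

#' Combine per-library coverage tracks into a position table
#'
#' The row set is the union of all nonzero 5'-end positions across
#' libraries; counts absent from a library are zero. Rows that are zero in
#' every library are never stored.
#'
#' @param track_sets Named list: `library_id` -> list of `coverage_track`s
#'   (as returned by [five_prime_coverage()] or [read_wiggle()]). Every
#'   library must cover the same (replicon, strand) keys.
#' @param conditions Character vector parallel to `track_sets` naming each
#'   library's condition, `"wild_type"` or `"mutant"`.
#' @return A `position_table`: list with `key` (data frame `replicon`,
#'   `strand`, `position`), `counts` (integer matrix, one column per
#'   library) and `libraries` (data frame `library_id`, `condition`).
#' @export
build_position_table <- function(track_sets, conditions) {
  libs <- names(track_sets)
  if (is.null(libs) || anyDuplicated(libs))
    stop("track_sets must be a named list with unique library ids")
  if (length(conditions) != length(libs))
    stop("one condition per library required")
  keys <- lapply(track_sets, names)
  ref <- sort(keys[[1]])
  for (k in keys) if (!identical(sort(k), ref))
    stop("mismatched (replicon, strand) sets across libraries")

  key_rows <- list(); count_cols <- list()
  for (tk in ref) {
    pos_union <- sort(unique(unlist(
      lapply(track_sets, function(ts) ts[[tk]]$positions))))
    if (!length(pos_union)) next
    tr1 <- track_sets[[1]][[tk]]
    key_rows[[tk]] <- data.frame(replicon = tr1$replicon,
                                 strand = tr1$strand,
                                 position = pos_union,
                                 stringsAsFactors = FALSE)
    count_cols[[tk]] <- vapply(track_sets, function(ts) {
      tr <- ts[[tk]]
      cnt <- integer(length(pos_union))
      cnt[match(tr$positions, pos_union)] <- tr$counts
      cnt
    }, integer(length(pos_union)))
  }
  if (!length(key_rows)) {
    key <- data.frame(replicon = character(), strand = character(),
                      position = integer(), stringsAsFactors = FALSE)
    counts <- matrix(0L, 0, length(libs), dimnames = list(NULL, libs))
  } else {
    key <- do.call(rbind, key_rows)
    rownames(key) <- NULL
    counts <- do.call(rbind, lapply(count_cols, function(m)
      matrix(m, ncol = length(libs), dimnames = list(NULL, libs))))
  }
  position_table(key, counts, data.frame(library_id = libs,
                                         condition = conditions,
                                         stringsAsFactors = FALSE))
}

#' Construct a position table directly
#'
#' @param key Data frame with `replicon`, `strand`, `position`.
#' @param counts Integer matrix, rows matching `key`, one named column per
#'   library.
#' @param libraries Data frame with `library_id` and `condition`.
#' @export
position_table <- function(key, counts, libraries) {
  stopifnot(nrow(key) == nrow(counts),
            ncol(counts) == nrow(libraries))
  if (anyDuplicated(libraries$library_id)) stop("duplicate library_id")
  if (!all(libraries$condition %in% c("wild_type", "mutant")))
    stop("conditions must be 'wild_type' or 'mutant'")
  rk <- paste(key$replicon, key$strand, key$position)
  if (anyDuplicated(rk)) stop("duplicate (replicon, strand, position) rows")
  colnames(counts) <- libraries$library_id
  structure(list(key = key, counts = counts, libraries = libraries),
            class = "position_table")
}

#' @export
print.position_table <- function(x, ...) {
  cat(sprintf("<position_table> %d positions x %d libraries (%s)\n",
              nrow(x$key), nrow(x$libraries),
              paste(table(x$libraries$condition), collapse = " vs ")))
  invisible(x)
}

#' @export
dim.position_table <- function(x) dim(x$counts)

#' Write / read a position table as TSV
#'
#' Key columns followed by one count column per library; condition labels
#' are stored in a `# condition:` header comment so the file round-trips.
#' @param table A `position_table`.
#' @param path File path.
#' @export
write_position_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition: ",
                    paste(table$libraries$condition, collapse = "\t")), con)
  df <- cbind(table$key, as.data.frame(table$counts))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_position_table
#' @export
read_position_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# condition:"))
    stop("missing '# condition:' header in ", path)
  cond <- strsplit(sub("^# condition: ?", "", hdr), "\t")[[1]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE, check.names = FALSE)
  key <- df[, c("replicon", "strand", "position")]
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(counts) <- "integer"
  position_table(key, counts,
                 data.frame(library_id = colnames(counts), condition = cond,
                            stringsAsFactors = FALSE))
}
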