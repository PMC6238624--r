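#' Configuration of a synthetic TIER-seq experiment
#'
#' The defaults restate the experimental design the pipeline targets: a
#' GC-rich genome (68.8% GC), three replicates per strain, sparse
#' per-nucleotide 5'-end counts with negative-binomial noise, implanted
#' wild-type-enriched cleavage sites with an AU-rich cut context, and
#' mutant-enriched stabilized 5' ends.
#'
#' @param seed Integer seed; every generator stage derives its RNG state
#'   from it, so identical configs give byte-identical outputs.
#' @param genome_length Replicon length in nt (default 200,000).
#' @param gc_content Fraction G+C, split equally between G and C
#'   (default 0.688).
#' @param n_genes Number of protein-coding genes (default 80).
#' @param utr5_fraction,utr3_fraction Fraction of genes carrying an
#'   annotated 5' / 3' UTR (defaults 0.7 / 0.5).
#' @param n_srna,n_rrna Counts of standalone sRNA and rRNA features.
#' @param n_cleavage_sites,n_enriched_sites Implanted site counts
#'   (defaults 200 / 200).
#' @param cleavage_log2fc,enriched_log2fc True log2 effect sizes
#'   (defaults 2.5).
#' @param site_mean_wt Mean normalized 5'-end coverage on the enriched
#'   side of a site (default 80).
#' @param dispersion NB dispersion alpha (default 0.1).
#' @param n_replicates Replicates per condition (default 3, minimum 2).
#' @param size_factors True per-library scale factors, recycled to
#'   2 * n_replicates libraries.
#' @param background_rate Per-nt, per-strand rate of non-differential
#'   background 5' ends (default 0.01).
#' @param noise_rate Per-nt, per-strand rate of low-count (0-2) noise
#'   positions, mostly removed by the coverage filter (default 0.02).
#' @param motif_prob Probability that a cleavage site gets A/U written at
#'   window offsets 0/+1 (default 0.8).
#' @param replicon_id Replicon name (default "chr1").
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       gc_content = 0.688,
                       n_genes = 80L,
                       utr5_fraction = 0.7,
                       utr3_fraction = 0.5,
                       n_srna = 6L,
                       n_rrna = 2L,
                       n_cleavage_sites = 200L,
                       n_enriched_sites = 200L,
                       cleavage_log2fc = 2.5,
                       enriched_log2fc = 2.5,
                       site_mean_wt = 80,
                       dispersion = 0.1,
                       n_replicates = 3L,
                       size_factors = c(1.0, 1.2, 0.8, 1.1, 0.9, 1.05),
                       background_rate = 0.01,
                       noise_rate = 0.02,
                       motif_prob = 0.8,
                       replicon_id = "chr1") {
  cfg <- as.list(environment())
  stopifnot(gc_content > 0, gc_content < 1,
            cleavage_log2fc >= 0, enriched_log2fc >= 0,
            n_replicates >= 2, dispersion >= 0,
            motif_prob >= 0, motif_prob <= 1,
            all(size_factors > 0))
  structure(cfg, class = "sim_config")
}

#' Simulate a GC-rich genome
#'
#' I.i.d. bases with P(G) = P(C) = gc_content / 2; deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_index] with a single replicon.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  bases <- sample(names(p), config$genome_length, replace = TRUE, prob = p)
  seqs <- stats::setNames(paste(bases, collapse = ""), config$replicon_id)
  genome_index(seqs)
}

#' Simulate a non-overlapping gene annotation
#'
#' Genes (optional 5' UTR + CDS + optional 3' UTR, start codon at the CDS
#' 5' boundary) plus standalone sRNA and rRNA features are laid out in
#' disjoint bins on alternating random strands.
#'
#' @param config A [sim_config()].
#' @param genome The matching [genome_index].
#' @return A `feature_set` data frame (see [parse_gff()]).
#' @export
simulate_annotation <- function(config, genome) {
  set.seed(config$seed + 1L)
  n_slots <- config$n_genes + config$n_srna + config$n_rrna
  L <- config$genome_length
  bin <- L %/% n_slots
  kinds <- sample(c(rep("gene", config$n_genes),
                    rep("sRNA", config$n_srna),
                    rep("rRNA", config$n_rrna)))
  rows <- list()
  for (i in seq_len(n_slots)) {
    lo <- (i - 1L) * bin + 1L
    strand <- sample(c("+", "-"), 1)
    if (kinds[i] == "gene") {
      gid <- sprintf("g%03d", sum(kinds[seq_len(i)] == "gene"))
      cds_len <- 3L * sample(100:400, 1)
      u5 <- if (stats::runif(1) < config$utr5_fraction)
        sample(20:100, 1) else 0L
      u3 <- if (stats::runif(1) < config$utr3_fraction)
        sample(20:80, 1) else 0L
      total <- cds_len + u5 + u3
      if (bin < total + 20L)
        stop("genome too short for the requested gene layout")
      start <- lo + sample.int(bin - total - 10L, 1)
      # transcript 5'->3' order: UTR5, CDS, UTR3 (reversed on '-')
      seg_len <- c(u5, cds_len, u3)
      seg_type <- c("five_prime_UTR", "CDS", "three_prime_UTR")
      if (strand == "-") { seg_len <- rev(seg_len); seg_type <- rev(seg_type) }
      at <- start
      for (k in 1:3) {
        if (seg_len[k] == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = config$replicon_id, type = seg_type[k],
          start = at, end = at + seg_len[k] - 1L, strand = strand,
          gene_id = paste0(gid, "_", c(five_prime_UTR = "5utr",
                                       CDS = "cds",
                                       three_prime_UTR = "3utr")[seg_type[k]]),
          stringsAsFactors = FALSE)
        at <- at + seg_len[k]
      }
    } else {
      len <- if (kinds[i] == "rRNA") 1500L else sample(80:200, 1)
      if (bin < len + 20L)
        stop("genome too short for the requested feature layout")
      start <- lo + sample.int(bin - len - 10L, 1)
      n_prev <- sum(kinds[seq_len(i)] == kinds[i])
      rows[[length(rows) + 1L]] <- data.frame(
        replicon = config$replicon_id, type = kinds[i],
        start = start, end = start + len - 1L, strand = strand,
        gene_id = sprintf("%s%02d", tolower(kinds[i]), n_prev),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}

# genomic positions of transcript-orientation offsets 0 and +1 from a site
motif_positions <- function(position, strand) {
  if (strand == "+") c(position, position + 1L) else c(position, position - 1L)
}

#' Implant ground-truth sites and their sequence context
#'
#' Cleavage sites are placed uniformly within transcribed features (CDS,
#' UTRs, sRNA) weighted by length; enriched (mutant-stabilized) sites are
#' placed preferentially at feature 5' ends, emulating primary 5' ends
#' escaping 5'-end-dependent decay. All implanted sites are at least 10 nt
#' apart. With probability `motif_prob` the genome bases at transcript
#' offsets 0/+1 of a cleavage site are rewritten as random A/T, planting
#' the AU-rich cut context in the GC-rich background.
#'
#' @param config A [sim_config()].
#' @param features Output of [simulate_annotation()].
#' @param genome The matching [genome_index].
#' @return List: `truth` (data frame `replicon`, `strand`, `position`,
#'   `class`, `log2_effect`, `wt_mean`, `mut_mean`) and `genome` (edited
#'   [genome_index]).
#' @export
implant_sites <- function(config, features, genome) {
  set.seed(config$seed + 2L)
  L <- config$genome_length
  margin <- 10L   # keep motif windows clear of replicon edges
  place <- function(n, class) {
    host_types <- if (class == "cleavage")
      c("CDS", "five_prime_UTR", "three_prime_UTR", "sRNA")
    else FEATURE_TYPES
    hosts <- features[features$type %in% host_types, , drop = FALSE]
    if (!nrow(hosts)) stop("feature space too small: no host features")
    w <- hosts$end - hosts$start + 1
    taken <- integer(0)
    out <- list()
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * n)
        stop("feature space too small for ", n, " ", class, " sites")
      f <- hosts[sample.int(nrow(hosts), 1, prob = w), ]
      if (class == "enriched" && stats::runif(1) < 0.5) {
        five_end <- if (f$strand == "+") f$start else f$end
        jit <- sample(0:5, 1)
        pos <- if (f$strand == "+") five_end + jit else five_end - jit
      } else {
        pos <- f$start + sample.int(f$end - f$start + 1L, 1) - 1L
      }
      if (pos <= margin || pos > L - margin) next
      if (length(taken) && min(abs(taken - pos)) < 10L) next
      taken <- c(taken, pos)
      out[[length(out) + 1L]] <- data.frame(
        replicon = config$replicon_id, strand = f$strand,
        position = as.integer(pos), class = class,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  truth_cl <- if (config$n_cleavage_sites > 0)
    place(config$n_cleavage_sites, "cleavage") else NULL
  # enforce the min-distance constraint across classes too
  if (!is.null(truth_cl)) {
    taken0 <- truth_cl$position
  } else taken0 <- integer(0)
  place_enriched <- function(n) {
    hosts <- features
    w <- hosts$end - hosts$start + 1
    taken <- taken0; out <- list(); tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * n)
        stop("feature space too small for ", n, " enriched sites")
      f <- hosts[sample.int(nrow(hosts), 1, prob = w), ]
      if (stats::runif(1) < 0.5) {
        five_end <- if (f$strand == "+") f$start else f$end
        jit <- sample(0:5, 1)
        pos <- if (f$strand == "+") five_end + jit else five_end - jit
      } else {
        pos <- f$start + sample.int(f$end - f$start + 1L, 1) - 1L
      }
      if (pos <= margin || pos > L - margin) next
      if (length(taken) && min(abs(taken - pos)) < 10L) next
      taken <- c(taken, pos)
      out[[length(out) + 1L]] <- data.frame(
        replicon = config$replicon_id, strand = f$strand,
        position = as.integer(pos), class = "enriched",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  truth_en <- if (config$n_enriched_sites > 0)
    place_enriched(config$n_enriched_sites) else NULL
  truth <- rbind(truth_cl, truth_en)
  if (is.null(truth))
    truth <- data.frame(replicon = character(), strand = character(),
                        position = integer(), class = character(),
                        stringsAsFactors = FALSE)
  truth$log2_effect <- ifelse(truth$class == "cleavage",
                              config$cleavage_log2fc,
                              config$enriched_log2fc)
  truth$wt_mean <- ifelse(truth$class == "cleavage", config$site_mean_wt,
                          config$site_mean_wt * 2^(-truth$log2_effect))
  truth$mut_mean <- ifelse(truth$class == "cleavage",
                           config$site_mean_wt * 2^(-truth$log2_effect),
                           config$site_mean_wt)

  # plant the AU cut context of cleavage sites into the genome sequence
  seq <- genome$seqs[[config$replicon_id]]
  cl <- truth[truth$class == "cleavage", , drop = FALSE]
  if (nrow(cl)) {
    edit <- stats::runif(nrow(cl)) < config$motif_prob
    if (any(edit)) {
      pos_edit <- unlist(mapply(motif_positions, cl$position[edit],
                                cl$strand[edit], SIMPLIFY = FALSE))
      new_bases <- sample(c("A", "T"), length(pos_edit), replace = TRUE)
      seq <- Biostrings::replaceLetterAt(
        seq, pos_edit, paste(new_bases, collapse = ""))
    }
  }
  seqs <- Biostrings::DNAStringSet(stats::setNames(list(seq),
                                                   config$replicon_id))
  list(truth = truth, genome = genome_index(seqs))
}

rnbinom_mu <- function(n, mu, alpha) {
  if (alpha < 1e-12) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate per-library 5'-end counts
#'
#' Cleavage sites draw wild-type counts from NB(mu s_j, alpha) and mutant
#' counts from NB(mu 2^-effect s_j, alpha); enriched sites reverse the
#' roles. Background positions are a sparse spatial scatter of
#' non-differential NB signal plus low-count (0-2) noise positions that
#' mostly fall to the coverage filter.
#'
#' @param truth Truth table from [implant_sites()].
#' @param config A [sim_config()].
#' @return A `position_table` (all-zero rows dropped); the true size
#'   factors are attached as attribute `"true_size_factors"`.
#' @export
simulate_counts <- function(truth, config) {
  set.seed(config$seed + 3L)
  n_lib <- 2L * config$n_replicates
  sf <- rep_len(config$size_factors, n_lib)
  libs <- data.frame(
    library_id = c(sprintf("wt_%d", seq_len(config$n_replicates)),
                   sprintf("mut_%d", seq_len(config$n_replicates))),
    condition = rep(c("wild_type", "mutant"), each = config$n_replicates),
    stringsAsFactors = FALSE)
  L <- config$genome_length
  wt_cols <- seq_len(config$n_replicates)
  mut_cols <- config$n_replicates + wt_cols

  key_site <- truth[, c("replicon", "strand", "position")]
  occupied <- split(truth$position, truth$strand)

  scatter <- function(rate, exclude) {
    lapply(c("+", "-"), function(st) {
      n <- stats::rbinom(1, L, rate)
      pos <- sort(sample.int(L, n))
      setdiff(pos, exclude[[st]])
    })
  }
  bg_pos <- scatter(config$background_rate, occupied)
  noise_excl <- list("+" = c(occupied[["+"]], bg_pos[[1]]),
                     "-" = c(occupied[["-"]], bg_pos[[2]]))
  noise_pos <- scatter(config$noise_rate, noise_excl)

  key_bg <- data.frame(
    replicon = config$replicon_id,
    strand = rep(c("+", "-"), times = lengths(bg_pos)),
    position = unlist(bg_pos), stringsAsFactors = FALSE)
  key_noise <- data.frame(
    replicon = config$replicon_id,
    strand = rep(c("+", "-"), times = lengths(noise_pos)),
    position = unlist(noise_pos), stringsAsFactors = FALSE)

  counts_site <- matrix(0L, nrow(truth), n_lib)
  for (i in seq_len(nrow(truth))) {
    counts_site[i, wt_cols] <- rnbinom_mu(
      config$n_replicates, truth$wt_mean[i] * sf[wt_cols],
      config$dispersion)
    counts_site[i, mut_cols] <- rnbinom_mu(
      config$n_replicates, truth$mut_mean[i] * sf[mut_cols],
      config$dispersion)
  }
  n_bg <- nrow(key_bg)
  bg_mean <- pmax(stats::rlnorm(n_bg, log(20), 1), 1)
  counts_bg <- matrix(0L, n_bg, n_lib)
  for (j in seq_len(n_lib))
    counts_bg[, j] <- rnbinom_mu(n_bg, bg_mean * sf[j], config$dispersion)
  counts_noise <- matrix(sample(0:2, nrow(key_noise) * n_lib,
                                replace = TRUE),
                         nrow(key_noise), n_lib)

  key <- rbind(key_site, key_bg, key_noise)
  counts <- rbind(counts_site, counts_bg, counts_noise)
  keep <- rowSums(counts) > 0
  key <- key[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  o <- order(key$replicon, key$strand, key$position)
  key <- key[o, , drop = FALSE]
  rownames(key) <- NULL
  tab <- position_table(key, counts[o, , drop = FALSE], libs)
  attr(tab, "true_size_factors") <- stats::setNames(sf, libs$library_id)
  tab
}

#' Fully null synthetic experiment
#'
#' A position table with no differential signal at all: every position has
#' the same NB mean in both conditions. Used for FDR calibration; means
#' are drawn log-normally and floored so the default coverage filter keeps
#' essentially all positions.
#'
#' @param n_positions Number of positions (default 10,000).
#' @param mean_meanlog,mean_sdlog Log-normal parameters of per-position
#'   means (defaults log(50), 0.8).
#' @param min_mean Floor on the mean so positions survive `min_cov = 10`.
#' @param dispersion NB alpha (default 0.1).
#' @param n_replicates Per condition (default 3).
#' @param size_factors True library scale factors.
#' @param seed RNG seed.
#' @return A `position_table`.
#' @export
simulate_null_experiment <- function(n_positions = 10000,
                                     mean_meanlog = log(50),
                                     mean_sdlog = 0.8,
                                     min_mean = 15,
                                     dispersion = 0.1,
                                     n_replicates = 3,
                                     size_factors = c(1.0, 1.2, 0.8,
                                                      1.1, 0.9, 1.05),
                                     seed = 1L) {
  set.seed(seed)
  n_lib <- 2L * n_replicates
  sf <- rep_len(size_factors, n_lib)
  mu <- pmax(stats::rlnorm(n_positions, mean_meanlog, mean_sdlog), min_mean)
  counts <- vapply(seq_len(n_lib), function(j)
    rnbinom_mu(n_positions, mu * sf[j], dispersion), numeric(n_positions))
  storage.mode(counts) <- "integer"
  libs <- data.frame(
    library_id = c(sprintf("wt_%d", seq_len(n_replicates)),
                   sprintf("mut_%d", seq_len(n_replicates))),
    condition = rep(c("wild_type", "mutant"), each = n_replicates),
    stringsAsFactors = FALSE)
  key <- data.frame(replicon = "chr1", strand = "+",
                    position = seq_len(n_positions) * 10L,
                    stringsAsFactors = FALSE)
  position_table(key, counts, libs)
}

#' Split a position table into per-library coverage tracks
#'
#' @param table A `position_table`.
#' @param genome Optional [genome_index]; when given, empty tracks are
#'   emitted for uncovered (replicon, strand) pairs so the tracks
#'   round-trip through [build_position_table()].
#' @return Named list: `library_id` -> named list of `coverage_track`s.
#' @export
table_to_tracks <- function(table, genome = NULL) {
  reps <- if (is.null(genome)) unique(table$key$replicon) else genome$ids
  lapply(stats::setNames(seq_len(nrow(table$libraries)),
                         table$libraries$library_id), function(j) {
    lib <- table$libraries$library_id[j]
    out <- list()
    for (rep_id in reps) {
      for (st in c("+", "-")) {
        sel <- table$key$replicon == rep_id & table$key$strand == st &
          table$counts[, j] > 0
        out[[track_key(rep_id, st)]] <- new_coverage_track(
          lib, rep_id, st, table$key$position[sel], table$counts[sel, j])
      }
    }
    out
  })
}

#' Score called sites against the implanted truth
#'
#' A truth site is recovered when a same-class cluster center lies within
#' `tolerance` nt on the same replicon and strand; matching is one-to-one
#' greedy by distance. With zero called clusters the precision is reported
#' as 1.0 and flagged (`zero_called`).
#'
#' @param clusters Cluster data frame from [cluster_candidates()] /
#'   [call_sites()].
#' @param truth Truth table from [implant_sites()].
#' @param tolerance Center tolerance in nt (default 2).
#' @return List: `summary` (per class: `n_truth`, `n_called`, `n_matched`,
#'   `precision`, `recall`, `zero_called`) and `offsets` (data frame of
#'   matched center - truth offsets per class).
#' @export
evaluate_recovery <- function(clusters, truth, tolerance = 2) {
  classes <- sort(unique(c(clusters$class, truth$class)))
  summ <- list(); offs <- list()
  for (cl in classes) {
    tr <- truth[truth$class == cl, , drop = FALSE]
    ca <- clusters[clusters$class == cl, , drop = FALSE]
    matched_t <- rep(FALSE, nrow(tr))
    matched_c <- rep(FALSE, nrow(ca))
    pair_off <- integer(0)
    if (nrow(tr) && nrow(ca)) {
      pairs <- list()
      for (i in seq_len(nrow(ca))) {
        d <- ifelse(tr$replicon == ca$replicon[i] &
                      tr$strand == ca$strand[i],
                    abs(tr$position - ca$center[i]), Inf)
        hit <- which(d <= tolerance)
        if (length(hit))
          pairs[[length(pairs) + 1L]] <- data.frame(
            c = i, t = hit, d = d[hit])
      }
      if (length(pairs)) {
        pairs <- do.call(rbind, pairs)
        pairs <- pairs[order(pairs$d, pairs$c, pairs$t), , drop = FALSE]
        for (k in seq_len(nrow(pairs))) {
          i <- pairs$c[k]; t <- pairs$t[k]
          if (!matched_c[i] && !matched_t[t]) {
            matched_c[i] <- TRUE; matched_t[t] <- TRUE
            pair_off <- c(pair_off,
                          ca$center[i] - tr$position[t])
          }
        }
      }
    }
    zero <- nrow(ca) == 0L
    summ[[cl]] <- data.frame(
      class = cl, n_truth = nrow(tr), n_called = nrow(ca),
      n_matched = sum(matched_t),
      precision = if (zero) 1.0 else sum(matched_c) / nrow(ca),
      recall = if (nrow(tr)) sum(matched_t) / nrow(tr) else NA_real_,
      zero_called = zero, stringsAsFactors = FALSE)
    if (length(pair_off))
      offs[[cl]] <- data.frame(class = cl, offset = pair_off,
                               stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       offsets = if (length(offs)) do.call(rbind, c(offs,
         list(make.row.names = FALSE)))
       else data.frame(class = character(), offset = integer()))
}

#' Generate a complete synthetic experiment, optionally on disk
#'
#' Runs [simulate_genome()], [simulate_annotation()], [implant_sites()]
#' and [simulate_counts()]; when `dir` is given, writes the genome FASTA,
#' GFF3 annotation, per-library wiggle pairs, a truth TSV/BED and a JSON
#' run manifest consumable by [run_all()].
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return List: `config`, `genome`, `features`, `truth`, `table`, and
#'   (when written) `manifest` path.
#' @export
simulate_experiment <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  features <- simulate_annotation(config, genome)
  imp <- implant_sites(config, features, genome)
  tab <- simulate_counts(imp$truth, config)
  out <- list(config = config, genome = imp$genome, features = features,
              truth = imp$truth, table = tab)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    gff <- file.path(dir, "annotation.gff3")
    write_genome_fasta(imp$genome, fa)
    write_gff3(features, gff)
    tracks <- table_to_tracks(tab, imp$genome)
    lib_entries <- list()
    for (lib in names(tracks)) {
      fwd <- file.path(dir, paste0(lib, "_forward.wig"))
      rev <- file.path(dir, paste0(lib, "_reverse.wig"))
      ks <- names(tracks[[lib]])
      write_wiggle(tracks[[lib]][grepl("\\|\\+$", ks)], fwd)
      write_wiggle(tracks[[lib]][grepl("\\|-$", ks)], rev)
      cond <- tab$libraries$condition[tab$libraries$library_id == lib]
      lib_entries[[length(lib_entries) + 1L]] <- list(
        id = lib, condition = cond,
        wiggle_forward = basename(fwd), wiggle_reverse = basename(rev))
    }
    utils::write.table(imp$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_bed <- data.frame(chrom = imp$truth$replicon,
                            start = imp$truth$position - 1L,
                            end = imp$truth$position,
                            name = imp$truth$class, score = 0L,
                            strand = imp$truth$strand)
    utils::write.table(truth_bed, file.path(dir, "truth.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    manifest <- list(
      libraries = lib_entries,
      genome_fasta = "genome.fa", gff = "annotation.gff3",
      thresholds = list(min_cov = 10, fc_min = 2, alpha = 0.05,
                        proximity = 3, flank = 5),
      output_dir = "results", seed = config$seed)
    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
    out$manifest <- mpath
  }
  out
}
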