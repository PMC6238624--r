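# shared small experiment for several blocks (seconds at this scale)
cfg_small <- sim_config(seed = 3, genome_length = 60000L, n_genes = 30L,
                        n_srna = 3L, n_rrna = 1L,
                        n_cleavage_sites = 60L, n_enriched_sites = 60L)
sim_small <- simulate_experiment(cfg_small)

test_that("simulate_genome matches the configured GC content", {
  cfg <- sim_config(seed = 2, genome_length = 100000L)
  g <- simulate_genome(cfg)
  gc <- sum(genome_background(g)[c("C", "G")])
  expect_lt(abs(gc - 0.688), 0.01)
  # degenerate composition
  g2 <- simulate_genome(sim_config(seed = 2, gc_content = 0.999999,
                                   genome_length = 2000L))
  expect_true(all(strsplit(as.character(g2$seqs[[1]]), "")[[1]]
                  %in% c("G", "C")))
  # determinism
  expect_identical(as.character(simulate_genome(cfg)$seqs),
                   as.character(simulate_genome(cfg)$seqs))
})

test_that("simulate_annotation lays out non-overlapping typed features", {
  feats <- sim_small$features
  expect_equal(sum(feats$type == "CDS"), cfg_small$n_genes)
  expect_equal(sum(feats$type == "sRNA"), cfg_small$n_srna)
  expect_true(all(c("+", "-") %in% feats$strand))
  # no overlaps anywhere
  o <- order(feats$start)
  expect_true(all(diff(feats$start[o]) > 0))
  expect_true(all(utils::head(feats$end[o], -1) <
                    utils::tail(feats$start[o], -1)))
  # UTR knobs
  f0 <- simulate_annotation(sim_config(seed = 4, utr5_fraction = 0,
                                       utr3_fraction = 0),
                            simulate_genome(sim_config(seed = 4)))
  expect_false(any(grepl("UTR", f0$type)))
  expect_error(simulate_annotation(
    sim_config(seed = 4, genome_length = 5000L, n_genes = 40L),
    simulate_genome(sim_config(seed = 4, genome_length = 5000L))),
    "too short")
})

test_that("implant_sites writes truth with spacing and AU context", {
  truth <- sim_small$truth
  expect_equal(sum(truth$class == "cleavage"), 60L)
  expect_equal(sum(truth$class == "enriched"), 60L)
  expect_true(all(diff(sort(truth$position)) >= 10))
  # sites lie inside annotated features
  feats <- sim_small$features
  inside <- vapply(seq_len(nrow(truth)), function(i)
    any(feats$start <= truth$position[i] & feats$end >= truth$position[i] &
          feats$strand == truth$strand[i]), logical(1))
  expect_gt(mean(inside), 0.95)   # enriched 5'-end jitter can exit by <=5 nt
  # motif_prob 1: genome bases at transcript offsets 0/+1 are all A/T
  cfg <- sim_config(seed = 9, genome_length = 50000L, n_genes = 25L,
                    n_srna = 2L, n_rrna = 1L,
                    n_cleavage_sites = 40L, n_enriched_sites = 0L,
                    motif_prob = 1)
  g <- simulate_genome(cfg)
  imp <- implant_sites(cfg, simulate_annotation(cfg, g), g)
  seqchr <- strsplit(as.character(imp$genome$seqs[[1]]), "")[[1]]
  cl <- imp$truth
  pos2 <- ifelse(cl$strand == "+", cl$position + 1L, cl$position - 1L)
  expect_true(all(seqchr[cl$position] %in% c("A", "T")))
  expect_true(all(seqchr[pos2] %in% c("A", "T")))
})

test_that("simulate_counts reproduces effects, size factors and noise law", {
  truth <- sim_small$truth
  tab <- sim_small$table
  idx <- match(paste(truth$strand, truth$position),
               paste(tab$key$strand, tab$key$position))
  expect_false(anyNA(idx))
  cl <- truth$class == "cleavage"
  wt_cols <- tab$libraries$condition == "wild_type"
  sf <- attr(tab, "true_size_factors")
  norm <- sweep(tab$counts, 2, sf, "/")
  ratio <- mean(rowMeans(norm[idx[cl], !wt_cols])) /
    mean(rowMeans(norm[idx[cl], wt_cols]))
  expect_lt(abs(ratio / 2^-2.5 - 1), 0.2)
  # library with sf 2 doubles its expected totals vs sf 1
  cfg2 <- sim_config(seed = 12, genome_length = 50000L, n_genes = 25L,
                     n_srna = 2L, n_rrna = 1L,
                     n_cleavage_sites = 100L, n_enriched_sites = 0L,
                     size_factors = c(1, 2, 1, 1, 1, 1))
  sim2 <- simulate_experiment(cfg2)
  tot <- colSums(sim2$table$counts)
  expect_lt(abs(tot[2] / tot[1] - 2), 0.2)
  # alpha -> 0: replicate variance tracks the mean (Poisson limit)
  cfg3 <- sim_config(seed = 13, genome_length = 30000L, n_genes = 15L,
                     n_srna = 2L, n_rrna = 0L,
                     n_cleavage_sites = 100L, n_enriched_sites = 0L,
                     dispersion = 0, size_factors = rep(1, 6))
  sim3 <- simulate_experiment(cfg3)
  i3 <- match(paste(sim3$truth$strand, sim3$truth$position),
              paste(sim3$table$key$strand, sim3$table$key$position))
  wt3 <- sim3$table$counts[i3, 1:3]
  expect_lt(abs(mean(apply(wt3, 1, var)) / mean(wt3) - 1), 0.25)
})

test_that("generated files are byte-deterministic under the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, genome_length = 30000L, n_genes = 15L,
                    n_srna = 2L, n_rrna = 0L,
                    n_cleavage_sites = 30L, n_enriched_sites = 30L)
  simulate_experiment(cfg, dir = d1)
  simulate_experiment(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("generated files feed the coverage and annotation modules", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 6, genome_length = 30000L, n_genes = 15L,
                    n_srna = 2L, n_rrna = 0L,
                    n_cleavage_sites = 30L, n_enriched_sites = 30L)
  sim <- simulate_experiment(cfg, dir = d)
  m <- read_manifest(file.path(d, "manifest.json"))
  track_sets <- lapply(m$libraries, function(l)
    c(read_wiggle(file.path(d, l$wiggle_forward), l$id),
      read_wiggle(file.path(d, l$wiggle_reverse), l$id)))
  names(track_sets) <- vapply(m$libraries, `[[`, "", "id")
  tab <- build_position_table(
    track_sets, vapply(m$libraries, `[[`, "", "condition"))
  expect_equal(tab$counts, sim$table$counts)
  expect_equal(tab$key, sim$table$key)
  feats <- parse_gff(file.path(d, "annotation.gff3"))
  expect_equal(nrow(feats), nrow(sim$features))
  g <- read_genome_fasta(file.path(d, "genome.fa"))
  expect_identical(as.character(g$seqs), as.character(sim$genome$seqs))
})

test_that("evaluate_recovery scores matches, misses and shifts", {
  truth <- data.frame(replicon = "chr1", strand = "+",
                      position = c(100L, 200L, 300L), class = "cleavage")
  perfect <- data.frame(replicon = "chr1", strand = "+",
                        center = c(100L, 200L, 300L), class = "cleavage")
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$summary$precision, 1.0)
  expect_equal(ev$summary$recall, 1.0)
  # no calls: recall 0, precision reported 1.0 with the flag set
  ev0 <- evaluate_recovery(perfect[0, ], truth)
  expect_equal(ev0$summary$recall, 0)
  expect_equal(ev0$summary$precision, 1.0)
  expect_true(ev0$summary$zero_called)
  # +3 nt shift at tolerance 2 recovers nothing
  shifted <- transform(perfect, center = center + 3L)
  expect_equal(evaluate_recovery(shifted, truth)$summary$recall, 0)
  # one-to-one: two clusters near one truth site count once
  dup <- data.frame(replicon = "chr1", strand = "+",
                    center = c(100L, 101L), class = "cleavage")
  evd <- evaluate_recovery(dup, truth)
  expect_equal(evd$summary$n_matched, 1L)
  expect_equal(evd$summary$precision, 0.5)
})

test_that("null configuration keeps the pipeline's empirical FDR in check", {
  cfg <- sim_config(seed = 8, genome_length = 60000L, n_genes = 30L,
                    n_cleavage_sites = 0L, n_enriched_sites = 0L)
  sim <- simulate_experiment(cfg)
  res <- run_difftest(filter_low_coverage(sim$table))
  frac <- mean(res$padj < 0.05)
  n <- nrow(res)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
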