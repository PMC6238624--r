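DEFAULT_THRESHOLDS <- list(min_cov = 10, fc_min = 2, alpha = 0.05,
                           proximity = 3, flank = 5)

#' Read and validate a run manifest
#'
#' Manifests are JSON (a YAML subset): a `libraries` array with `id`,
#' `condition` (`wild_type`/`mutant`) and per-strand wiggle paths, plus
#' `genome_fasta`, `gff`, a `thresholds` block and an `output_dir`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A validated `run_manifest` list.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$.dir <- dirname(normalizePath(path))
  validate_manifest(m)
}

resolve_path <- function(p, dir) {
  if (is.null(p)) return(NULL)
  if (startsWith(p, "/")) p else file.path(dir, p)
}

#' @rdname read_manifest
#' @param manifest A manifest list (as from [jsonlite::read_json()]).
#' @export
validate_manifest <- function(manifest) {
  fail <- function(...) stop("manifest validation: ", ..., call. = FALSE)
  libs <- manifest$libraries
  if (is.null(libs) || length(libs) < 4L)
    fail("need >= 4 libraries (>= 2 per condition)")
  cond <- vapply(libs, function(l) l$condition %||% "", "")
  if (!all(cond %in% c("wild_type", "mutant")))
    fail("library condition must be 'wild_type' or 'mutant'")
  if (any(table(factor(cond, c("wild_type", "mutant"))) < 2L))
    fail("need >= 2 libraries per condition")
  ids <- vapply(libs, function(l) l$id %||% "", "")
  if (anyDuplicated(ids)) fail("duplicate library id")
  dir <- manifest$.dir %||% "."
  for (l in libs) {
    for (f in c("wiggle_forward", "wiggle_reverse")) {
      p <- resolve_path(l[[f]], dir)
      if (is.null(p) || !file.exists(p))
        fail("missing ", f, " for library ", l$id)
    }
  }
  gp <- resolve_path(manifest$genome_fasta, dir)
  if (is.null(gp) || !file.exists(gp)) fail("genome_fasta not found")
  if (!is.null(manifest$gff) &&
      !file.exists(resolve_path(manifest$gff, dir)))
    fail("gff not found")
  thr <- utils::modifyList(DEFAULT_THRESHOLDS,
                           lapply(manifest$thresholds %||% list(),
                                  function(x) x))
  manifest$thresholds <- thr
  structure(manifest, class = "run_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(manifest) {
  m <- manifest
  m$.dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(m), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete analysis from a manifest
#'
#' Stages run in order: coverage loading, coverage filter, differential
#' test, site calling/clustering, category annotation and densities,
#' codon-relative profiles, motif matrices. All intermediate artifacts are
#' plain text (TSV / wiggle / BED / GFF3 / FASTA) under the manifest's
#' `output_dir`, every run writes a `summary.json` carrying the config
#' hash and the filtering funnel, and a rerun on identical inputs is
#' byte-identical.
#'
#' @param manifest A `run_manifest` or path to one.
#' @return Invisibly, a list with the main in-memory results (`table`,
#'   `results`, `clusters`, `assignment`, `density`, `codon`, `motifs`,
#'   `summary`).
#' @export
run_all <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  thr <- manifest$thresholds
  dir <- manifest$.dir %||% "."
  out_dir <- resolve_path(manifest$output_dir %||% "results", dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(manifest)
  log_lines <- c(sprintf("tierseq %s", as.character(
                   utils::packageVersion("tierseq"))),
                 sprintf("config_hash: %s", hash),
                 sprintf("thresholds: %s",
                         jsonlite::toJSON(thr, auto_unbox = TRUE)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  genome <- stage("coverage", read_genome_fasta(
    resolve_path(manifest$genome_fasta, dir)))
  track_sets <- stage("coverage", {
    ts <- lapply(manifest$libraries, function(l) {
      c(read_wiggle(resolve_path(l$wiggle_forward, dir), l$id),
        read_wiggle(resolve_path(l$wiggle_reverse, dir), l$id))
    })
    names(ts) <- vapply(manifest$libraries, `[[`, "", "id")
    ts
  })
  cond <- vapply(manifest$libraries, `[[`, "", "condition")
  table_all <- stage("coverage", build_position_table(track_sets, cond))
  table <- stage("sitecalling", filter_low_coverage(table_all,
                                                    thr$min_cov))
  log_lines <- c(log_lines,
                 sprintf("positions with any coverage: %d", nrow(table_all$key)),
                 sprintf("positions passing min_cov=%s: %d", thr$min_cov,
                         nrow(table$key)))
  results <- stage("difftest", run_difftest(table, fc_min = thr$fc_min,
                                            alpha = thr$alpha))
  write_test_results(results, file.path(out_dir, "test_results.tsv"))
  cands <- stage("sitecalling",
                 classify_candidates(results, thr$fc_min, thr$alpha))
  clusters <- stage("sitecalling", call_sites(results, thr$fc_min,
                                              thr$alpha, thr$proximity))
  export_sites(clusters, file.path(out_dir, "sites.bed"))
  utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  funnel <- table(factor(cands$class, c("cleavage", "enriched")))
  cl_n <- table(factor(clusters$class, c("cleavage", "enriched")))
  log_lines <- c(log_lines,
                 sprintf("candidate 5' ends: cleavage %d, enriched %d",
                         funnel[["cleavage"]], funnel[["enriched"]]),
                 sprintf("clustered sites: cleavage %d, enriched %d",
                         cl_n[["cleavage"]], cl_n[["enriched"]]))

  assignment <- density <- codon <- NULL
  if (!is.null(manifest$gff)) {
    features <- stage("annotation",
                      parse_gff(resolve_path(manifest$gff, dir)))
    assignment <- stage("annotation", assign_sites(clusters, features))
    utils::write.table(assignment$sites,
                       file.path(out_dir, "sites_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assignment$category_counts,
                       file.path(out_dir, "category_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    density <- stage("annotation", site_density(
      clusters[clusters$class == "cleavage", , drop = FALSE], features))
    utils::write.table(density$records,
                       file.path(out_dir, "site_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    codon <- stage("annotation", codon_relative_frequency(
      clusters[clusters$class == "cleavage", , drop = FALSE], features))
    utils::write.table(codon$start,
                       file.path(out_dir, "codon_offsets_start.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(codon$stop,
                       file.path(out_dir, "codon_offsets_stop.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  motifs <- list()
  bg <- genome_background(genome)
  for (cls in c("cleavage", "enriched")) {
    cl <- clusters[clusters$class == cls, , drop = FALSE]
    if (!nrow(cl)) next
    win <- suppressWarnings(extract_windows(cl, genome,
                                            flank = thr$flank + 1))
    if (!nrow(win)) next
    aligned <- shift_align(win, bg)
    motifs[[cls]] <- aligned$matrix
    export_windows_fasta(win, file.path(out_dir,
                                        paste0("windows_", cls, ".fa")))
    write_motif_matrix(aligned$matrix,
                       file.path(out_dir, paste0("motif_", cls, ".tsv")))
    write_meme_minimal(aligned$matrix,
                       file.path(out_dir, paste0("motif_", cls, ".meme")),
                       name = cls)
  }

  summary <- list(
    config_hash = hash,
    n_libraries = length(manifest$libraries),
    thresholds = thr,
    size_factors = as.list(attr(results, "size_factors")),
    funnel = list(
      positions_any = nrow(table_all$key),
      positions_filtered = nrow(table$key),
      candidates_cleavage = unname(funnel[["cleavage"]]),
      candidates_enriched = unname(funnel[["enriched"]]),
      sites_cleavage = unname(cl_n[["cleavage"]]),
      sites_enriched = unname(cl_n[["enriched"]])))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(table = table, results = results, clusters = clusters,
                 assignment = assignment, density = density, codon = codon,
                 motifs = motifs, summary = summary))
}

cli_usage <- function() {
  paste(
    "usage: tierseq <subcommand> [--key value ...]",
    "",
    "subcommands:",
    "  simulate  --out DIR [--seed N] [--n-cleavage N] [--n-enriched N]",
    "  run       --manifest FILE",
    "  coverage  --manifest FILE --out FILE     (write filtered table TSV)",
    "  call      --table FILE --out-prefix P [--min-cov N] [--fc-min X]",
    "            [--alpha X] [--proximity N]",
    "  annotate  --clusters FILE --gff FILE --out-prefix P",
    "  motif     --clusters FILE --genome FILE --out-prefix P",
    "  evaluate  --clusters FILE --truth FILE [--tolerance N]",
    "  --version",
    sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

read_clusters_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Command-line entry point
#'
#' Dispatches the `simulate` / `run` / `coverage` / `call` / `annotate` /
#' `motif` / `evaluate` subcommands; see `inst/cli/tierseq` for the
#' Rscript wrapper. Exit codes: 0 ok, 1 validation error, 2 compute
#' error.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
tierseq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(cli_usage()); return(invisible(1L))
  }
  if (args[1] == "--version") {
    cat("tierseq", as.character(utils::packageVersion("tierseq")), "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  opts <- tryCatch(parse_cli_args(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts)); message(cli_usage())
    return(invisible(1L))
  }
  message(sprintf("tierseq %s | %s | %s",
                  as.character(utils::packageVersion("tierseq")), sub,
                  paste(names(opts), unlist(opts), sep = "=",
                        collapse = " ")))
  run <- function(expr) {
    tryCatch({ expr; invisible(0L) },
             error = function(e) {
               message("error: ", conditionMessage(e))
               invisible(if (grepl("validation", conditionMessage(e)))
                 1L else 2L)
             })
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  switch(sub,
    simulate = run({
      if (is.null(opts$out)) stop("manifest validation: --out required")
      cfg <- sim_config(
        seed = as.integer(num(opts$seed, 1)),
        n_cleavage_sites = as.integer(num(opts$n_cleavage, 200)),
        n_enriched_sites = as.integer(num(opts$n_enriched, 200)))
      simulate_experiment(cfg, dir = opts$out)
      message("wrote synthetic experiment to ", opts$out)
    }),
    run = run({
      if (is.null(opts$manifest)) stop("manifest validation: --manifest required")
      run_all(opts$manifest)
    }),
    coverage = run({
      m <- read_manifest(opts$manifest)
      dir <- m$.dir
      ts <- lapply(m$libraries, function(l)
        c(read_wiggle(resolve_path(l$wiggle_forward, dir), l$id),
          read_wiggle(resolve_path(l$wiggle_reverse, dir), l$id)))
      names(ts) <- vapply(m$libraries, `[[`, "", "id")
      tab <- build_position_table(
        ts, vapply(m$libraries, `[[`, "", "condition"))
      tab <- filter_low_coverage(tab, m$thresholds$min_cov)
      write_position_table(tab, opts$out)
    }),
    call = run({
      tab <- read_position_table(opts$table)
      tab <- filter_low_coverage(tab, num(opts$min_cov, 10))
      res <- run_difftest(tab, fc_min = num(opts$fc_min, 2),
                          alpha = num(opts$alpha, 0.05))
      cl <- call_sites(res, num(opts$fc_min, 2), num(opts$alpha, 0.05),
                       num(opts$proximity, 3))
      write_test_results(res, paste0(opts$out_prefix, "_results.tsv"))
      utils::write.table(cl, paste0(opts$out_prefix, "_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_sites(cl, paste0(opts$out_prefix, "_sites.bed"))
    }),
    annotate = run({
      cl <- read_clusters_tsv(opts$clusters)
      feats <- parse_gff(opts$gff)
      asg <- assign_sites(cl, feats)
      dens <- site_density(cl, feats)
      utils::write.table(asg$sites,
                         paste0(opts$out_prefix, "_annotated.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(asg$category_counts,
                         paste0(opts$out_prefix, "_categories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dens$records,
                         paste0(opts$out_prefix, "_density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }),
    motif = run({
      cl <- read_clusters_tsv(opts$clusters)
      genome <- read_genome_fasta(opts$genome)
      bg <- genome_background(genome)
      win <- suppressWarnings(extract_windows(cl, genome, flank = 6))
      al <- shift_align(win, bg)
      write_motif_matrix(al$matrix, paste0(opts$out_prefix, "_motif.tsv"))
      export_windows_fasta(win, paste0(opts$out_prefix, "_windows.fa"))
    }),
    evaluate = run({
      cl <- read_clusters_tsv(opts$clusters)
      truth <- utils::read.table(opts$truth, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      ev <- evaluate_recovery(cl, truth, num(opts$tolerance, 2))
      utils::write.table(ev$summary, stdout(), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }),
    {
      message("unknown subcommand: ", sub); message(cli_usage())
      invisible(1L)
    })
}
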