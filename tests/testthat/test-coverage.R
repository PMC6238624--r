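test_that("five_prime_coverage applies the first-base-in-read convention", {
  g <- toy_genome(c(chr1 = strrep("A", 200)))
  reads <- data.frame(replicon = "chr1",
                      start = c(100, 100, rep(7, 10)),
                      end = c(150, 150, rep(30, 10)),
                      strand = c("+", "-", rep("+", 10)))
  tr <- five_prime_coverage(reads, g)
  fwd <- tr[["chr1|+"]]; rev <- tr[["chr1|-"]]
  # + read counts at start, - read at end (its biological 5' end)
  expect_equal(fwd$counts[fwd$positions == 100], 1L)
  expect_equal(rev$positions, 150L)
  expect_equal(rev$counts, 1L)
  # additivity: 10 identical reads pile up at one position
  expect_equal(fwd$counts[fwd$positions == 7], 10L)
  expect_equal(sum(fwd$counts) + sum(rev$counts), nrow(reads))
})

test_that("five_prime_coverage rejects out-of-bounds and unknown replicons", {
  g <- toy_genome(c(chr1 = strrep("A", 100)))
  expect_error(five_prime_coverage(
    data.frame(replicon = "chr1", start = 90, end = 120, strand = "+"), g),
    "outside replicon bounds")
  expect_error(five_prime_coverage(
    data.frame(replicon = "chrX", start = 1, end = 5, strand = "+"), g),
    "unknown replicon")
})

test_that("coverage conserves read counts and mirrors under strand flip", {
  set.seed(42)
  L <- 500L
  g <- toy_genome(c(chr1 = paste(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = "")))
  for (rep_i in 1:5) {
    n <- 200
    start <- sample.int(L - 60, n)
    reads <- data.frame(replicon = "chr1", start = start,
                        end = start + sample(10:50, n, replace = TRUE),
                        strand = sample(c("+", "-"), n, replace = TRUE))
    tr <- five_prime_coverage(reads, g)
    # conservation per (replicon, strand)
    for (st in c("+", "-"))
      expect_equal(sum(tr[[paste0("chr1|", st)]]$counts),
                   sum(reads$strand == st))
    # mirror: flip coordinates and strands
    mreads <- data.frame(replicon = "chr1",
                         start = L + 1L - reads$end,
                         end = L + 1L - reads$start,
                         strand = ifelse(reads$strand == "+", "-", "+"))
    mtr <- five_prime_coverage(mreads, mirror_genome(g))
    for (st in c("+", "-")) {
      orig <- tr[[paste0("chr1|", st)]]
      mirr <- mtr[[paste0("chr1|", if (st == "+") "-" else "+")]]
      expect_equal(sort(L + 1L - orig$positions), mirr$positions)
      expect_equal(orig$counts[order(L + 1L - orig$positions)], mirr$counts)
    }
  }
})

test_that("wiggle write/read round-trips sparse count maps", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(0:40, 1)
    pos <- sort(sample.int(1000, n))
    cnt <- sample.int(500, n, replace = TRUE)
    tr <- tierseq:::new_coverage_track("libA", "chr1",
                                      sample(c("+", "-"), 1), pos, cnt)
    path <- withr::local_tempfile(fileext = ".wig")
    write_wiggle(tr, path)
    back <- read_wiggle(path)
    key <- paste0("chr1|", tr$strand)
    expect_named(back, key)
    expect_identical(back[[key]]$positions, tr$positions)
    expect_identical(back[[key]]$counts, tr$counts)
    expect_identical(back[[key]]$library_id, "libA")
  }
})

test_that("read_wiggle handles sign convention, dialect and parse errors", {
  path <- withr::local_tempfile(fileext = ".wig")
  writeLines(c('track type=wiggle_0 name="libA_reverse"',
               "variableStep chrom=chr1 span=1",
               "12 -4"), path)
  tr <- read_wiggle(path)[["chr1|-"]]
  expect_equal(tr$positions, 12L)
  expect_equal(tr$counts, 4L)   # magnitude of a sign-encoded reverse value

  writeLines(c('track type=wiggle_0 name="libA_forward"',
               "fixedStep chrom=chr1 start=1 step=1", "3"), path)
  expect_error(read_wiggle(path), "unsupported dialect")

  writeLines(c('track type=wiggle_0 name="libA_forward"',
               "variableStep chrom=chr1 span=1",
               "5 3", "9 1.5"), path)
  expect_error(read_wiggle(path), "line 4")

  # empty track: header only -> empty count map
  writeLines(c('track type=wiggle_0 name="libA_forward"',
               "variableStep chrom=chr1 span=1"), path)
  tr <- read_wiggle(path)[["chr1|+"]]
  expect_length(tr$positions, 0)
})

test_that("build_position_table takes the union of nonzero positions", {
  mk <- function(lib, pos, cnt)
    list("chr1|+" = tierseq:::new_coverage_track(lib, "chr1", "+", pos, cnt),
         "chr1|-" = tierseq:::new_coverage_track(lib, "chr1", "-",
                                                 integer(), integer()))
  tab <- build_position_table(
    list(lib1 = mk("lib1", 10L, 5L), lib2 = mk("lib2", 11L, 2L)),
    c("wild_type", "mutant"))
  expect_equal(tab$key$position, c(10L, 11L))
  expect_equal(unname(tab$counts), matrix(c(5L, 0L, 0L, 2L), 2))

  tab2 <- build_position_table(
    list(lib1 = mk("lib1", 10L, 5L), lib2 = mk("lib2", 10L, 7L)),
    c("wild_type", "mutant"))
  expect_equal(nrow(tab2$key), 1L)
  expect_equal(unname(tab2$counts[1, ]), c(5L, 7L))

  empty <- build_position_table(
    list(lib1 = mk("lib1", integer(), integer()),
         lib2 = mk("lib2", integer(), integer())),
    c("wild_type", "mutant"))
  expect_equal(nrow(empty$key), 0L)

  expect_error(build_position_table(
    list(lib1 = mk("lib1", 10L, 5L), lib1 = mk("lib1", 10L, 5L)),
    c("wild_type", "mutant")), "unique library ids")
  bad <- list(lib1 = mk("lib1", 10L, 5L),
              lib2 = mk("lib2", 10L, 5L)["chr1|+"])
  expect_error(build_position_table(bad, c("wild_type", "mutant")),
               "mismatched")
})

test_that("position table TSV round-trips with condition labels", {
  tab <- toy_table(matrix(c(10, 0, 3, 25, 1, 9, 0, 8), 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_position_table(tab, path)
  back <- read_position_table(path)
  expect_equal(back$key, tab$key)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$libraries, tab$libraries)
})
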