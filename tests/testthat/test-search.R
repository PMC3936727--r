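test_that("align_spacer handles the identity case and the 90% threshold", {
  set.seed(55)
  sp <- rand_dna(20)
  al <- align_spacer(sp, sp)
  expect_equal(al$identity, 1.0)
  expect_identical(al$gaps, 0L)
  expect_identical(c(al$start, al$end), c(0L, 20L))

  flip <- function(x, pos) {
    for (p in pos) substr(x, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(x, p, p))[1]
    x
  }
  # two mismatches sit at the paper-scale threshold; three fall below it
  expect_equal(align_spacer(sp, flip(sp, c(3, 11)))$identity, 0.90)
  expect_equal(align_spacer(sp, flip(sp, c(3, 11, 17)))$identity, 0.85)
  expect_error(align_spacer("ACGTACGT", "ACG"), "longer than window")
})

test_that("align_spacer score equals exhaustive alignment enumeration", {
  set.seed(101)
  for (case in 1:8) {
    m <- sample(5:7, 1)
    n <- sample(m:12, 1)
    sp <- rand_dna(m)
    w <- rand_dna(n)
    expect_equal(align_spacer(sp, w)$score,
                 oracle_semiglobal_score(sp, w),
                 info = sprintf("case %d: %s vs %s", case, sp, w))
  }
  # and on a window that contains the spacer verbatim
  sp <- rand_dna(6)
  w <- paste0(rand_dna(3), sp, rand_dna(3))
  expect_equal(align_spacer(sp, w)$score, oracle_semiglobal_score(sp, w))
  expect_equal(align_spacer(sp, w)$score, 6)
})

test_that("a verbatim planted spacer is found at its exact coordinates", {
  set.seed(7)
  sp <- rand_dna(22)
  genome <- paste0(rand_dna(100), sp, rand_dna(80))
  lc <- crispr_locus("l1", "sp.", "GTTTTAGAGCTATGCTGTTTTG", c(s1 = sp))
  tg <- seq_records("t1", genome)
  h <- find_protospacers(lc, tg)
  h <- h[h$identity == 1, ]
  expect_identical(h$start, 100L)
  expect_identical(h$end, 122L)
  expect_identical(h$strand, "+")
  expect_identical(h$protospacer_seq, sp)
})

test_that("hit sets equal the brute-force sliding-window oracle", {
  set.seed(202)
  cols <- c("spacer_id", "target_id", "start", "end", "strand", "score",
            "identity", "matches", "gaps")
  for (case in 1:6) {
    m <- sample(12:16, 1)
    sp <- rand_dna(m)
    lc <- crispr_locus(sprintf("l%d", case), "sp.", rand_dna(30),
                       stats::setNames(sp, sprintf("s%d", case)))
    genome <- rand_dna(250)
    # plant one clean and one mutated copy
    mut <- sp
    substr(mut, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 4, 4))[1]
    genome <- paste0(substr(genome, 1, 60), sp,
                     substr(genome, 61, 170), revcomp(mut),
                     substr(genome, 171, 250))
    tg <- seq_records("t1", genome)
    got <- find_protospacers(lc, tg)[, cols]
    want <- oracle_find_protospacers(lc, tg)[, cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("case", case))
    expect_gte(nrow(got), 2)
  }
})

test_that("reverse-complementing all targets mirrors hits exactly", {
  cp <- synth_corpus(seed = 31, n_protospacers = 15, true_pam = "NGG",
                     mutation_rate = 0.01, genome_length = 1500)
  fwd <- find_protospacers(cp$locus, cp$genome)
  rc <- cp$genome
  rc$residues <- revcomp(rc$residues)
  rev <- find_protospacers(cp$locus, rc)
  L <- nchar(cp$genome$residues)
  expect_identical(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         protospacer_seq = rev$protospacer_seq,
                         stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$start), ]
  orig <- fwd[order(fwd$start), c("start", "end", "strand",
                                  "protospacer_seq")]
  rownames(mirrored) <- rownames(orig) <- NULL
  expect_equal(orig, mirrored)
})

test_that("filter soundness, determinism, and degenerate inputs", {
  cp <- synth_corpus(seed = 17, n_protospacers = 10, mutation_rate = 0.05,
                     genome_length = 1200)
  h1 <- find_protospacers(cp$locus, cp$genome, min_identity = 0.9)
  expect_true(all(h1$identity >= 0.9))
  expect_true(all(h1$gaps <= 2))
  expect_true(all(h1$start >= 0 & h1$end <= nchar(cp$genome$residues)))
  h2 <- find_protospacers(cp$locus, cp$genome, min_identity = 0.9)
  expect_identical(h1, h2)
  # protospacer_seq equals the strand-adjusted target slice
  for (i in seq_len(nrow(h1))) {
    slice <- substr(cp$genome$residues, h1$start[i] + 1, h1$end[i])
    if (h1$strand[i] == "-") slice <- revcomp(slice)
    expect_identical(h1$protospacer_seq[i], slice)
  }
  expect_error(find_protospacers(list(), cp$genome), "no spacers")
  expect_warning(h0 <- find_protospacers(cp$locus, cp$genome[0, ]),
                 "empty target")
  expect_identical(nrow(h0), 0L)
})

test_that("array-mask intervals exclude self-array matches", {
  set.seed(9)
  sp <- rand_dna(20)
  genome <- paste0(rand_dna(50), sp, rand_dna(50), sp, rand_dna(50))
  lc <- crispr_locus("l1", "sp.", rand_dna(30), c(s1 = sp))
  tg <- seq_records("t1", genome)
  h <- find_protospacers(lc, tg)
  expect_identical(nrow(h[h$identity == 1, ]), 2L)
  masked <- find_protospacers(lc, tg,
    mask = data.frame(target_id = "t1", start = 50, end = 70))
  expect_identical(nrow(masked[masked$identity == 1, ]), 1L)
  expect_identical(masked$start[masked$identity == 1], 120L)
})

test_that("classify_source labels hits and falls back to unknown", {
  hits <- data.frame(target_id = c("p1", "g1", "zz"),
                     stringsAsFactors = FALSE)
  meta <- data.frame(target_id = c("p1", "g1"),
                     class = c("phage", "genome"))
  expect_message(out <- classify_source(hits, meta), "genome-class")
  expect_identical(out$source_class, c("phage", "genome", "unknown"))
})

test_that("BED6 and GFF3 writers emit the documented conventions", {
  cp <- synth_corpus(seed = 23, n_protospacers = 5, mutation_rate = 0,
                     genome_length = 900)
  h <- find_protospacers(cp$locus, cp$genome)
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_hits_bed(h, bed)
  write_hits_gff3(h, gff)
  bl <- read.delim(bed, header = FALSE)
  expect_identical(nrow(bl), nrow(h))
  expect_identical(bl$V5, as.integer(round(h$identity * 1000)))
  gl <- readLines(gff)
  expect_identical(gl[1], "##gff-version 3")
  fields <- strsplit(gl[-1], "\t")
  expect_true(all(lengths(fields) == 9))
  # GFF3 is 1-based inclusive
  expect_identical(as.integer(vapply(fields, `[`, "", 4)), h$start + 1L)
  expect_identical(as.integer(vapply(fields, `[`, "", 5)), h$end)
  gr <- hits_to_granges(h)
  expect_identical(BiocGenerics::start(gr), h$start + 1L)
  expect_identical(BiocGenerics::end(gr), h$end)
})
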