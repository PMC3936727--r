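test_that("extract_flank obeys strand and boundary conventions", {
  tg <- seq_records("t1", "AAAACCCCGGGGTTTTACGTACGTAAAACCCC")   # 32 nt
  # forward hit over [4, 8): flank = next 10 bases
  hit <- data.frame(target_id = "t1", start = 4L, end = 8L, strand = "+")
  expect_identical(extract_flank(hit, tg), substr(tg$residues, 9, 18))
  # reverse hit starting at 20: flank = revcomp of the 10 bases before it
  hit2 <- data.frame(target_id = "t1", start = 20L, end = 24L, strand = "-")
  expect_identical(extract_flank(hit2, tg),
                   revcomp(substr(tg$residues, 11, 20)))
  # too close to the contig end -> absent with warning
  hit3 <- data.frame(target_id = "t1", start = 22L, end = 26L, strand = "+")
  expect_warning(fl <- extract_flank(hit3, tg), "fewer than 10")
  expect_identical(fl, NA_character_)
  expect_error(extract_flank(hit, seq_records("t2", "ACGT")), "refers to")
})

test_that("PFM counts conserve and skip ambiguous bases", {
  pfm <- build_pfm("AAAAAAAAAA")
  expect_identical(unname(pfm$counts[, "A"]), rep(1L, 10))
  expect_identical(sum(pfm$counts), 10L)

  fl <- c("ACGNACGTAC", "ACGTACGTAC", "NCGTACGTAN")
  pfm <- build_pfm(fl)
  expect_identical(pfm$n, 3L)
  # conservation at every position
  expect_identical(as.integer(rowSums(pfm$counts) + pfm$skipped),
                   rep(3L, 10))
  expect_identical(pfm$skipped, c(1L, 0L, 0L, 1L, rep(0L, 5), 1L))
  expect_error(build_pfm(character(0)), "no protospacers")
  expect_error(build_pfm(c("ACGT", "ACGTACGTAC")), "length")
})

test_that("information content matches the closed forms", {
  uni <- build_pfm(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                     "TTTTTTTTTT"))
  expect_equal(information_content(uni), rep(0, 10))
  pure <- build_pfm(c("GGGGGGGGGG", "GGGGGGGGGG"))
  expect_equal(information_content(pure), rep(2, 10))
  half <- build_pfm(c("AAAAAAAAAA", "CCCCCCCCCC"))
  expect_equal(information_content(half), rep(1, 10))
  # always within [0, 2]
  set.seed(3)
  for (k in 1:10) {
    pfm <- build_pfm(replicate(7, rand_dna(10)))
    ic <- information_content(pfm)
    expect_true(all(ic >= 0 & ic <= 2))
  }
  # zero usable counts -> 0 with warning
  allN <- build_pfm(c("NNNNNNNNNN", "NNNNNNNNNN"))
  expect_warning(ic <- information_content(allN), "zero usable")
  expect_equal(ic, rep(0, 10))
  # small-sample correction only lowers IC
  pfm <- build_pfm(replicate(5, rand_dna(10)))
  expect_true(all(information_content(pfm, TRUE) <=
                    information_content(pfm) + 1e-12))
})

test_that("consensus calling surfaces balanced positions as two-letter codes", {
  # 50/50 A/C at every position -> M (the position-5 ambiguity pattern)
  half <- build_pfm(c("AAAAAAAAAA", "CCCCCCCCCC", "AAAAAAAAAA",
                      "CCCCCCCCCC"))
  expect_identical(call_consensus(half), strrep("M", 10))
  pure <- build_pfm(rep("GGGGGGGGGG", 3))
  expect_identical(call_consensus(pure), strrep("G", 10))
  uni <- build_pfm(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                     "TTTTTTTTTT"))
  expect_identical(call_consensus(uni), strrep("N", 10))
  expect_error(call_consensus(build_pfm(c("AAAAAAAAAA", "AAAAAAAAAA"))),
               "min_support")
})

test_that("consensus base sets cover at least the coverage fraction", {
  set.seed(12)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  for (k in 1:15) {
    flanks <- replicate(sample(5:30, 1), rand_dna(10))
    pfm <- build_pfm(flanks)
    cons <- strsplit(call_consensus(pfm, coverage = 0.8,
                                    min_support = 0), "")[[1]]
    f <- pfm$counts / rowSums(pfm$counts)
    for (p in 1:10) {
      covered <- sum(f[p, sets[[cons[p]]]])
      expect_gte(covered, 0.8 - 1e-12)
    }
  }
})

test_that("a planted PAM is recovered through the full flank pipeline", {
  cp <- synth_corpus(seed = 5, n_protospacers = 50, true_pam = "NGG",
                     mutation_rate = 0.02)
  hits <- find_protospacers(cp$locus, cp$genome)
  hf <- collect_flanks(hits, cp$genome)
  cons <- call_consensus(build_pfm(hf$flank))
  expect_identical(substr(cons, 2, 3), "GG")
})

test_that("strand invariance: profiles are identical after global revcomp", {
  cp <- synth_corpus(seed = 19, n_protospacers = 25, true_pam = "NNAGAAW",
                     mutation_rate = 0.01, genome_length = 2500)
  h1 <- find_protospacers(cp$locus, cp$genome)
  rc <- cp$genome
  rc$residues <- revcomp(rc$residues)
  h2 <- find_protospacers(cp$locus, rc)
  f1 <- sort(collect_flanks(h1, cp$genome)$flank)
  f2 <- sort(collect_flanks(h2, rc)$flank)
  expect_identical(f1, f2)
  expect_identical(call_consensus(build_pfm(f1)),
                   call_consensus(build_pfm(f2)))
})

test_that("source partitions separate a mutated chromosomal PAM", {
  # phage targets carry NNNNACA, the genome target carries NNNNCCA:
  # the position-5 consensus must differ between partitions
  lc <- generate_locus(seed = 77, n_spacers = 4, spacer_len = 20)
  gP <- generate_genome(2500, seed = 771, id = "phageA")
  gG <- generate_genome(2500, seed = 772, id = "chrom1")
  eP <- embed_protospacers(gP, lc$spacers, "NNNNACA", n = 25, seed = 773,
                           mutation_rate = 0)
  eG <- embed_protospacers(gG, lc$spacers, "NNNNCCA", n = 25, seed = 774,
                           mutation_rate = 0)
  targets <- rbind(eP$genome, eG$genome)
  meta <- data.frame(target_id = c("phageA", "chrom1"),
                     class = c("phage", "genome"))
  hits <- suppressMessages(
    find_protospacers(lc, targets, target_metadata = meta))
  profs <- partition_by_source(hits, targets)
  expect_setequal(names(profs), c("phage", "genome"))
  expect_identical(substr(profs$phage$consensus, 5, 5), "A")
  expect_identical(substr(profs$genome$consensus, 5, 5), "C")
  expect_identical(substr(profs$phage$consensus, 6, 7), "CA")
  # per-class n sums to total usable flanks
  hf <- collect_flanks(hits, targets)
  expect_identical(profs$phage$n + profs$genome$n, nrow(hf))
})

test_that("logo heights per position sum to the information content", {
  set.seed(8)
  pfm <- build_pfm(replicate(12, rand_dna(10)))
  logo <- export_logo_data(pfm)
  ic <- information_content(pfm)
  sums <- tapply(logo$height, logo$position, sum)
  expect_equal(as.numeric(sums), ic)
  # uniform column -> all zero heights; pure column -> single height 2
  uni <- export_logo_data(build_pfm(c("AAAAAAAAAA", "CCCCCCCCCC",
                                      "GGGGGGGGGG", "TTTTTTTTTT")))
  expect_equal(uni$height, rep(0, 40))
  pure <- export_logo_data(build_pfm(rep("GGGGGGGGGG", 2)))
  expect_equal(sum(pure$height[pure$base == "G"]), 20)
  expect_equal(sum(pure$height[pure$base != "G"]), 0)
})

test_that("flank deduplication collapses inherited protospacers", {
  set.seed(44)
  sp <- rand_dna(20)
  lc <- crispr_locus("l1", "sp.", rand_dna(30), c(s1 = sp))
  block <- paste0(sp, "TTTGGAACCA")
  genome <- paste0(rand_dna(40), block, rand_dna(40), block, rand_dna(40))
  tg <- seq_records("t1", genome)
  h <- find_protospacers(lc, tg)
  expect_identical(nrow(collect_flanks(h, tg, dedupe = TRUE)), 1L)
  expect_identical(nrow(collect_flanks(h, tg, dedupe = FALSE)), 2L)
})

test_that("PFM and profile writers round-trip the counts", {
  pfm <- build_pfm(replicate(6, rand_dna(10)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pfm(pfm, f)
  back <- read.delim(f)
  expect_identical(nrow(back), 10L)
  expect_identical(as.matrix(back[, c("A", "C", "G", "T")]),
                   matrix(pfm$counts, 10, 4,
                          dimnames = list(NULL, c("A", "C", "G", "T"))))
  j <- withr::local_tempfile(fileext = ".json")
  prof <- pam_profile(pfm, min_support = 0)
  write_profile_json(prof, j)
  parsed <- jsonlite::read_json(j)
  expect_identical(parsed$consensus, prof$consensus)
  expect_identical(parsed$n, prof$n)
})
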