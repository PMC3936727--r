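# run code under a private RNG stream, restoring any existing state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# derive independent per-operation substream seeds from one master seed
substream <- function(seed, tag) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(tag)) * 31L) %% 2147483647L
}

#' Generate a random genome sequence
#'
#' i.i.d. bases with the requested GC fraction; deterministic per seed.
#'
#' @param length genome length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @param id record id (default derived from the seed).
#' @return a one-row [seq_records] table.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L,
                            id = sprintf("synth_genome_%d", seed)) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)", call. = FALSE)
  bases <- with_seed(substream(seed, "genome"),
    sample(DNA_STRICT, length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  seq_records(id, paste(bases, collapse = ""))
}

#' Generate a random CRISPR locus
#'
#' Random repeat and pairwise-distinct spacers (distinctness enforced by
#' rejection), forward orientation, deterministic ids.
#'
#' @param repeat_len repeat length (20-50 nt).
#' @param n_spacers number of spacers.
#' @param spacer_len spacer length (20-40 nt).
#' @param seed integer seed.
#' @param locus_id locus id (default derived from the seed).
#' @param species species label.
#' @return a [crispr_locus].
#' @export
generate_locus <- function(repeat_len = 36L, n_spacers = 6L,
                           spacer_len = 30L, seed = 1L,
                           locus_id = sprintf("synth_locus_%d", seed),
                           species = "Synthetica exempli") {
  stopifnot(repeat_len >= 20, repeat_len <= 50,
            spacer_len >= 15, spacer_len <= 40, n_spacers >= 1)
  rnd <- function(n) paste(sample(DNA_STRICT, n, replace = TRUE),
                           collapse = "")
  with_seed(substream(seed, "locus"), {
    rep_seq <- rnd(repeat_len)
    spacers <- character(0)
    while (length(spacers) < n_spacers) {
      cand <- rnd(spacer_len)
      if (!cand %in% spacers) spacers <- c(spacers, cand)
    }
    names(spacers) <- sprintf("%s_sp%02d", locus_id, seq_len(n_spacers))
    crispr_locus(locus_id, species, rep_seq, spacers,
                 orientation = "forward")
  })
}

# mutate a sequence at a per-base rate; returns sequence + mutated positions
mutate_seq <- function(x, rate) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(DNA_STRICT, ch[p]), 1)
  list(seq = paste(ch, collapse = ""), positions = hit)
}

# concrete flank sampled uniformly within each IUPAC base set, padded with
# N to flank_len
sample_flank <- function(true_pam, flank_len) {
  pat <- strsplit(toupper(true_pam), "")[[1]]
  if (length(pat) < flank_len)
    pat <- c(pat, rep("N", flank_len - length(pat)))
  paste(vapply(pat, function(p) {
    set <- iupac_sets[[p]]
    if (is.null(set)) stop("invalid IUPAC letter '", p, "' in true_pam",
                           call. = FALSE)
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

#' Plant protospacers with a ground-truth PAM into a genome
#'
#' Each placement writes a (per-base mutated) spacer copy into the genome on
#' a uniformly chosen strand, followed 3' on that strand by a concrete
#' flank drawn uniformly from the base sets of `true_pam` (padded with `N`
#' to `flank_len`) and mutated at the same rate.  Placements are rejected
#' rather than overlapped, and the flank convention mirrors
#' [extract_flank()] exactly.  The manifest records the full ground truth.
#'
#' @param genome a one-row [seq_records] table.
#' @param spacers named character vector of spacer sequences (e.g.
#'   `locus$spacers`).
#' @param true_pam IUPAC string of the ground-truth PAM.
#' @param n number of placements.
#' @param mutation_rate per-base mutation probability.
#' @param seed integer seed.
#' @param flank_len planted flank width (default 10).
#' @return list with `genome` (modified record) and `manifest` (list:
#'   `seed`, `true_pam`, `mutation_rate`, `flank_len`, and `placements`, a
#'   data frame with `target_id`, `spacer_id`, `start`, `end`, `strand`,
#'   `n_mutations`, `planted_spacer`, `realized_flank`,
#'   `flank_mutations`).
#' @export
embed_protospacers <- function(genome, spacers, true_pam, n,
                               mutation_rate = 0.02, seed = 1L,
                               flank_len = 10L) {
  stopifnot(nrow(genome) == 1, n >= 1, length(spacers) >= 1)
  L <- nchar(genome$residues)
  slot <- max(nchar(spacers)) + flank_len
  if (n * (slot + 2L) > L)
    stop("genome too short for ", n, " non-overlapping placements; ",
         "need at least ", n * (slot + 2L), " bp", call. = FALSE)
  with_seed(substream(seed, "embed"), {
    gch <- strsplit(genome$residues, "")[[1]]
    used <- logical(L)
    place <- list()
    attempts <- 0L
    while (length(place) < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n)
        stop("could not place ", n, " protospacers without overlap",
             call. = FALSE)
      si <- sample(seq_along(spacers), 1)
      sp <- unname(spacers[si]); slen <- nchar(sp)
      strand <- sample(c("+", "-"), 1)
      # reserve [start, end) for the protospacer plus the strand-aware flank
      start <- sample.int(L - slen - flank_len + 1L, 1) - 1L
      if (strand == "-") start <- start + flank_len
      lo <- if (strand == "+") start else start - flank_len
      hi <- if (strand == "+") start + slen + flank_len else start + slen
      if (lo < 0 || hi > L || any(used[seq(lo + 1L, hi)])) next
      mut <- mutate_seq(sp, mutation_rate)
      flank0 <- sample_flank(true_pam, flank_len)
      fmut <- mutate_seq(flank0, mutation_rate)
      if (strand == "+") {
        gch[seq(start + 1L, start + slen)] <- strsplit(mut$seq, "")[[1]]
        gch[seq(start + slen + 1L, start + slen + flank_len)] <-
          strsplit(fmut$seq, "")[[1]]
      } else {
        gch[seq(start + 1L, start + slen)] <-
          strsplit(revcomp(mut$seq), "")[[1]]
        gch[seq(start - flank_len + 1L, start)] <-
          strsplit(revcomp(fmut$seq), "")[[1]]
      }
      used[seq(lo + 1L, hi)] <- TRUE
      place[[length(place) + 1L]] <- data.frame(
        target_id = genome$id, spacer_id = names(spacers)[si],
        start = start, end = start + slen, strand = strand,
        n_mutations = length(mut$positions),
        planted_spacer = mut$seq, realized_flank = fmut$seq,
        flank_mutations = length(fmut$positions),
        stringsAsFactors = FALSE)
    }
    placements <- do.call(rbind, place)
    placements <- placements[order(placements$start), , drop = FALSE]
    rownames(placements) <- NULL
    genome$residues <- paste(gch, collapse = "")
    list(genome = genome,
         manifest = list(seed = seed, true_pam = true_pam,
                         mutation_rate = mutation_rate,
                         flank_len = flank_len, placements = placements))
  })
}

#' Generate protein families with known cluster membership
#'
#' `k_families` random ancestral proteins (rejected until pairwise
#' divergence is at least `between_divergence`), each expanded into members
#' by i.i.d. substitution at `within_divergence`.
#'
#' @param k_families number of families.
#' @param members_per_family members per family.
#' @param length protein length in aa.
#' @param within_divergence per-site substitution probability within a
#'   family (must be `< between_divergence`).
#' @param between_divergence minimum pairwise divergence between ancestors.
#' @param seed integer seed.
#' @return list with `records` ([seq_records], protein) and `labels`
#'   (named integer vector of family indices).
#' @export
generate_protein_family <- function(k_families = 3L, members_per_family = 5L,
                                    length = 900L, within_divergence = 0.05,
                                    between_divergence = 0.7, seed = 1L) {
  if (within_divergence >= between_divergence)
    stop("within_divergence must be < between_divergence", call. = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(substream(seed, "protfam"), {
    rnd <- function() sample(aa, length, replace = TRUE)
    anc <- list()
    tries <- 0L
    while (length(anc) < k_families) {
      tries <- tries + 1L
      if (tries > 100L * k_families)
        stop("cannot satisfy between_divergence by rejection", call. = FALSE)
      cand <- rnd()
      if (all(vapply(anc, function(a) mean(a != cand), 0) >=
              between_divergence))
        anc[[length(anc) + 1L]] <- cand
    }
    ids <- character(0); seqs <- character(0); labels <- integer(0)
    for (f in seq_len(k_families)) {
      for (mm in seq_len(members_per_family)) {
        ch <- anc[[f]]
        hit <- which(stats::runif(length) < within_divergence)
        for (p in hit) ch[p] <- sample(setdiff(aa, ch[p]), 1)
        ids <- c(ids, sprintf("fam%02d_m%02d", f, mm))
        seqs <- c(seqs, paste(ch, collapse = ""))
        labels <- c(labels, f)
      }
    }
    list(records = seq_records(ids, seqs, moltype = "protein"),
         labels = stats::setNames(labels, ids))
  })
}

#' Materialize a complete synthetic PAM-discovery corpus
#'
#' Convenience wrapper: one locus, one genome with planted protospacers,
#' and the ground-truth manifest — the standard test bed for the
#' spacer-to-consensus pipeline.
#'
#' @param seed integer seed (drives every random choice).
#' @param n_protospacers placements to plant.
#' @param true_pam ground-truth IUPAC PAM.
#' @param mutation_rate per-base mutation rate.
#' @param genome_length background genome length.
#' @param n_spacers,spacer_len locus geometry.
#' @param gc background GC fraction.
#' @return list with `locus`, `genome`, `manifest`.
#' @export
synth_corpus <- function(seed = 1L, n_protospacers = 50L, true_pam = "NGG",
                         mutation_rate = 0.02, genome_length = 4000L,
                         n_spacers = 5L, spacer_len = 20L, gc = 0.5) {
  locus <- generate_locus(n_spacers = n_spacers, spacer_len = spacer_len,
                          seed = seed)
  genome <- generate_genome(genome_length, gc = gc, seed = seed)
  emb <- embed_protospacers(genome, locus$spacers, true_pam,
                            n = n_protospacers,
                            mutation_rate = mutation_rate, seed = seed)
  list(locus = locus, genome = emb$genome, manifest = emb$manifest)
}
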