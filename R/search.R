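#' Best semi-global alignment of a spacer inside a window
#'
#' The spacer is aligned end-to-end; window overhangs are free.  Scoring is
#' megaBLAST-like: match `+1`, mismatch `-2`, affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`).  Identity is anchored to the spacer:
#' `matches / nchar(spacer)`, which makes a 90% threshold unambiguous.
#'
#' Ties are resolved deterministically: among equal-scoring alignments the
#' one ending leftmost in the window wins, and the traceback prefers
#' aligned columns over window-gap over spacer-gap states.
#'
#' @param spacer spacer sequence (A/C/G/T, length 15-60 in typical use).
#' @param window window sequence, at least as long as the spacer.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `score`, `identity`, `matches`, `gaps` (gap columns),
#'   and `start`/`end` (0-based half-open span of the alignment in the
#'   window).
#' @export
align_spacer <- function(spacer, window, match = 1, mismatch = -2,
                         gap_open = -5, gap_extend = -2) {
  s <- strsplit(toupper(spacer), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  m <- length(s); n <- length(w)
  if (m < 1) stop("empty spacer", call. = FALSE)
  if (m > n) stop("spacer longer than window", call. = FALSE)
  NEG <- -1e9
  go <- gap_open + gap_extend              # cost of the first gapped column
  # state matrices over (i = spacer pos, j = window pos), row 0 = free start
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  M[1, ] <- 0                              # free leading window overhang
  for (i in seq_len(m)) {
    ii <- i + 1
    Y[ii, 1] <- max(M[ii - 1, 1] + go, Y[ii - 1, 1] + gap_extend)
    for (j in seq_len(n)) {
      jj <- j + 1
      sub <- if (s[i] == w[j]) match else mismatch
      M[ii, jj] <- sub + max(M[ii - 1, jj - 1], X[ii - 1, jj - 1],
                             Y[ii - 1, jj - 1])
      X[ii, jj] <- max(M[ii, jj - 1] + go, X[ii, jj - 1] + gap_extend)
      Y[ii, jj] <- max(M[ii - 1, jj] + go, Y[ii - 1, jj] + gap_extend)
    }
  }
  fin <- pmax(M[m + 1, ], Y[m + 1, ])      # free trailing window overhang
  best <- max(fin)
  jend <- which(fin == best)[1] - 1        # leftmost end, 0-based
  # traceback
  i <- m; j <- jend
  state <- if (M[m + 1, jend + 1] >= Y[m + 1, jend + 1]) "M" else "Y"
  matches <- 0L; gaps <- 0L; end0 <- jend
  while (i > 0) {
    ii <- i + 1; jj <- j + 1
    if (state == "M") {
      if (s[i] == w[j]) matches <- matches + 1L
      sub <- if (s[i] == w[j]) match else mismatch
      prevs <- c(M = M[ii - 1, jj - 1], X = X[ii - 1, jj - 1],
                 Y = Y[ii - 1, jj - 1])
      state <- names(prevs)[which(abs(prevs - (M[ii, jj] - sub)) < 1e-9)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      gaps <- gaps + 1L
      state <- if (abs(X[ii, jj] - (M[ii, jj - 1] + go)) < 1e-9) "M" else "X"
      j <- j - 1
    } else {                               # Y: spacer base against gap
      gaps <- gaps + 1L
      state <- if (abs(Y[ii, jj] - (M[ii - 1, jj] + go)) < 1e-9) "M" else "Y"
      i <- i - 1
    }
  }
  # j is now the number of window columns preceding the aligned span
  list(score = best, identity = matches / m, matches = matches,
       gaps = gaps, start = as.integer(j), end = as.integer(end0))
}

# split a spacer into `pieces` contiguous chunks; returns 0-based offsets
# and the chunk strings.  Pigeonhole: an alignment with < `pieces` edit
# operations leaves at least one chunk exactly conserved.
spacer_pieces <- function(spacer, pieces) {
  m <- nchar(spacer)
  bounds <- unique(round(seq(0, m, length.out = pieces + 1)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  list(offset = starts,
       piece = substring(spacer, starts + 1, ends))
}

# scan one strand-oriented sequence for one spacer; returns hits with
# 0-based half-open coords on that sequence.
scan_one <- function(spacer, seqchars, min_identity, max_gaps) {
  m <- nchar(spacer)
  L <- nchar(seqchars)
  if (m > L) return(NULL)
  matches_min <- ceiling(min_identity * m - 1e-9)
  mm_budget <- m - matches_min
  pieces <- mm_budget + max_gaps + 1L
  pc <- spacer_pieces(spacer, pieces)
  subj <- Biostrings::DNAString(seqchars)
  w0 <- integer(0)
  for (t in seq_along(pc$piece)) {
    hits <- Biostrings::matchPattern(pc$piece[t], subj)
    p <- BiocGenerics::start(hits) - 1L          # 0-based seed position
    if (length(p))
      w0 <- c(w0, p - pc$offset[t] - max_gaps)
  }
  if (!length(w0)) return(NULL)
  w0 <- sort(unique(pmax(w0, 0L)))
  wlen <- m + 2L * max_gaps
  out <- vector("list", length(w0))
  for (k in seq_along(w0)) {
    a <- w0[k]
    b <- min(a + wlen, L)
    if (b - a < m) a <- max(0L, b - m)
    al <- align_spacer(spacer, substr(seqchars, a + 1, b))
    if (al$identity >= min_identity - 1e-12 && al$gaps <= max_gaps) {
      out[[k]] <- data.frame(start = a + al$start, end = a + al$end,
                             score = al$score, identity = al$identity,
                             matches = al$matches, gaps = al$gaps)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

#' Find protospacer candidates for a set of CRISPR loci
#'
#' Scans every target on both strands for windows matching each spacer at or
#' above `min_identity` (identity anchored to spacer length), using exact
#' k-mer seeding with full dynamic-programming verification so that no hit
#' within the mismatch/gap budget is missed.  Overlapping hits of the same
#' spacer on the same target are reduced to the best-scoring span (ties:
#' leftmost, then `+` strand).
#'
#' @param loci a [crispr_locus] or list of them.
#' @param targets a [seq_records] table of DNA targets.
#' @param min_identity minimum `matches / spacer_length` (default 0.90).
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @param max_gaps maximum gap columns admitted in a hit (default 2).
#' @param mask optional data frame (`target_id`, `start`, `end`; 0-based
#'   half-open) of intervals — e.g. the host's own CRISPR arrays — whose
#'   overlapping hits are discarded.
#' @param target_metadata optional data frame (`target_id`, `class`) used to
#'   label hits via [classify_source()].
#' @return a data frame of hits sorted by (`target_id`, `start`): columns
#'   `locus_id`, `spacer_id`, `target_id`, `start`, `end`, `strand`,
#'   `identity`, `matches`, `gaps`, `score`, `protospacer_seq`,
#'   `source_class`.
#' @export
find_protospacers <- function(loci, targets, min_identity = 0.90,
                              both_strands = TRUE, max_gaps = 2L,
                              mask = NULL, target_metadata = NULL) {
  if (inherits(loci, "crispr_locus")) loci <- list(loci)
  if (!length(loci) || !sum(lengths(lapply(loci, `[[`, "spacers"))))
    stop("no spacers supplied", call. = FALSE)
  empty <- data.frame(locus_id = character(), spacer_id = character(),
                      target_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = double(), matches = integer(),
                      gaps = integer(), score = double(),
                      protospacer_seq = character(),
                      source_class = character(), stringsAsFactors = FALSE)
  if (is.null(targets) || nrow(targets) == 0) {
    warning("empty target set: no protospacers to find", call. = FALSE)
    return(empty)
  }
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (ti in seq_len(nrow(targets))) {
    tid <- targets$id[ti]
    fwd <- targets$residues[ti]
    L <- nchar(fwd)
    rev <- if (both_strands) revcomp(fwd) else NULL
    for (lc in loci) {
      for (si in seq_along(lc$spacers)) {
        sp <- unname(lc$spacers[si]); sid <- names(lc$spacers)[si]
        for (std in strands) {
          sq <- if (std == "+") fwd else rev
          h <- scan_one(sp, sq, min_identity, max_gaps)
          if (is.null(h)) next
          if (std == "-") {
            ps <- substring(sq, h$start + 1, h$end)
            tmp <- L - h$end
            h$end <- L - h$start
            h$start <- tmp
          } else {
            ps <- substring(sq, h$start + 1, h$end)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            locus_id = lc$locus_id, spacer_id = sid, target_id = tid,
            start = as.integer(h$start), end = as.integer(h$end),
            strand = std, identity = h$identity,
            matches = as.integer(h$matches), gaps = as.integer(h$gaps),
            score = h$score, protospacer_seq = ps,
            source_class = "unknown", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  hits <- dedupe_hits_overlap(hits)
  if (!is.null(mask) && nrow(mask)) {
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      mi <- mask[mask$target_id == hits$target_id[i], , drop = FALSE]
      !any(hits$start[i] < mi$end & hits$end[i] > mi$start)
    }, TRUE)
    hits <- hits[keep, , drop = FALSE]
  }
  if (!is.null(target_metadata)) hits <- classify_source(hits, target_metadata)
  hits <- hits[order(hits$target_id, hits$start, hits$spacer_id,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# collapse overlapping hits of the same (locus, spacer, target): greedily
# accept the best-scoring span (ties -> smallest start, smallest end, "+"
# strand first) and discard spans overlapping an accepted one.
dedupe_hits_overlap <- function(hits) {
  key <- paste(hits$locus_id, hits$spacer_id, hits$target_id, sep = "\r")
  sel <- integer(0)
  for (grp in split(seq_len(nrow(hits)), key)) {
    sub <- hits[grp, , drop = FALSE]
    o <- order(-sub$score, sub$start, sub$end, sub$strand)
    chosen <- integer(0)
    for (k in o) {
      if (!length(chosen) ||
          !any(sub$start[k] < sub$end[chosen] &
               sub$end[k] > sub$start[chosen]))
        chosen <- c(chosen, k)
    }
    sel <- c(sel, grp[chosen])
  }
  hits[sort(sel), , drop = FALSE]
}

#' Label hits by the declared class of their target
#'
#' Targets are declared `phage`, `plasmid` or `genome` in a metadata table;
#' undeclared targets fall back to `unknown`.  Genome-class hits are kept —
#' chromosomal protospacers can carry a deviant flank that distinguishes
#' self from invader — but a message reports how many there are.
#'
#' @param hits data frame from [find_protospacers()].
#' @param target_metadata data frame with columns `target_id`, `class`.
#' @return `hits` with `source_class` filled in.
#' @export
classify_source <- function(hits, target_metadata) {
  stopifnot(all(c("target_id", "class") %in% names(target_metadata)))
  cls <- target_metadata$class[match(hits$target_id,
                                     target_metadata$target_id)]
  cls[is.na(cls)] <- "unknown"
  bad <- !cls %in% c("phage", "plasmid", "genome", "unknown")
  if (any(bad)) cls[bad] <- "unknown"
  hits$source_class <- cls
  ng <- sum(cls == "genome")
  if (ng) message(ng, " hit(s) lie on genome-class targets; ",
                  "their flanks may reflect self-protective PAM mutation")
  hits
}

#' Convert hits to a GRanges object
#'
#' @param hits data frame from [find_protospacers()].
#' @return a [GenomicRanges::GRanges] with hit statistics as metadata
#'   columns (1-based coordinates).
#' @export
hits_to_granges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$target_id,
    ranges = IRanges::IRanges(hits$start + 1L, hits$end),
    strand = hits$strand,
    spacer_id = hits$spacer_id, locus_id = hits$locus_id,
    identity = hits$identity, matches = hits$matches, gaps = hits$gaps,
    source_class = hits$source_class)
}

#' Write hits as BED6
#'
#' `name` is the spacer id and `score` is `round(identity * 1000)`.
#'
#' @param hits data frame from [find_protospacers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$target_id, hits$start, hits$end, hits$spacer_id,
                    round(hits$identity * 1000), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write hits as GFF3
#'
#' 1-based coordinates; identity, gap count and source class are carried in
#' the attribute column.
#'
#' @param hits data frame from [find_protospacers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    attrs <- sprintf(
      "ID=hit%d;spacer_id=%s;locus_id=%s;identity=%.4f;gaps=%d;source_class=%s",
      seq_len(nrow(hits)), hits$spacer_id, hits$locus_id, hits$identity,
      hits$gaps, hits$source_class)
    lines <- paste(hits$target_id, "crispam", "protospacer",
                   hits$start + 1L, hits$end,
                   sprintf("%.4f", hits$identity), hits$strand, ".",
                   attrs, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
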