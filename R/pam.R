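#' Extract the 3' flank of a protospacer hit on the non-target strand
#'
#' The PAM for type II systems sits immediately 3' of the protospacer on the
#' non-target strand — the strand carrying the spacer sequence itself.  For a
#' `+` hit ending at `e` (0-based half-open) this is `target[e, e + len)`;
#' for a `-` hit starting at `s` it is the reverse complement of
#' `target[s - len, s)`.
#'
#' @param hit one hit (single-row data frame or list) from
#'   [find_protospacers()].
#' @param target the matching [seq_records] row.
#' @param flank_len flank width in nt (default 10).
#' @return the flank string, or `NA_character_` (with a warning) when fewer
#'   than `flank_len` bases remain on the contig.
#' @export
extract_flank <- function(hit, target, flank_len = 10L) {
  if (hit$target_id[1] != target$id[1])
    stop("hit refers to target '", hit$target_id[1], "', not '",
         target$id[1], "'", call. = FALSE)
  seq <- target$residues[1]
  L <- nchar(seq)
  if (hit$strand[1] == "+") {
    e <- hit$end[1]
    if (e + flank_len > L) {
      warning("hit at [", hit$start[1], ",", e, ") on '", target$id[1],
              "': fewer than ", flank_len, " bases 3' of the protospacer",
              call. = FALSE)
      return(NA_character_)
    }
    substr(seq, e + 1L, e + flank_len)
  } else {
    s <- hit$start[1]
    if (s - flank_len < 0) {
      warning("hit at [", s, ",", hit$end[1], ") on '", target$id[1],
              "': fewer than ", flank_len, " bases 3' of the protospacer",
              call. = FALSE)
      return(NA_character_)
    }
    revcomp(substr(seq, s - flank_len + 1L, s))
  }
}

#' Extract flanks for a whole hit table
#'
#' @param hits data frame from [find_protospacers()].
#' @param targets [seq_records] table containing every `target_id`.
#' @param flank_len flank width in nt.
#' @param dedupe drop duplicated (protospacer, flank) pairs so that the same
#'   protospacer inherited by near-identical phages is counted once
#'   (default `TRUE`).
#' @return `hits` with a `flank` column added; rows whose flank is
#'   unavailable (contig edge) or duplicated are removed.
#' @export
collect_flanks <- function(hits, targets, flank_len = 10L, dedupe = TRUE) {
  if (!nrow(hits)) {
    hits$flank <- character(0)
    return(hits)
  }
  fl <- vapply(seq_len(nrow(hits)), function(i) {
    trow <- targets[targets$id == hits$target_id[i], , drop = FALSE]
    if (!nrow(trow))
      stop("hit refers to unknown target '", hits$target_id[i], "'",
           call. = FALSE)
    extract_flank(hits[i, , drop = FALSE], trow, flank_len)
  }, character(1))
  hits$flank <- fl
  hits <- hits[!is.na(fl), , drop = FALSE]
  if (dedupe && nrow(hits)) {
    key <- paste(hits$protospacer_seq, hits$flank, sep = "\r")
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Build a position frequency matrix from fixed-width flanks
#'
#' Flanks are stacked positionally (they are fixed-width, so alignment is
#' trivial).  Ambiguous bases are excluded from the counts and tallied in
#' `skipped`, so that for every position `sum(counts) + skipped == n`.
#'
#' @param flanks character vector of flank strings, all of length `width`.
#' @param width motif width (default 10).
#' @return an object of class `pam_pfm`: list with `width`, `counts`
#'   (`width` x 4 matrix over A,C,G,T), `skipped` (per position) and `n`.
#' @export
build_pfm <- function(flanks, width = 10L) {
  flanks <- toupper(flanks)
  if (!length(flanks))
    stop("no flanks: no protospacers found ",
         "(consider adding targets from closely related strains)",
         call. = FALSE)
  if (any(nchar(flanks) != width))
    stop("all flanks must have length ", width, call. = FALSE)
  mat <- do.call(rbind, strsplit(flanks, ""))
  counts <- matrix(0L, width, 4, dimnames = list(NULL, DNA_STRICT))
  skipped <- integer(width)
  for (p in seq_len(width)) {
    tab <- table(factor(mat[, p], levels = DNA_STRICT))
    counts[p, ] <- as.integer(tab)
    skipped[p] <- length(flanks) - sum(tab)
  }
  structure(list(width = as.integer(width), counts = counts,
                 skipped = skipped, n = length(flanks)),
            class = "pam_pfm")
}

# per-position base fractions over usable (unambiguous) counts
pfm_freqs <- function(pfm) {
  tot <- rowSums(pfm$counts)
  f <- pfm$counts / ifelse(tot > 0, tot, 1)
  f[tot == 0, ] <- 0
  f
}

#' Per-position information content (bits)
#'
#' `IC = 2 - H`, with `H` the base-2 Shannon entropy of the position's base
#' fractions.  Positions with no usable counts get `IC = 0` with a warning.
#'
#' @param pfm a [build_pfm()] object.
#' @param small_sample_correction subtract the Schneider small-sample
#'   correction `3 / (2 ln 2 n)` (floored at 0).  Off by default: with the
#'   small protospacer counts typical of this analysis the correction can
#'   zero out weak but real signals.
#' @return numeric vector of length `width`, entries in `[0, 2]`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  f <- pfm_freqs(pfm)
  tot <- rowSums(pfm$counts)
  h <- apply(f, 1, function(p) {
    p <- p[p > 0]
    if (!length(p)) 2 else -sum(p * log2(p))
  })
  ic <- 2 - h
  if (any(tot == 0)) {
    warning("position(s) with zero usable counts: IC set to 0",
            call. = FALSE)
    ic[tot == 0] <- 0
  }
  if (small_sample_correction) {
    e <- 3 / (2 * log(2) * pmax(tot, 1))
    ic <- pmax(ic - e, 0)
  }
  ic
}

# IUPAC letter for a set of bases
iupac_letter <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(iupac_sets)[vapply(iupac_sets, function(s)
    paste(sort(s), collapse = "") == key, TRUE)]
  if (!length(hit)) stop("no IUPAC letter for base set ", key, call. = FALSE)
  hit[1]
}

#' Call a degenerate IUPAC consensus from a PFM
#'
#' Per position, bases are added in descending frequency until their
#' cumulative fraction reaches `coverage`; frequency ties are included
#' together (so a 50/50 A/C position yields `M`, surfacing ambiguity rather
#' than hiding it).  A four-base set prints `N`.
#'
#' @param pfm a [build_pfm()] object.
#' @param coverage cumulative-frequency threshold in (0, 1] (default 0.8).
#' @param min_support refuse to call a consensus from fewer than this many
#'   flanks (default 3; set to 0 to disable).  With too few protospacers the
#'   sensible remedy is pooling targets from closely related strains.
#' @return IUPAC string of length `width`.
#' @export
call_consensus <- function(pfm, coverage = 0.8, min_support = 3L) {
  if (pfm$n < min_support)
    stop("only ", pfm$n, " flank(s) support this profile (min_support = ",
         min_support, "); pool closely related strains or add targets",
         call. = FALSE)
  f <- pfm_freqs(pfm)
  tot <- rowSums(pfm$counts)
  letters <- character(pfm$width)
  for (p in seq_len(pfm$width)) {
    if (tot[p] == 0) {
      warning("position ", p, " has no usable counts: consensus 'N'",
              call. = FALSE)
      letters[p] <- "N"
      next
    }
    fr <- sort(f[p, f[p, ] > 0], decreasing = TRUE)
    cum <- cumsum(fr)
    k <- which(cum >= coverage - 1e-12)[1]
    # include all bases tied with the last one admitted
    k <- max(which(abs(fr - fr[k]) < 1e-12))
    letters[p] <- iupac_letter(names(fr)[seq_len(k)])
  }
  paste(letters, collapse = "")
}

#' Assemble a PAM profile (consensus + logo data) from a PFM
#'
#' @param pfm a [build_pfm()] object.
#' @param coverage consensus coverage threshold, see [call_consensus()].
#' @param min_support minimum flank support, see [call_consensus()].
#' @param small_sample_correction see [information_content()].
#' @param label optional partition label (e.g. a source class or strain
#'   group).
#' @return object of class `pam_profile`: `consensus`, `ic`, `freqs`, `n`,
#'   `partition_label`, plus the underlying `pfm`.
#' @export
pam_profile <- function(pfm, coverage = 0.8, min_support = 3L,
                        small_sample_correction = FALSE, label = NULL) {
  structure(list(
    consensus = call_consensus(pfm, coverage, min_support),
    ic = information_content(pfm, small_sample_correction),
    freqs = pfm_freqs(pfm),
    n = pfm$n,
    partition_label = label,
    pfm = pfm), class = "pam_profile")
}

#' @export
print.pam_profile <- function(x, ...) {
  cat("PAM profile", if (!is.null(x$partition_label))
    paste0(" [", x$partition_label, "]"), "\n",
      "  consensus: ", x$consensus, "  (n = ", x$n, ")\n",
      "  IC (bits): ", paste(sprintf("%.2f", x$ic), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' One PAM profile per source class
#'
#' Splits classified hits by `source_class` and profiles each class with at
#' least one usable flank separately — e.g. to contrast a phage-derived PAM
#' with a mutated chromosomal one.
#'
#' @param hits classified hits (see [classify_source()]).
#' @param targets [seq_records] table of targets.
#' @param flank_len flank width.
#' @param coverage,min_support,dedupe passed through.
#' @return named list of `pam_profile` objects, one per source class.
#' @export
partition_by_source <- function(hits, targets, flank_len = 10L,
                                coverage = 0.8, min_support = 3L,
                                dedupe = TRUE) {
  hf <- collect_flanks(hits, targets, flank_len, dedupe = dedupe)
  out <- list()
  for (cls in sort(unique(hf$source_class))) {
    fl <- hf$flank[hf$source_class == cls]
    if (!length(fl)) next
    pfm <- build_pfm(fl, flank_len)
    out[[cls]] <- pam_profile(pfm, coverage, min_support, label = cls)
  }
  out
}

#' Sequence-logo data for a PFM
#'
#' Letter heights follow the standard logo convention
#' `height = freq * IC(position)`, so per-position heights sum to the
#' position's information content.
#'
#' @param pfm a [build_pfm()] object.
#' @param small_sample_correction see [information_content()].
#' @return data frame with columns `position`, `base`, `height`.
#' @export
export_logo_data <- function(pfm, small_sample_correction = FALSE) {
  f <- pfm_freqs(pfm)
  ic <- suppressWarnings(information_content(pfm, small_sample_correction))
  data.frame(
    position = rep(seq_len(pfm$width), each = 4L),
    base = rep(DNA_STRICT, pfm$width),
    height = as.vector(t(f * ic)),
    stringsAsFactors = FALSE)
}

#' Write a PFM (counts, skipped, frequencies) as TSV
#'
#' @param pfm a [build_pfm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  f <- pfm_freqs(pfm)
  tab <- data.frame(position = seq_len(pfm$width), pfm$counts,
                    skipped = pfm$skipped,
                    freq_A = f[, "A"], freq_C = f[, "C"],
                    freq_G = f[, "G"], freq_T = f[, "T"])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PAM profile as JSON
#'
#' @param profile a [pam_profile()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(list(
    consensus = profile$consensus,
    n = profile$n,
    partition_label = profile$partition_label,
    ic = profile$ic,
    freqs = as.data.frame(profile$freqs)), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
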