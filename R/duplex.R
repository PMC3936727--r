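# base-pair weight lookup: canonical + wobble, otherwise mismatch
duplex_pair_weight <- function(x, y, weights) {
  key <- paste(sort(c(x, y)), collapse = "")
  switch(key, "CG" = weights[["GC"]], "AU" = weights[["AU"]],
         "GU" = weights[["GU"]], NA_real_)
}

#' Score a repeat:anti-repeat RNA duplex
#'
#' Maximum-scoring antiparallel inter-strand alignment under simple
#' base-pair weights (`GC = 3`, `AU = 2`, `GU = 1` by default), a per-base
#' gap penalty and a mismatch penalty, computed by local dynamic
#' programming (strand 1 against the reverse of strand 2).  Intra-strand
#' structure is ignored and the score is not energy-calibrated: this is a
#' transparent device for comparing the extent of repeat:anti-repeat
#' pairing across loci, not a thermodynamic folding.
#'
#' The empty duplex is admissible, so the score is never negative.
#'
#' @param strand1,strand2 RNA strings over A/C/G/U, each written 5' to 3'
#'   (DNA input is converted `T` to `U` with a warning).
#' @param weights named vector of pair weights (`GC`, `AU`, `GU`).
#' @param gap_penalty score per unpaired-bulge base inside the duplex
#'   (default -2).
#' @param mismatch_penalty score per opposed non-pairing base pair inside
#'   the duplex (default -1).
#' @return object of class `duplex_alignment`: `pairs` (data frame `i`,
#'   `j`, `type` of 1-based paired positions, `i` increasing, `j`
#'   decreasing), `score`, and `structure` (dot-bracket strings for both
#'   strands).
#' @export
hybridize <- function(strand1, strand2,
                      weights = c(GC = 3, AU = 2, GU = 1),
                      gap_penalty = -2, mismatch_penalty = -1) {
  norm <- function(x, nm) {
    x <- toupper(x)
    if (grepl("T", x, fixed = TRUE)) {
      warning("DNA letters in ", nm, ": converting T to U", call. = FALSE)
      x <- gsub("T", "U", x, fixed = TRUE)
    }
    if (grepl("[^ACGU]", x))
      stop(nm, " must be RNA over A/C/G/U", call. = FALSE)
    if (nchar(x) < 1 || nchar(x) > 200)
      stop(nm, " must have length 1-200", call. = FALSE)
    x
  }
  s1 <- strsplit(norm(strand1, "strand1"), "")[[1]]
  s2 <- strsplit(norm(strand2, "strand2"), "")[[1]]
  n <- length(s1); m <- length(s2)
  r2 <- rev(s2)                       # align s1 against reversed strand 2
  S <- matrix(0, n + 1, m + 1)        # local: floor at 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      w <- duplex_pair_weight(s1[i], r2[j], weights)
      diag <- S[i, j] + if (is.na(w)) mismatch_penalty else w
      S[i + 1, j + 1] <- max(0, diag, S[i, j + 1] + gap_penalty,
                             S[i + 1, j] + gap_penalty)
    }
  }
  best <- max(S)
  idx <- which(S == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]  # leftmost end
  pairs <- list()
  i <- idx[1] - 1L; j <- idx[2] - 1L
  if (best > 0) {
    while (i > 0 && j > 0 && S[i + 1, j + 1] > 0) {
      w <- duplex_pair_weight(s1[i], r2[j], weights)
      step <- S[i, j] + if (is.na(w)) mismatch_penalty else w
      if (abs(S[i + 1, j + 1] - step) < 1e-9) {
        if (!is.na(w))
          pairs[[length(pairs) + 1L]] <- data.frame(
            i = i, j = m - j + 1L,
            type = paste0(s1[i], ":", r2[j]), stringsAsFactors = FALSE)
        i <- i - 1L; j <- j - 1L
      } else if (abs(S[i + 1, j + 1] - (S[i, j + 1] + gap_penalty)) < 1e-9) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, rev(pairs)) else
    data.frame(i = integer(), j = integer(), type = character(),
               stringsAsFactors = FALSE)
  db1 <- rep(".", n); db2 <- rep(".", m)
  db1[pairs$i] <- "("; db2[pairs$j] <- ")"
  structure(list(pairs = pairs, score = best,
                 structure = list(strand1 = paste(db1, collapse = ""),
                                  strand2 = paste(db2, collapse = ""))),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex alignment: score ", x$score, ", ", nrow(x$pairs),
      " base pair(s)\n", sep = "")
  cat(" 5'-", x$structure$strand1, "-3'\n", sep = "")
  cat(" 3'-", paste(rev(strsplit(x$structure$strand2, "")[[1]]),
                    collapse = ""), "-5'\n", sep = "")
  invisible(x)
}

#' Write a duplex alignment as JSON
#'
#' @param dup a [hybridize()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_duplex_json <- function(dup, path) {
  jsonlite::write_json(list(score = dup$score, pairs = dup$pairs,
                            structure = dup$structure),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
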