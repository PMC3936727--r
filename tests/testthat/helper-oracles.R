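# Independent reference implementations used as oracles.  Each is written
# as directly as possible (exhaustive enumeration / textbook DP) and stays
# separate from the package's optimized code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")
rand_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                    n, replace = TRUE), collapse = "")

# ---- exhaustive semi-global alignment score (spacer fully aligned, free
# window overhangs, affine gaps) by recursive enumeration of alignments ----
oracle_semiglobal_score <- function(spacer, window, match = 1,
                                    mismatch = -2, gap_open = -5,
                                    gap_extend = -2) {
  s <- strsplit(spacer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  m <- length(s); n <- length(w)
  best <- -Inf
  rec <- function(i, j, sc, prev) {
    if (i > m) { best <<- max(best, sc); return(invisible(NULL)) }
    if (j <= n) {
      sub <- if (s[i] == w[j]) match else mismatch
      rec(i + 1, j + 1, sc + sub, "M")
      pen <- if (prev == "X") gap_extend else gap_open + gap_extend
      rec(i, j + 1, sc + pen, "X")
    }
    pen <- if (prev == "Y") gap_extend else gap_open + gap_extend
    rec(i + 1, j, sc + pen, "Y")
  }
  for (st in 0:n) rec(1, st + 1, 0, "M")   # free leading overhang
  best
}

# ---- exhaustive sliding-window protospacer scan; reuses the package DP
# per window but replaces seeding, strand handling and deduplication with
# plain enumeration ----
oracle_find_protospacers <- function(locus, targets, min_identity = 0.90,
                                     max_gaps = 2L) {
  rows <- list()
  for (ti in seq_len(nrow(targets))) {
    fwd <- targets$residues[ti]
    L <- nchar(fwd)
    for (si in seq_along(locus$spacers)) {
      sp <- unname(locus$spacers[si])
      m <- nchar(sp)
      wlen <- m + 2L * max_gaps
      for (std in c("+", "-")) {
        sq <- if (std == "+") fwd else revcomp(fwd)
        if (m > L) next
        for (a in 0:(L - m)) {
          b <- min(a + wlen, L)
          al <- align_spacer(sp, substr(sq, a + 1, b))
          if (al$identity >= min_identity - 1e-12 && al$gaps <= max_gaps) {
            st0 <- a + al$start; en0 <- a + al$end
            if (std == "-") { tmp <- L - en0; en0 <- L - st0; st0 <- tmp }
            rows[[length(rows) + 1L]] <- data.frame(
              spacer_id = names(locus$spacers)[si], target_id = targets$id[ti],
              start = st0, end = en0, strand = std, score = al$score,
              identity = al$identity, matches = al$matches, gaps = al$gaps,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(spacer_id = character(), target_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = double(),
                      identity = double(), matches = integer(),
                      gaps = integer(), stringsAsFactors = FALSE))
  hits <- unique(do.call(rbind, rows))
  # greedy best-first overlap resolution, coded flat
  out <- list()
  for (key in unique(paste(hits$spacer_id, hits$target_id))) {
    sub <- hits[paste(hits$spacer_id, hits$target_id) == key, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$start, sub$end, sub$strand), ,
               drop = FALSE]
    acc <- sub[0, ]
    for (r in seq_len(nrow(sub))) {
      olap <- acc$start < sub$end[r] & acc$end > sub$start[r]
      if (!any(olap)) acc <- rbind(acc, sub[r, ])
    }
    out[[key]] <- acc
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$target_id, hits$start, hits$spacer_id,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# ---- textbook Smith-Waterman with affine gaps (gap of length L costs
# open + L * extend); returns the maximum local score ----
oracle_smith_waterman <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             E[i + 1, j] - gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             F[i, j + 1] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + mat[A[i], B[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# ---- connected components by union-find over an explicit edge list ----
oracle_components <- function(ids, edges_a, edges_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  unname(lapply(split(ids, roots), sort))
}

# partitions as canonical strings for comparison
canonical_partition <- function(clusters) {
  paste(sort(vapply(clusters, function(cl)
    paste(sort(cl), collapse = ","), "")), collapse = ";")
}

# TRUE iff partition `fine` refines `coarse` (every fine cluster inside
# one coarse cluster)
is_refinement <- function(fine, coarse) {
  all(vapply(fine, function(cl) {
    any(vapply(coarse, function(cc) all(cl %in% cc), TRUE))
  }, TRUE))
}

# ---- duplex oracle: enumerate every monotone pair set (i increasing, j
# decreasing, all couples complementary); interior between consecutive
# pairs scores min(a,b) mismatches + |a-b| gap bases, ends are free ----
oracle_duplex_score <- function(s1, s2, weights = c(GC = 3, AU = 2, GU = 1),
                                gap_penalty = -2, mismatch_penalty = -1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  pw <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "")
    switch(key, "CG" = weights[["GC"]], "AU" = weights[["AU"]],
           "GU" = weights[["GU"]], NA_real_)
  }
  best <- 0
  for (k in seq_len(min(n, m))) {
    ci <- utils::combn(n, k)
    cj <- utils::combn(m, k)
    for (ii in seq_len(ncol(ci))) {
      I <- ci[, ii]
      for (jj in seq_len(ncol(cj))) {
        J <- rev(cj[, jj])                     # j strictly decreasing
        w <- mapply(function(x, y) pw(a[x], b[y]), I, J)
        if (anyNA(w)) next
        sc <- sum(w)
        if (k > 1) {
          di <- I[-1] - I[-k] - 1L
          dj <- J[-k] - J[-1] - 1L
          sc <- sc + sum(pmin(di, dj) * mismatch_penalty +
                           abs(di - dj) * gap_penalty)
        }
        best <- max(best, sc)
      }
    }
  }
  best
}

# ---- random additive distance matrix from a random unrooted tree ----
random_additive_matrix <- function(nleaf) {
  tr <- ape::rtree(nleaf, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(nleaf))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# ---- monophyly by graph cut: for each edge of the tree, delete it and
# compare the tip component against the group ----
oracle_monophyly <- function(tree, group) {
  ntip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(
    apply(tree$edge, 2, as.character), directed = FALSE)
  grp <- sort(unique(group))
  if (length(grp) == 1 || length(grp) == ntip) return(TRUE)
  tipv <- as.character(seq_len(ntip))
  for (e in seq_len(nrow(tree$edge))) {
    cut <- igraph::delete_edges(g, e)
    comp <- igraph::components(cut)$membership
    side <- tree$tip.label[as.integer(
      intersect(names(comp)[comp == comp[[tipv[1]]]], tipv))]
    if (identical(sort(side), grp) ||
        identical(sort(setdiff(tree$tip.label, side)), grp))
      return(TRUE)
  }
  FALSE
}
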