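#' Read an aligned FASTA into an alignment matrix
#'
#' @param path path to an aligned (gapped) FASTA file.
#' @return character matrix, one row per sequence (rownames = ids), one
#'   column per alignment column; gap character `-`.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path, moltype = "protein")
  as_alignment(stats::setNames(recs$residues, recs$id))
}

#' Coerce named gapped strings to an alignment matrix
#'
#' @param x named character vector of equal-length gapped sequences.
#' @return character matrix with sequence ids as rownames.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(unique(nchar(x))) != 1)
    stop("alignment rows differ in length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

#' Select informative alignment columns
#'
#' Keeps columns whose gap fraction is at most `max_gap_fraction` and (when
#' `require_variation`) that carry at least two distinct non-gap residues.
#' This is a declared approximation to curated "confidently aligned blocks":
#' thresholds are exposed, and no claim is made of reproducing any
#' particular curated column count.
#'
#' @param alignment alignment matrix (see [as_alignment()]).
#' @param max_gap_fraction maximum tolerated gap fraction per column.
#' @param require_variation require >= 2 distinct non-gap residues.
#' @return list with `alignment` (kept columns) and `kept` (1-based column
#'   indices, for audit).
#' @export
select_informative_columns <- function(alignment, max_gap_fraction = 0.5,
                                       require_variation = TRUE) {
  alignment <- as_alignment(alignment)
  keep <- vapply(seq_len(ncol(alignment)), function(j) {
    col <- alignment[, j]
    gapf <- mean(col == "-")
    if (gapf > max_gap_fraction) return(FALSE)
    if (require_variation && length(unique(col[col != "-"])) < 2)
      return(FALSE)
    TRUE
  }, TRUE)
  if (!any(keep))
    stop("no informative columns retained; relax max_gap_fraction or ",
         "disable require_variation", call. = FALSE)
  list(alignment = alignment[, keep, drop = FALSE], kept = which(keep))
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance with pairwise deletion (mismatches over compared non-gap
#' columns), optionally Poisson-corrected (`d = -ln(1 - p)`).  `p` is capped
#' just below 1 (with a warning) to keep the correction finite.
#'
#' @param alignment alignment matrix or named gapped strings.
#' @param model `"poisson"` (default) or `"p"` for the raw p-distance.
#' @return symmetric numeric matrix with zero diagonal, labeled by sequence
#'   id.
#' @export
distance_matrix <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  aln <- as_alignment(alignment)
  n <- nrow(aln)
  if (n < 3) stop("need at least 3 sequences", call. = FALSE)
  labs <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      if (!any(ok))
        stop("no comparable positions between '", labs[i], "' and '",
             labs[j], "'", call. = FALSE)
      p <- mean(aln[i, ok] != aln[j, ok])
      if (model == "poisson") {
        if (p > 0.99) {
          warning("p-distance ", sprintf("%.3f", p), " between '", labs[i],
                  "' and '", labs[j], "' capped at 0.99 for the Poisson ",
                  "correction", call. = FALSE)
          p <- 0.99
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]).  Labels are
#' sorted lexicographically before the join so that identical matrices give
#' byte-identical newick strings regardless of input order; negative branch
#' lengths are clamped to 0.
#'
#' @param dm symmetric non-negative matrix with zero diagonal (labelled).
#' @return an unrooted [ape] `phylo` object.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix must be labelled",
                                  call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(dm < -1e-12) ||
      any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must be symmetric, non-negative, with zero ",
         "diagonal", call. = FALSE)
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Column-bootstrap supports on a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree for each replicate, and maps per-bipartition frequencies onto the
#' point-estimate tree (stored in `node.label` as fractions in `[0, 1]`).
#'
#' @param alignment alignment matrix or named gapped strings.
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed; the resampling is deterministic given it.
#' @param model distance model, see [distance_matrix()].
#' @return list with `tree` (point estimate, `node.label` = supports),
#'   `replicates` (list of replicate trees) and `B`.
#' @export
bootstrap_support <- function(alignment, B = 100L, seed = 1L,
                              model = "poisson") {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  aln <- as_alignment(alignment)
  point <- nj_tree(distance_matrix(aln, model))
  reps <- with_seed(seed, lapply(seq_len(B), function(b) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    nj_tree(distance_matrix(aln[, cols, drop = FALSE], model))
  }))
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- counts / B
  list(tree = point, replicates = reps, B = B)
}

# leaf-descendant sets for each internal edge of an unrooted phylo tree
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- seq_len(max(tree$edge)) [-seq_len(ntip)]
  lapply(nodes, function(nd) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    sort(tips)
  })
}

#' Test unrooted monophyly of a leaf group
#'
#' `TRUE` iff some edge bipartition separates exactly `group` from the other
#' leaves.  Singletons and the full leaf set are monophyletic by convention
#' (leaf edge / trivial bipartition).
#'
#' @param tree a `phylo` object.
#' @param group character vector of leaf labels.
#' @return logical.
#' @export
check_monophyly <- function(tree, group) {
  tips <- tree$tip.label
  if (!length(group)) stop("empty group", call. = FALSE)
  unknown <- setdiff(group, tips)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  group <- sort(unique(group))
  # leaf edges realize the singleton|rest bipartitions; the full set is the
  # trivial bipartition
  if (length(group) <= 1 || length(group) >= length(tips) - 1) return(TRUE)
  comp <- sort(setdiff(tips, group))
  for (s in tree_splits(tree)) {
    if (identical(s, group) || identical(s, comp)) return(TRUE)
    other <- sort(setdiff(tips, s))
    if (identical(other, group)) return(TRUE)
  }
  FALSE
}

#' Fraction of replicate trees in which a group is monophyletic
#'
#' A direct support measure for one labelled group (e.g. a cluster or a
#' subtype) under the bootstrap.
#'
#' @param replicates list of `phylo` trees (e.g. from
#'   [bootstrap_support()]).
#' @param group character vector of leaf labels.
#' @return fraction in `[0, 1]`.
#' @export
split_support <- function(replicates, group) {
  mean(vapply(replicates, check_monophyly, TRUE, group = group))
}

#' Monophyly verdicts for every cluster of a cluster set
#'
#' @param tree a `phylo` object whose tips are sequence ids.
#' @param cs a [greedy_cluster()] result (clusters over the same ids).
#' @param replicates optional replicate trees for bootstrap support.
#' @return data frame: `cluster_id`, `size`, `monophyletic`, and `support`
#'   when replicates are given.
#' @export
clade_concordance <- function(tree, cs, replicates = NULL) {
  out <- data.frame(
    cluster_id = seq_along(cs$clusters),
    size = lengths(cs$clusters),
    monophyletic = vapply(cs$clusters, function(g)
      check_monophyly(tree, intersect(g, tree$tip.label)), TRUE))
  if (!is.null(replicates))
    out$support <- vapply(cs$clusters, function(g)
      split_support(replicates, intersect(g, tree$tip.label)), 0)
  out
}

#' Write a tree as newick
#'
#' @param tree a `phylo` object (node labels, if present, are written as
#'   supports).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
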