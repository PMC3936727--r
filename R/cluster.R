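#' Discard proteins shorter than a minimum length
#'
#' Full-length Cas9 orthologs run from roughly 900 to over 1600 amino
#' acids; an 800-aa floor removes fragments and unrelated short matches
#' before clustering.
#'
#' @param records protein [seq_records] table.
#' @param min_len minimum length in amino acids (default 800).
#' @return the retained rows, in input order; discarded ids are reported
#'   in a message.
#' @export
filter_by_length <- function(records, min_len = 800L) {
  keep <- nchar(records$residues) >= min_len
  if (any(!keep))
    message("discarded ", sum(!keep), " sequence(s) shorter than ",
            min_len, " aa: ", paste(records$id[!keep], collapse = ", "))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# BLOSUM62 with X (and *) scored 0 against everything
blosum62_x0 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      for (ch in c("X", "*")) {
        m[ch, ] <- 0L
        m[, ch] <- 0L
      }
      mat <<- m
    }
    mat
  }
})

#' Pairwise local protein alignment statistics
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1); `X` is tolerated and scored 0.  The bit score uses the gapped
#' Karlin-Altschul transformation `(lambda * S - ln K) / ln 2` with the
#' standard protein-BLAST constants `lambda = 0.267`, `K = 0.041`.
#' Coverages are the fractions of each sequence spanned by the aligned
#' region.
#'
#' @param a,b single-row protein [seq_records] (or lists with `id` and
#'   `residues`).
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @param lambda,K Karlin-Altschul constants.
#' @return one-row data frame: `id_a`, `id_b`, `raw_score`, `bit_score`,
#'   `align_len`, `cov_a`, `cov_b`, `identity`.
#' @export
align_pair <- function(a, b, gap_open = 11, gap_extend = 1,
                       lambda = 0.267, K = 0.041) {
  if (!nzchar(a$residues[1]) || !nzchar(b$residues[1]))
    stop("empty protein sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues[1]), Biostrings::AAString(b$residues[1]),
    substitutionMatrix = blosum62_x0(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  raw <- Biostrings::score(aln)
  alen <- nchar(as.character(Biostrings::pattern(aln)))
  pa <- Biostrings::pattern(aln); sb <- Biostrings::subject(aln)
  span_a <- BiocGenerics::end(pa) - BiocGenerics::start(pa) + 1L
  span_b <- BiocGenerics::end(sb) - BiocGenerics::start(sb) + 1L
  data.frame(
    id_a = a$id[1], id_b = b$id[1],
    raw_score = raw,
    bit_score = (lambda * raw - log(K)) / log(2),
    align_len = alen,
    cov_a = span_a / nchar(a$residues[1]),
    cov_b = span_b / nchar(b$residues[1]),
    identity = Biostrings::nmatch(aln) / alen,
    stringsAsFactors = FALSE)
}

#' All-vs-all pairwise alignment statistics
#'
#' @param records protein [seq_records] table.
#' @param ... passed to [align_pair()].
#' @return data frame of [align_pair()] rows for every unordered pair,
#'   suitable as an audit trail for the clustering thresholds.
#' @export
align_all <- function(records, ...) {
  n <- nrow(records)
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        rows[[length(rows) + 1L]] <-
          align_pair(records[i, ], records[j, ], ...)
      }
    }
  }
  if (!length(rows))
    return(data.frame(id_a = character(), id_b = character(),
                      raw_score = double(), bit_score = double(),
                      align_len = integer(), cov_a = double(),
                      cov_b = double(), identity = double(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Greedy single-linkage clustering under coverage thresholds
#'
#' Two sequences are linked when the alignment covers at least `length_cov`
#' of *both* sequences and the score coverage (bit score divided by
#' alignment length) is at least `score_cov`; clusters are the connected
#' components of the resulting graph.  Members are sorted within clusters;
#' clusters are sorted by size (descending), then by first member.
#'
#' @param records protein [seq_records] table (already length-filtered).
#' @param length_cov length-coverage cutoff (default 0.8).
#' @param score_cov score-coverage cutoff in bits/column (default 0.8).
#' @param edges optional precomputed [align_all()] table (to reuse an audit
#'   table instead of realigning).
#' @param ... passed to [align_all()] when `edges` is not supplied.
#' @return object of class `cluster_set`: `clusters` (list of member-id
#'   vectors), `parameters`, and the `edges` audit table.
#' @export
greedy_cluster <- function(records, length_cov = 0.8, score_cov = 0.8,
                           edges = NULL, ...) {
  if (is.null(edges)) edges <- align_all(records, ...)
  ok <- pmin(edges$cov_a, edges$cov_b) >= length_cov &
    edges$bit_score / edges$align_len >= score_cov
  g <- igraph::graph_from_data_frame(
    edges[ok, c("id_a", "id_b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = records$id))
  comp <- igraph::components(g)
  clusters <- unname(split(names(comp$membership), comp$membership))
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, "", 1))
  structure(list(clusters = clusters[ord],
                 parameters = list(length_cov = length_cov,
                                   score_cov = score_cov),
                 edges = edges),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set: ", length(x$clusters), " cluster(s) over ",
      sum(lengths(x$clusters)), " sequence(s)\n", sep = "")
  cat("  sizes:", paste(lengths(x$clusters), collapse = " "), "\n")
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param cs a [greedy_cluster()] result.
#' @return integer vector of cluster indices named by member id.
#' @export
cluster_membership <- function(cs) {
  ids <- unlist(cs$clusters)
  stats::setNames(rep(seq_along(cs$clusters), lengths(cs$clusters)), ids)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors over the same elements (matched by name when
#'   both are named).
#' @return adjusted Rand index; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  mclust::adjustedRandIndex(a, b)
}

#' Write clusters as TSV (cluster_id, member_id)
#'
#' @param cs a [greedy_cluster()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cs, path) {
  tab <- data.frame(
    cluster_id = rep(seq_along(cs$clusters), lengths(cs$clusters)),
    member_id = unlist(cs$clusters))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pairwise-alignment audit table as TSV
#'
#' @param edges an [align_all()] table (or `cs$edges`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
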