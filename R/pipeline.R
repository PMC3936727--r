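#' Assemble a pipeline configuration
#'
#' Collects every tunable of the spacer-to-consensus and cluster-to-tree
#' pipelines with the standard defaults: identity threshold 0.90, 10-nt
#' flank, consensus coverage 0.8, 800-aa length floor, 0.8/0.8
#' length/score coverage.
#'
#' @param loci list of [crispr_locus] objects, or path to a locus table.
#' @param targets [seq_records] table, or path to a FASTA file.
#' @param target_metadata optional data frame (`target_id`, `class`) or TSV
#'   path.
#' @param proteins optional protein [seq_records] or FASTA path.
#' @param msa optional alignment (see [as_alignment()]) or aligned-FASTA
#'   path, used for bootstrap supports.
#' @param groups optional named vector mapping `locus_id` to a pooling
#'   group label (closely related strains of one species share a label);
#'   default: one group per species.
#' @param min_identity,flank_len,coverage,min_support,dedupe PAM-side
#'   parameters.
#' @param min_len,length_cov,score_cov cluster-side parameters.
#' @param bootstrap_B bootstrap replicates (0 disables).
#' @param model distance model for the tree.
#' @param mask optional array-mask data frame for [find_protospacers()].
#' @param seed integer seed for the bootstrap resampling.
#' @return a `pam_config` list.
#' @export
pam_config <- function(loci = NULL, targets = NULL, target_metadata = NULL,
                       proteins = NULL, msa = NULL, groups = NULL,
                       min_identity = 0.90, flank_len = 10L, coverage = 0.8,
                       min_support = 3L, dedupe = TRUE, min_len = 800L,
                       length_cov = 0.8, score_cov = 0.8,
                       bootstrap_B = 100L, model = "poisson", mask = NULL,
                       seed = 1L) {
  stopifnot(min_identity > 0, min_identity <= 1, flank_len >= 1,
            coverage > 0, coverage <= 1, length_cov >= 0, length_cov <= 1,
            score_cov >= 0, min_len >= 0, bootstrap_B >= 0)
  structure(list(loci = loci, targets = targets,
                 target_metadata = target_metadata, proteins = proteins,
                 msa = msa, groups = groups, min_identity = min_identity,
                 flank_len = as.integer(flank_len), coverage = coverage,
                 min_support = as.integer(min_support), dedupe = dedupe,
                 min_len = as.integer(min_len), length_cov = length_cov,
                 score_cov = score_cov,
                 bootstrap_B = as.integer(bootstrap_B), model = model,
                 mask = mask, seed = as.integer(seed)),
            class = "pam_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar parameters are taken from the file; path-valued fields (`loci`,
#' `targets`, `target_metadata`, `proteins`, `msa`) are kept as paths and
#' resolved by the runners.
#'
#' @param path YAML file.
#' @return a `pam_config` list.
#' @export
read_pam_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pam_config, y)
}

resolve_loci <- function(x) {
  if (is.character(x)) return(read_locus_table(x))
  if (inherits(x, "crispr_locus")) return(list(x))
  x
}
resolve_records <- function(x, moltype) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(read_fasta(x, moltype))
  x
}
resolve_table <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(utils::read.delim(x, stringsAsFactors = FALSE))
  x
}

config_digest <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the spacer-to-consensus PAM discovery pipeline
#'
#' Hits are found for every locus, flanks extracted, loci pooled into
#' strain groups, and one PAM profile called per group, plus per-source
#' partitions when target metadata is available.
#'
#' @param config a [pam_config()].
#' @return object of class `pam_report`: `profiles` (per group),
#'   `by_source` (per source class), `hits` (with flanks), and `provenance`
#'   (config digest, package version, seed).
#' @export
run_pam_discovery <- function(config) {
  loci <- resolve_loci(config$loci)
  targets <- resolve_records(config$targets, "dna")
  meta <- resolve_table(config$target_metadata)
  if (is.null(loci) || !length(loci))
    stop("config carries no CRISPR loci", call. = FALSE)
  if (is.null(targets) || !nrow(targets))
    stop("config carries no targets", call. = FALSE)
  hits <- find_protospacers(loci, targets,
                            min_identity = config$min_identity,
                            mask = config$mask, target_metadata = meta)
  hf <- collect_flanks(hits, targets, config$flank_len,
                       dedupe = config$dedupe)
  if (!nrow(hf))
    stop("no usable protospacer hits in any group; add targets (e.g. from ",
         "closely related strains) or relax min_identity",
         call. = FALSE)
  groups <- config$groups
  if (is.null(groups)) {
    groups <- stats::setNames(
      vapply(loci, `[[`, "", "species"),
      vapply(loci, `[[`, "", "locus_id"))
  }
  hf$group <- unname(groups[hf$locus_id])
  hf$group[is.na(hf$group)] <- hf$locus_id[is.na(hf$group)]
  profiles <- list()
  for (g in sort(unique(hf$group))) {
    fl <- hf$flank[hf$group == g]
    if (length(fl) < config$min_support) {
      warning("group '", g, "' has only ", length(fl),
              " usable flank(s) (min_support = ", config$min_support,
              "); no consensus called — pool closely related strains",
              call. = FALSE)
      next
    }
    profiles[[g]] <- pam_profile(build_pfm(fl, config$flank_len),
                                 coverage = config$coverage,
                                 min_support = config$min_support,
                                 label = g)
  }
  by_source <- NULL
  if (!is.null(meta))
    by_source <- partition_by_source(hits, targets, config$flank_len,
                                     coverage = config$coverage,
                                     min_support = 1L,
                                     dedupe = config$dedupe)
  structure(list(profiles = profiles, by_source = by_source, hits = hf,
                 provenance = list(config_md5 = config_digest(config),
                                   package_version =
                                     as.character(utils::packageVersion("crispam")),
                                   seed = config$seed)),
            class = "pam_report")
}

#' @export
print.pam_report <- function(x, ...) {
  cat("PAM report: ", nrow(x$hits), " usable hit(s), ",
      length(x$profiles), " group profile(s)\n", sep = "")
  for (p in x$profiles)
    cat(sprintf("  %-20s %s  (n = %d)\n", p$partition_label, p$consensus,
                p$n))
  invisible(x)
}

#' Run the protein clustering and grouping pipeline
#'
#' Length filter, all-vs-all alignment, greedy clustering, informative
#' column selection (when an MSA is supplied), distance matrix, NJ tree
#' with optional column bootstrap, and per-cluster monophyly verdicts.
#' Without an MSA the tree is built from ungapped full-length sequences
#' stacked positionally only if they are equal-length; otherwise the tree
#' step requires the MSA.
#'
#' @param config a [pam_config()].
#' @return list: `clusters` (a `cluster_set`), `tree` (`phylo`),
#'   `concordance` (data frame), `bootstrap` (a [bootstrap_support()]
#'   result or `NULL`) and `provenance`.
#' @export
run_cluster_tree <- function(config) {
  proteins <- resolve_records(config$proteins, "protein")
  if (is.null(proteins) || !nrow(proteins))
    stop("config carries no protein sequences", call. = FALSE)
  kept <- filter_by_length(proteins, config$min_len)
  if (nrow(kept) < 3)
    stop("fewer than 3 proteins pass the ", config$min_len,
         "-aa length filter; tree undefined", call. = FALSE)
  cs <- greedy_cluster(kept, config$length_cov, config$score_cov)
  aln <- if (!is.null(config$msa)) {
    x <- config$msa
    if (is.character(x) && length(x) == 1 && file.exists(x))
      read_alignment(x) else as_alignment(x)
  } else {
    if (length(unique(nchar(kept$residues))) != 1)
      stop("no MSA supplied and retained proteins are not equal-length; ",
           "provide `msa` for the tree step", call. = FALSE)
    as_alignment(stats::setNames(kept$residues, kept$id))
  }
  sel <- select_informative_columns(aln)
  boot <- NULL
  if (config$bootstrap_B >= 1) {
    boot <- bootstrap_support(sel$alignment, B = config$bootstrap_B,
                              seed = config$seed, model = config$model)
    tree <- boot$tree
  } else {
    tree <- nj_tree(distance_matrix(sel$alignment, config$model))
  }
  conc <- clade_concordance(tree, cs,
                            replicates = if (!is.null(boot))
                              boot$replicates)
  list(clusters = cs, tree = tree, concordance = conc, bootstrap = boot,
       kept_columns = sel$kept,
       provenance = list(config_md5 = config_digest(config),
                         package_version =
                           as.character(utils::packageVersion("crispam")),
                         seed = config$seed))
}

#' Write a PAM report as JSON
#'
#' @param report a [run_pam_discovery()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    profiles = lapply(report$profiles, function(p)
      list(consensus = p$consensus, n = p$n, ic = p$ic)),
    by_source = lapply(report$by_source, function(p)
      list(consensus = p$consensus, n = p$n)),
    n_hits = nrow(report$hits),
    provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
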