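#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet DNAString
#'   reverseComplement IUPAC_CODE_MAP
NULL

# IUPAC nucleotide ambiguity sets, e.g. N -> A,C,G,T; W -> A,T.
iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(strsplit(unname(m), "", fixed = TRUE), names(m))
})

DNA_STRICT <- c("A", "C", "G", "T")

#' Construct a sequence record table
#'
#' Sequence sets are represented throughout the package as plain data frames
#' with one row per record and columns `id`, `description`, `residues` and
#' `moltype`.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param residues character vector of sequences (uppercased on input; for
#'   `moltype = "dna"`, `U` is normalized to `T`).
#' @param description free-text descriptions (default empty).
#' @param moltype one of `"dna"`, `"rna"`, `"protein"`.
#' @return a `data.frame` with class `c("seq_records", "data.frame")`.
#' @export
seq_records <- function(id, residues, description = "", moltype = "dna") {
  moltype <- match.arg(moltype, c("dna", "rna", "protein"))
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("`id` and `residues` must have the same length", call. = FALSE)
  if (any(!nzchar(residues)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "), call. = FALSE)
  if (any(grepl("[[:space:]]", id)))
    stop("record ids must not contain whitespace", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  if (moltype == "dna") {
    residues <- gsub("U", "T", residues, fixed = TRUE)
    bad <- grepl(sprintf("[^%s-]", paste(names(iupac_sets), collapse = "")),
                 residues)
    if (any(bad))
      stop("non-IUPAC DNA characters in record(s): ",
           paste(id[bad], collapse = ", "), call. = FALSE)
  }
  description <- rep_len(as.character(description), length(id))
  out <- data.frame(id = id, description = description, residues = residues,
                    moltype = rep_len(moltype, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file into a record table
#'
#' Wrapping is collapsed and residues are uppercased.  An empty file yields a
#' zero-row table.
#'
#' @param path path to a FASTA file.
#' @param moltype molecule type assigned to all records (`"dna"`, `"rna"` or
#'   `"protein"`).
#' @return a [seq_records] data frame.
#' @export
read_fasta <- function(path, moltype = "dna") {
  moltype <- match.arg(moltype, c("dna", "rna", "protein"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(raw))))
    return(seq_records(character(), character(), moltype = moltype)[0, ])
  first <- which(nzchar(trimws(raw)))[1]
  if (!startsWith(raw[first], ">"))
    stop("malformed FASTA: line ", first, " is not a '>' header in ", path,
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0)) {
    bad <- which(Biostrings::width(set) == 0)[1]
    stop("malformed FASTA: empty sequence under header '",
         names(set)[bad], "'", call. = FALSE)
  }
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seq_records(id, as.character(set), desc, moltype = moltype)
}

#' Write a record table as FASTA
#'
#' @param records a [seq_records] data frame.
#' @param path output path.
#' @param width maximum sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), width >= 1)
  nm <- ifelse(nzchar(records$description),
               paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(stats::setNames(records$residues, nm))
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, path, width = as.integer(width))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write FASTA to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Reverse complement with IUPAC-aware complementation
#'
#' Each ambiguity letter maps to the letter whose base set is the complement
#' set (`W` to `W`, `R` to `Y`, ...).
#'
#' @param dna character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(dna) {
  vapply(dna, function(x) {
    x <- toupper(x)
    if (grepl(sprintf("[^%s]", paste(names(iupac_sets), collapse = "")), x))
      stop("non-IUPAC character in DNA string", call. = FALSE)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

#' Test a sequence against an IUPAC pattern
#'
#' @param pattern IUPAC string (e.g. `"NGG"`).
#' @param seq sequence over A/C/G/T of the same length.
#' @return `TRUE` iff every base of `seq` lies in the base set of the
#'   corresponding `pattern` letter.
#' @export
iupac_match <- function(pattern, seq) {
  pattern <- toupper(pattern); seq <- toupper(seq)
  if (nchar(pattern) != nchar(seq))
    stop("pattern and sequence must have equal length", call. = FALSE)
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  if (!all(p %in% names(iupac_sets)))
    stop("non-IUPAC letter in pattern", call. = FALSE)
  if (!all(s %in% DNA_STRICT))
    stop("sequence must be over A/C/G/T", call. = FALSE)
  all(mapply(function(pi, si) si %in% iupac_sets[[pi]], p, s))
}

#' Construct a CRISPR locus
#'
#' A locus carries the repeat, the ordered spacers and the experimentally
#' determined array orientation for one host.  Spacers must be unambiguous
#' (A/C/G/T only) so that identity arithmetic downstream is well defined;
#' `U` is normalized to `T`.
#'
#' @param locus_id whitespace-free token.
#' @param species free-text host species.
#' @param repeat_seq repeat sequence (DNA or RNA letters).
#' @param spacers named character vector: names are spacer ids, values
#'   spacer sequences, in array order.
#' @param orientation `"forward"`, `"reverse"` or `"unknown"` (allowed but
#'   flagged with a warning — orientation is an experimental input, not
#'   computed).
#' @param subtype optional `"II-A"`, `"II-B"` or `"II-C"`.
#' @return an object of class `crispr_locus`.
#' @export
crispr_locus <- function(locus_id, species, repeat_seq, spacers,
                         orientation = c("forward", "reverse", "unknown"),
                         subtype = NA_character_) {
  orientation <- match.arg(orientation)
  if (grepl("[[:space:]]", locus_id))
    stop("locus_id must not contain whitespace", call. = FALSE)
  if (length(spacers) < 1)
    stop("locus '", locus_id, "' must carry at least one spacer",
         call. = FALSE)
  ids <- names(spacers)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("spacers must be a named character vector (names = spacer ids)",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate spacer_id within locus '", locus_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  norm <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
  spacers[] <- norm(spacers)
  repeat_seq <- norm(repeat_seq)
  bad <- grepl("[^ACGT]", spacers)
  if (any(bad))
    stop("spacer(s) with ambiguous bases in locus '", locus_id, "': ",
         paste(ids[bad], collapse = ", "),
         " (spacers must be A/C/G/T only)", call. = FALSE)
  if (!is.na(subtype)) subtype <- match.arg(subtype, c("II-A", "II-B", "II-C"))
  if (orientation == "unknown")
    warning("locus '", locus_id, "' has unknown array orientation",
            call. = FALSE)
  structure(list(locus_id = locus_id, species = species,
                 repeat_seq = repeat_seq, spacers = spacers,
                 orientation = orientation, subtype = subtype),
            class = "crispr_locus")
}

#' @export
print.crispr_locus <- function(x, ...) {
  cat("CRISPR locus ", x$locus_id, " (", x$species, ")\n",
      "  repeat: ", x$repeat_seq, "\n",
      "  spacers: ", length(x$spacers),
      "; orientation: ", x$orientation,
      if (!is.na(x$subtype)) paste0("; subtype: ", x$subtype), "\n", sep = "")
  invisible(x)
}

LOCUS_COLS <- c("locus_id", "species", "repeat", "orientation",
                "spacer_id", "spacer_seq")

#' Read a CRISPR locus table
#'
#' Tab-separated, one spacer per row, columns `locus_id`, `species`,
#' `repeat`, `orientation`, `spacer_id`, `spacer_seq` and optionally
#' `subtype`.  Spacer order within a locus is file order.
#'
#' @param path path to the TSV file.
#' @return a named list of [crispr_locus] objects.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  miss <- setdiff(LOCUS_COLS, names(tab))
  if (length(miss))
    stop("locus table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  loci <- lapply(split(seq_len(nrow(tab)), factor(tab$locus_id,
                                                  levels = unique(tab$locus_id))),
                 function(i) {
    sub <- tab[i, , drop = FALSE]
    crispr_locus(
      locus_id = sub$locus_id[1], species = sub$species[1],
      repeat_seq = sub[["repeat"]][1],
      spacers = stats::setNames(sub$spacer_seq, sub$spacer_id),
      orientation = sub$orientation[1],
      subtype = if ("subtype" %in% names(sub) && nzchar(sub$subtype[1]))
        sub$subtype[1] else NA_character_)
  })
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  loci
}

#' Write CRISPR loci as a locus table
#'
#' Inverse of [read_locus_table()].
#'
#' @param loci list of [crispr_locus] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  rows <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus_id = l$locus_id, species = l$species,
               "repeat" = l$repeat_seq, orientation = l$orientation,
               spacer_id = names(l$spacers), spacer_seq = unname(l$spacers),
               subtype = ifelse(is.na(l$subtype), "", l$subtype),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
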