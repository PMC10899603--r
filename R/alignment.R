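#' Gapped protein multiple sequence alignments
#'
#' An `msa_alignment` holds a gapped protein alignment together with the
#' identifier of a designated reference sequence (the engineering target whose
#' ungapped numbering anchors all downstream mutation nomenclature, e.g. E75P).
#'
#' @param ids character vector of record identifiers (unique).
#' @param seqs character vector of gapped sequences, upper case, equal length.
#' @param reference_id identifier of the reference record; must be in `ids`.
#' @return An object of class `msa_alignment`: a list with elements `ids`,
#'   `seqs` (named by id) and `reference_id`.
#' @export
msa_alignment <- function(ids, seqs, reference_id) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0) stop("empty-input: alignment has no records")
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate record identifiers")
  if (any(!nzchar(seqs))) stop("alignment-format: empty sequence")
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment-format: sequences have unequal lengths")
  if (!reference_id %in% ids)
    stop("missing-reference: reference_id '", reference_id,
         "' not among records")
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), UNKNOWN, GAP, "]"),
               seqs)
  if (any(bad))
    stop("alignment-format: invalid residue symbols in record(s) ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, reference_id = reference_id),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("Gapped protein alignment: ", length(x$ids), " records x ",
      nchar(x$seqs[[1]]), " columns\n", sep = "")
  cat("Reference: ", x$reference_id, "\n", sep = "")
  invisible(x)
}

#' @export
length.msa_alignment <- function(x) length(x$ids)

## alignment as a character matrix (records x columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$ids
  m
}

#' Read a gapped FASTA alignment
#'
#' @param path path to a FASTA file holding the gapped alignment.
#' @param reference_id identifier of the reference sequence.
#' @return An [msa_alignment()] with record order preserved.
#' @export
read_alignment <- function(path, reference_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty-input: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  msa_alignment(ids, as.character(set), reference_id)
}

#' Write an alignment to FASTA (canonical form)
#'
#' Writes 60-column wrapped FASTA; a write-read-write cycle is byte-identical.
#'
#' @param aln an [msa_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa_alignment"))
  set <- Biostrings::BStringSet(aln$seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Pairwise sequence identity over mutually aligned columns
#'
#' Identity is counted over columns where both sequences are non-gap
#' (mutual-coverage convention). If no such column exists the identity is 0
#' and the result carries attribute `no_overlap = TRUE`.
#'
#' @param a,b gapped sequences (single strings) of equal length.
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb))
    stop("alignment-format: sequences have unequal lengths")
  both <- ca != GAP & cb != GAP
  if (!any(both)) {
    warning("no shared non-gap columns; identity undefined, reporting 0")
    return(structure(0, no_overlap = TRUE))
  }
  sum(ca[both] == cb[both]) / sum(both)
}

#' Filter homologs by identity to the reference
#'
#' Retains the reference plus homologs whose identity to the reference is
#' strictly greater than `min_identity`. Columns that become all-gap are
#' removed; reference ungapped numbering is unaffected by construction.
#'
#' @param aln an [msa_alignment()].
#' @param min_identity identity threshold (strict `>`); default 0.60.
#' @return Filtered [msa_alignment()].
#' @export
filter_homologs <- function(aln, min_identity = 0.60) {
  stopifnot(inherits(aln, "msa_alignment"))
  ref <- aln$seqs[[aln$reference_id]]
  keep <- vapply(aln$ids, function(id) {
    id == aln$reference_id ||
      suppressWarnings(pairwise_identity(aln$seqs[[id]], ref)) > min_identity
  }, logical(1))
  if (sum(keep) < 2)
    stop("empty-homolog-set: no homolog exceeds identity ", min_identity)
  m <- aln_matrix(aln)[keep, , drop = FALSE]
  allgap <- apply(m, 2, function(col) all(col == GAP))
  m <- m[, !allgap, drop = FALSE]
  msa_alignment(rownames(m), apply(m, 1, paste, collapse = ""),
                aln$reference_id)
}
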