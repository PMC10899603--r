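#' Per-column residue profiles against the reference
#'
#' Tallies homolog residues at every alignment column where the reference is
#' non-gap. The reference row does not vote: counts, coverage and all
#' frequencies are computed over the homologs only. `'X'` and gaps are
#' excluded from frequency denominators; gaps reduce coverage.
#'
#' @param aln an [msa_alignment()].
#' @return A data frame with one row per reference position: `column_index`
#'   (0-based alignment column), `ref_position` (1-based ungapped reference
#'   numbering), `ref_residue`, `coverage` (fraction of homologs non-gap),
#'   plus one count column per amino acid (`n_A` ... `n_Y`).
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "msa_alignment"))
  m <- aln_matrix(aln)
  ref <- m[aln$reference_id, ]
  hom <- m[setdiff(aln$ids, aln$reference_id), , drop = FALSE]
  n_hom <- nrow(hom)
  if (n_hom == 0) stop("alignment has no homologs besides the reference")
  cols <- which(ref != GAP)
  counts <- t(vapply(cols, function(j) {
    tab <- table(factor(hom[, j], levels = AA20))
    as.integer(tab)
  }, integer(length(AA20))))
  colnames(counts) <- paste0("n_", AA20)
  coverage <- vapply(cols, function(j) sum(hom[, j] != GAP) / n_hom,
                     numeric(1))
  out <- data.frame(
    column_index = cols - 1L,
    ref_position = seq_along(cols),
    ref_residue = ref[cols],
    coverage = coverage,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(counts))
  attr(out, "n_homologs") <- n_hom
  out
}

## residue frequencies at one profile row over non-gap, non-X homologs
profile_freqs <- function(row) {
  counts <- as.numeric(row[paste0("n_", AA20)])
  names(counts) <- AA20
  denom <- sum(counts)
  if (denom == 0) return(counts)  # all-gap/X column: frequencies all zero
  counts / denom
}

#' Call consensus-mutagenesis candidates
#'
#' Emits one candidate substitution per reference position where the wildtype
#' residue is underrepresented among homologs and a clear alternative
#' consensus exists: coverage >= `min_coverage`, wildtype frequency <=
#' `wt_max_freq`, the modal homolog residue differs from wildtype, and its
#' frequency >= `consensus_min_freq`. Modal ties break by higher count, then
#' alphabetical residue order.
#'
#' @param profiles output of [column_profiles()].
#' @param wt_max_freq maximum wildtype frequency for a position to be called.
#' @param consensus_min_freq minimum modal residue frequency.
#' @param min_coverage minimum homolog coverage at the column.
#' @return Data frame `ref_position`, `wt_residue`, `proposed_residue`,
#'   `wt_frequency`, `consensus_frequency`, `coverage` (0 rows if no call).
#' @export
call_consensus <- function(profiles, wt_max_freq = 0.30,
                           consensus_min_freq = 0.50, min_coverage = 0.70) {
  stopifnot(all(c(wt_max_freq, consensus_min_freq, min_coverage) >= 0),
            all(c(wt_max_freq, consensus_min_freq, min_coverage) <= 1))
  empty <- data.frame(ref_position = integer(), wt_residue = character(),
                      proposed_residue = character(), wt_frequency = numeric(),
                      consensus_frequency = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(profiles) || nrow(profiles) == 0) return(empty)
  calls <- lapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, ]
    if (row$coverage < min_coverage) return(NULL)
    freqs <- profile_freqs(row)
    wt <- row$ref_residue
    wt_f <- freqs[[wt]]
    if (wt_f > wt_max_freq) return(NULL)
    ## modal residue: max frequency, ties by alphabetical order (AA20 sorted)
    modal <- AA20[which.max(freqs)]
    if (modal == wt) return(NULL)
    if (freqs[[modal]] < consensus_min_freq) return(NULL)
    data.frame(ref_position = row$ref_position, wt_residue = wt,
               proposed_residue = modal, wt_frequency = unname(wt_f),
               consensus_frequency = unname(freqs[[modal]]),
               coverage = row$coverage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), calls))
  rownames(out) <- NULL
  out
}

#' Differential sequence-logo matrix
#'
#' For each reference position, non-wildtype residue frequencies are reported
#' as positive heights and the wildtype residue entry carries the negative
#' frequency deficit `-(1 - wt frequency)`, matching a differential logo in
#' which conserved positions vanish and underrepresented wildtype residues
#' plot downward.
#'
#' @param profiles output of [column_profiles()].
#' @return Data frame: `ref_position`, `ref_residue`, then one signed height
#'   column per amino acid.
#' @export
differential_logo_matrix <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  heights <- t(vapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, ]
    freqs <- profile_freqs(row)
    wt <- row$ref_residue
    h <- freqs
    h[wt] <- -(1 - freqs[[wt]])
    if (sum(as.numeric(row[paste0("n_", AA20)])) == 0) h[wt] <- 0
    h
  }, numeric(length(AA20))))
  colnames(heights) <- AA20
  cbind(profiles[, c("ref_position", "ref_residue")],
        as.data.frame(heights))
}

#' Drop consensus calls near the active site
#'
#' Removes calls whose C-alpha lies within `radius` of any active-site
#' residue C-alpha, so stabilizing substitutions stay clear of catalysis.
#' Calls at positions absent from the structure are retained with
#' `flagged_missing = TRUE` and a warning.
#'
#' @param calls data frame from [call_consensus()].
#' @param structure a [read_structure()] model whose residue numbering matches
#'   reference numbering.
#' @param active_site_residues integer residue numbers of the active site.
#' @param radius exclusion radius in Angstrom.
#' @param chain chain identifier to use; default first chain.
#' @return `calls` filtered, with a `flagged_missing` column.
#' @export
exclude_near_active_site <- function(calls, structure, active_site_residues,
                                     radius, chain = NULL) {
  stopifnot(is.data.frame(calls), radius >= 0)
  calls$flagged_missing <- FALSE
  if (nrow(calls) == 0 || radius == 0) return(calls)
  ca <- ca_coords(structure, chain = chain)
  site <- ca[ca$resno %in% active_site_residues, c("x", "y", "z"),
             drop = FALSE]
  if (nrow(site) == 0) stop("no active-site residue found in structure")
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    pos <- calls$ref_position[i]
    j <- match(pos, ca$resno)
    if (is.na(j)) {
      warning("call position ", pos, " absent from structure; retained")
      calls$flagged_missing[i] <<- TRUE
      return(TRUE)
    }
    p <- as.numeric(ca[j, c("x", "y", "z")])
    d <- sqrt(rowSums((t(t(as.matrix(site)) - p))^2))
    all(d > radius)
  }, logical(1))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
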