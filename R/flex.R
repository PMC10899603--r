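#' Detect flexible segments from C-alpha B-factors
#'
#' Per chain, C-alpha B-factors are z-normalized, a sliding-window mean of
#' width `window` is computed, and maximal runs of windows whose mean exceeds
#' `z_threshold` are merged into residue segments. Invariant under affine
#' rescaling of the B-factor column.
#'
#' @param structure a `pdb_structure` with C-alpha B-factors.
#' @param window sliding window width in residues (default 5).
#' @param z_threshold z-score threshold (default 1.0).
#' @return Data frame `chain`, `start`, `end`, `mean_z`, sorted and
#'   non-overlapping within each chain.
#' @export
flexible_segments <- function(structure, window = 5, z_threshold = 1.0) {
  stopifnot(window >= 1)
  ca <- ca_coords(structure)
  if (nrow(ca) == 0) stop("no C-alpha atoms in structure")
  out <- list()
  for (ch in unique(ca$chain)) {
    cc <- ca[ca$chain == ch, ]
    cc <- cc[order(cc$resno), ]
    b <- cc$b
    if (length(b) < window) next
    if (stats::sd(b) == 0)
      stop("degenerate-B: all B-factors equal; z-score undefined")
    z <- (b - mean(b)) / stats::sd(b)
    ## window means; window w starting at residue index k covers k..k+w-1
    wm <- stats::filter(z, rep(1 / window, window), sides = 1)
    wm <- as.numeric(wm)[window:length(z)]  # mean of z[k..k+w-1] at index k
    hot <- wm > z_threshold
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]                 # first flagged window start index
      i1 <- ends[k] + window - 1      # last residue covered by flagged run
      idx <- i0:i1
      out[[length(out) + 1]] <- data.frame(
        chain = ch, start = cc$resno[i0], end = cc$resno[i1],
        mean_z = mean(z[idx]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(list(data.frame(chain = character(),
                                          start = integer(), end = integer(),
                                          mean_z = numeric(),
                                          stringsAsFactors = FALSE)), out))
  res <- res[order(res$chain, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
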