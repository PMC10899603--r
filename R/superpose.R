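#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `coords_b` onto `coords_a` via
#' singular value decomposition, constrained to a proper rotation
#' (determinant +1).
#'
#' @param coords_a,coords_b numeric matrices (n x 3), n >= 3, matched rows.
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `b %*% t(rotation) + translation` superposes onto `a`, and `rmsd`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("coordinate sets must be matched n x 3 matrices")
  if (nrow(a) < 3) stop("degenerate-geometry: need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  ## collinearity check: rank of centered coordinates
  if (sum(svd(a0)$d > 1e-8 * max(1, max(abs(a0)))) < 2 ||
      sum(svd(b0)$d > 1e-8 * max(1, max(abs(b0)))) < 2)
    stop("degenerate-geometry: points are collinear or coincident")
  h <- t(b0) %*% a0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - a0)^2)))
  list(rotation = rot, translation = as.numeric(ca - cb %*% t(rot)),
       rmsd = rmsd)
}

## C-alpha coordinates for a residue number vector, in order; NULL on a miss
segment_ca <- function(structure, chain, resnos) {
  ca <- ca_coords(structure, chain = chain)
  idx <- match(resnos, ca$resno)
  if (anyNA(idx)) return(NULL)
  as.matrix(ca[idx, c("x", "y", "z")])
}

#' Loop-graft candidates by anchor superposition
#'
#' For replacing a flexible target loop with a shorter homologous loop: the
#' `n_anchor` flanking C-alpha on each side of the donor segment are
#' superposed onto the target's flanks; donors whose anchor RMSD is within
#' `anchor_rmsd_max` and whose loop is strictly shorter than the target's are
#' reported, sorted by (length_delta, anchor RMSD).
#'
#' @param target a `pdb_structure`.
#' @param target_segment list `chain`, `start`, `end` of the target loop.
#' @param donors list of donor specs: each a list with `structure`,
#'   `id` (donor structure label), `chain`, `start`, `end`.
#' @param n_anchor flanking residues per side (default 3).
#' @param anchor_rmsd_max maximum anchor RMSD in Angstrom (default 1.0).
#' @return Data frame `donor_id`, `donor_chain`, `donor_start`, `donor_end`,
#'   `anchor_rmsd`, `length_delta`.
#' @export
loop_graft_candidates <- function(target, target_segment, donors,
                                  n_anchor = 3, anchor_rmsd_max = 1.0) {
  ts <- target_segment
  t_anch <- c(seq(ts$start - n_anchor, ts$start - 1),
              seq(ts$end + 1, ts$end + n_anchor))
  t_ca <- segment_ca(target, ts$chain, t_anch)
  if (is.null(t_ca))
    stop("target segment lacks ", n_anchor, " anchored flanking residues")
  t_len <- ts$end - ts$start + 1
  rows <- list()
  for (d in donors) {
    d_anch <- c(seq(d$start - n_anchor, d$start - 1),
                seq(d$end + 1, d$end + n_anchor))
    d_ca <- segment_ca(d$structure, d$chain, d_anch)
    if (is.null(d_ca)) {
      warning("donor ", d$id, " lacks flanking anchors; skipped")
      next
    }
    fit <- kabsch_superpose(t_ca, d_ca)
    delta <- (d$end - d$start + 1) - t_len
    if (fit$rmsd <= anchor_rmsd_max && delta < 0) {
      rows[[length(rows) + 1]] <- data.frame(
        donor_id = d$id, donor_chain = d$chain, donor_start = d$start,
        donor_end = d$end, anchor_rmsd = fit$rmsd, length_delta = delta,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(data.frame(donor_id = character(),
                                          donor_chain = character(),
                                          donor_start = integer(),
                                          donor_end = integer(),
                                          anchor_rmsd = numeric(),
                                          length_delta = integer(),
                                          stringsAsFactors = FALSE)), rows))
  out <- out[order(out$length_delta, out$anchor_rmsd), , drop = FALSE]
  rownames(out) <- NULL
  out
}
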