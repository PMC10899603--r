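## Independent oracles and fixture builders used across the suite. These are
## deliberately written as direct, brute-force procedures, separate from the
## package code paths they check.

AA4 <- c("A", "C", "D", "E")

## random small gapped alignment over a reduced alphabet
random_small_msa <- function(n_seq, n_col, gap_prob = 0.15,
                             alphabet = AA4) {
  ids <- c("REF", paste0("H", seq_len(n_seq - 1)))
  seqs <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(alphabet, n_col, replace = TRUE)
    if (i > 1) {
      gaps <- stats::runif(n_col) < gap_prob
      chars[gaps] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  msa_alignment(ids, seqs, "REF")
}

## brute-force consensus oracle: direct tally over the alignment matrix,
## no shared code with column_profiles()/call_consensus()
oracle_consensus <- function(aln, wt_max_freq, consensus_min_freq,
                             min_coverage) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$ids
  ref <- m[aln$reference_id, ]
  hom <- m[setdiff(aln$ids, aln$reference_id), , drop = FALSE]
  calls <- list()
  ref_pos <- 0
  for (j in seq_len(ncol(m))) {
    if (ref[j] == "-") next
    ref_pos <- ref_pos + 1
    col <- hom[, j]
    cov <- sum(col != "-") / length(col)
    if (cov < min_coverage) next
    resid <- col[col != "-" & col != "X"]
    if (length(resid) == 0) next
    aas <- sort(unique(resid))
    freqs <- vapply(aas, function(a) sum(resid == a) / length(resid),
                    numeric(1))
    wt_f <- if (ref[j] %in% aas) freqs[[ref[j]]] else 0
    if (wt_f > wt_max_freq) next
    modal <- aas[freqs == max(freqs)][1]  # alphabetical tie-break
    if (modal == ref[j] || max(freqs) < consensus_min_freq) next
    calls[[length(calls) + 1]] <- data.frame(
      ref_position = ref_pos, wt_residue = ref[j], proposed_residue = modal,
      stringsAsFactors = FALSE)
  }
  if (length(calls) == 0)
    return(data.frame(ref_position = integer(), wt_residue = character(),
                      proposed_residue = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

## 1-degree-grid brute-force disulfide acceptance oracle; independent sulfur
## placement (explicit rotation about the CA-CB axis rather than place_atom)
oracle_ss_accept <- function(row_i, row_j) {
  ## same CA/CB prefilter as the published criteria family, then a dense
  ## 1-degree chi1 x chi1 sweep
  dca <- sqrt(sum((c(row_i$cax, row_i$cay, row_i$caz) -
                     c(row_j$cax, row_j$cay, row_j$caz))^2))
  dcb <- sqrt(sum((c(row_i$cbx, row_i$cby, row_i$cbz) -
                     c(row_j$cbx, row_j$cby, row_j$cbz))^2))
  if (dca > 7.5 || dcb < 3.0 || dcb > 5.0) return(FALSE)
  sg_circle <- function(row) {
    n <- c(row$nx, row$ny, row$nz)
    ca <- c(row$cax, row$cay, row$caz)
    cb <- c(row$cbx, row$cby, row$cbz)
    axis <- (cb - ca) / sqrt(sum((cb - ca)^2))
    ## reference direction: component of (N - CA) perpendicular to the axis
    v <- (n - ca) - sum((n - ca) * axis) * axis
    v <- v / sqrt(sum(v^2))
    w <- c(axis[2] * v[3] - axis[3] * v[2],
           axis[3] * v[1] - axis[1] * v[3],
           axis[1] * v[2] - axis[2] * v[1])
    theta <- (109.47) * pi / 180
    t(vapply(seq(-180, 179, by = 1), function(chi) {
      ## rotate the reference direction about the axis; chi measured as the
      ## N-CA-CB-SG torsion equals the rotation angle from the reference
      phi <- chi * pi / 180
      dirn <- -cos(theta) * axis +
        sin(theta) * (cos(phi) * v + sin(phi) * w)
      cb + 1.81 * dirn
    }, numeric(3)))
  }
  sgi <- sg_circle(row_i)
  sgj <- sg_circle(row_j)
  cb_i <- c(row_i$cbx, row_i$cby, row_i$cbz)
  cb_j <- c(row_j$cbx, row_j$cby, row_j$cbz)
  dmat <- sqrt(pmax(outer(rowSums(sgi^2), rowSums(sgj^2), "+") -
                      2 * sgi %*% t(sgj), 0))
  hits <- which(abs(dmat - 2.05) <= 0.35, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    a <- hits[r, 1]; b <- hits[r, 2]
    chi3 <- dihedral_angle(cb_i, sgi[a, ], sgj[b, ], cb_j)
    if (abs(chi3) >= 60 && abs(chi3) <= 120) return(TRUE)
  }
  FALSE
}

## residue-pair structure with configurable disulfide geometry, optionally
## rigidly rotated/translated
perturbed_ss_pair <- function(d_sg, chi3, chi1 = -60, rotate = TRUE) {
  atoms <- ideal_ss_pair_atoms("A", 1, 10, d_sg = d_sg, chi3 = chi3,
                               chi1 = chi1)
  if (rotate) {
    th <- stats::runif(3, 0, 2 * pi)
    rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rz %*% rx)
    xyz <- sweep(xyz, 2, stats::runif(3, -20, 20), "+")
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  pdb_structure(atoms)
}

## the ten stabilized-variant consensus sites used as the planted signal set
stable_sites <- function() {
  data.frame(
    position = c(75, 86, 110, 188, 222, 296, 297, 388, 413, 430),
    wt = c("E", "Q", "S", "I", "G", "G", "V", "T", "S", "G"),
    consensus = c("P", "K", "V", "L", "D", "L", "G", "A", "K", "K"),
    stringsAsFactors = FALSE)
}
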