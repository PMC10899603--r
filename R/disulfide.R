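## Geometric constants of the disulfide scan. Sulfur is modelled at 1.81 A
## from C-beta with a tetrahedral CA-CB-SG angle; the S-S bond target is
## 2.05 A and the C-S-S-C torsion (chi3) target 87 degrees.
SS_BOND_SG <- 1.81
SS_ANGLE_CB_SG <- 109.47
SS_TARGET_D <- 2.05
SS_TOL_D <- 0.35
SS_CHI3_LO <- 60
SS_CHI3_HI <- 120
SS_CHI3_IDEAL <- 87
SS_CHI3_SCALE <- 30

#' Disulfide strain score
#'
#' Zero at ideal geometry (S-S distance 2.05 A, |chi3| = 87 deg) and strictly
#' increasing in both deviations.
#'
#' @param d_sg modelled S-gamma-S-gamma distance (Angstrom).
#' @param chi3 C-beta-S-S-C-beta torsion (degrees).
#' @return Dimensionless strain score >= 0.
#' @export
ss_strain_score <- function(d_sg, chi3) {
  ((d_sg - SS_TARGET_D) / SS_TOL_D)^2 +
    ((abs(chi3) - SS_CHI3_IDEAL) / SS_CHI3_SCALE)^2
}

#' Reconstruct an ideal C-beta from backbone atoms
#'
#' Places C-beta at 1.53 A from C-alpha with tetrahedral geometry, using the
#' standard improper torsion convention for L-amino acids; lets glycine be
#' screened as a cysteine-substitutable position.
#'
#' @param n,ca,c backbone N, C-alpha and C xyz vectors.
#' @return xyz of the ideal C-beta.
#' @export
reconstruct_cb <- function(n, ca, c) {
  as.numeric(place_atom(n, c, ca, 1.53, 110.1, 122.6))
}

## backbone (+CB) table, one row per screenable residue
residue_backbone <- function(structure) {
  a <- structure$atoms[!structure$atoms$het, ]
  keys <- unique(a[, c("chain", "resno", "insert", "resid")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- a[a$chain == k$chain & a$resno == k$resno & a$insert == k$insert, ]
    get <- function(e) {
      j <- match(e, sel$elety)
      if (is.na(j)) NULL else as.numeric(sel[j, c("x", "y", "z")])
    }
    n <- get("N"); ca <- get("CA"); cc <- get("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) {
      warning("residue ", k$chain, k$resno,
              " lacks backbone atoms; skipped")
      return(NULL)
    }
    cb <- get("CB")
    if (is.null(cb)) cb <- reconstruct_cb(n, ca, cc)
    data.frame(chain = k$chain, resno = k$resno, insert = k$insert,
               resid = k$resid,
               nx = n[1], ny = n[2], nz = n[3],
               cax = ca[1], cay = ca[2], caz = ca[3],
               cbx = cb[1], cby = cb[2], cbz = cb[3],
               cx = cc[1], cy = cc[2], cz = cc[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## S-gamma positions over a chi1 grid for one backbone row: matrix n_grid x 3
sg_positions <- function(row, chi1_grid) {
  n <- c(row$nx, row$ny, row$nz)
  ca <- c(row$cax, row$cay, row$caz)
  cb <- c(row$cbx, row$cby, row$cbz)
  t(vapply(chi1_grid, function(chi1)
    as.numeric(place_atom(n, ca, cb, SS_BOND_SG, SS_ANGLE_CB_SG, chi1)),
    numeric(3)))
}

sg_distance_matrix <- function(sg_i, sg_j) {
  d2 <- outer(rowSums(sg_i^2), rowSums(sg_j^2), "+") -
    2 * sg_i %*% t(sg_j)
  sqrt(pmax(d2, 0))
}

## best chi1 pair for two backbone rows: a coarse chi1 grid screens for any
## cell near the S-S distance window (the sulfur moves < 0.08 A per 2.5
## degrees, so a 0.25 A widened window cannot miss an acceptable geometry);
## if the screen hits, the full criterion is evaluated on a 1-degree grid.
## Returns NULL when no chi1 combination passes.
best_ss_geometry <- function(row_i, row_j, chi1_step = 5) {
  coarse <- seq(-180, 180 - chi1_step, by = chi1_step)
  d_coarse <- sg_distance_matrix(sg_positions(row_i, coarse),
                                 sg_positions(row_j, coarse))
  if (!any(abs(d_coarse - SS_TARGET_D) <= SS_TOL_D + 0.25)) return(NULL)
  fine <- seq(-180, 179, by = 1)
  sg_i <- sg_positions(row_i, fine)
  sg_j <- sg_positions(row_j, fine)
  d <- sg_distance_matrix(sg_i, sg_j)
  idx <- which(abs(d - SS_TARGET_D) <= SS_TOL_D, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cb_i <- c(row_i$cbx, row_i$cby, row_i$cbz)
  cb_j <- c(row_j$cbx, row_j$cby, row_j$cbz)
  best <- NULL
  for (r in seq_len(nrow(idx))) {
    gi <- idx[r, 1]; gj <- idx[r, 2]
    chi3 <- dihedral_angle(cb_i, sg_i[gi, ], sg_j[gj, ], cb_j)
    if (abs(chi3) < SS_CHI3_LO || abs(chi3) > SS_CHI3_HI) next
    s <- ss_strain_score(d[gi, gj], chi3)
    if (is.null(best) || s < best$strain) {
      best <- list(chi1_i = fine[gi], chi1_j = fine[gj],
                   d_sg = d[gi, gj], chi3 = chi3, strain = s)
    }
  }
  best
}

#' Scan a structure for disulfide-compatible residue pairs
#'
#' Over all residue pairs with sequence separation >= `min_sep` on the same
#' chain (any pair across chains), applies a C-alpha/C-beta distance
#' prefilter, then models S-gamma on both residues over a chi1 grid with
#' tetrahedral geometry and accepts pairs for which some chi1 combination
#' yields an S-S distance within 2.05 +/- 0.35 A and |chi3| in \[60, 120\]
#' degrees. Proline is excluded as a partner; glycine C-beta is
#' reconstructed. Candidates are sorted by ascending strain.
#'
#' @param structure a `pdb_structure`.
#' @param max_ca_ca C-alpha prefilter distance (default 7.5 A).
#' @param cb_cb_range C-beta distance window (default 3.0-5.0 A).
#' @param min_sep minimum intra-chain sequence separation (default 3).
#' @param chi1_step coarse chi1 screening step in degrees (default 5); pairs
#'   passing the screen are re-evaluated on a 1-degree grid.
#' @return Data frame of candidates: residue pair, `cb_cb_distance`,
#'   `chi1_i`, `chi1_j`, `sg_sg_distance`, `chi3`, `strain_score`,
#'   `interchain`.
#' @export
scan_disulfides <- function(structure, max_ca_ca = 7.5,
                            cb_cb_range = c(3.0, 5.0), min_sep = 3,
                            chi1_step = 5) {
  bb <- residue_backbone(structure)
  empty <- data.frame(chain_i = character(), resno_i = integer(),
                      chain_j = character(), resno_j = integer(),
                      cb_cb_distance = numeric(), chi1_i = numeric(),
                      chi1_j = numeric(), sg_sg_distance = numeric(),
                      chi3 = numeric(), strain_score = numeric(),
                      interchain = logical(), stringsAsFactors = FALSE)
  if (is.null(bb) || nrow(bb) < 2) return(empty)
  bb <- bb[bb$resid != "PRO", , drop = FALSE]
  if (nrow(bb) < 2) return(empty)
  ca <- as.matrix(bb[, c("cax", "cay", "caz")])
  cb <- as.matrix(bb[, c("cbx", "cby", "cbz")])
  n <- nrow(bb)
  res <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- bb$chain[i] == bb$chain[j]
      if (same && abs(bb$resno[i] - bb$resno[j]) < min_sep) next
      dca <- vnorm(ca[i, ] - ca[j, ])
      if (dca > max_ca_ca) next
      dcb <- vnorm(cb[i, ] - cb[j, ])
      if (dcb < cb_cb_range[1] || dcb > cb_cb_range[2]) next
      g <- best_ss_geometry(bb[i, ], bb[j, ], chi1_step)
      if (is.null(g)) next
      res[[length(res) + 1]] <- data.frame(
        chain_i = bb$chain[i], resno_i = bb$resno[i],
        chain_j = bb$chain[j], resno_j = bb$resno[j],
        cb_cb_distance = dcb, chi1_i = g$chi1_i, chi1_j = g$chi1_j,
        sg_sg_distance = g$d_sg, chi3 = g$chi3, strain_score = g$strain,
        interchain = !same, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(empty), res))
  out <- out[order(out$strain_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
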