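#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] producing a flat atom table.
#' A single model is retained; alternate locations are resolved to the
#' highest-occupancy conformer (ties by altloc label order); HETATM records
#' are retained but flagged.
#'
#' @param path path to a PDB file.
#' @param model model number to keep (default 1).
#' @return An object of class `pdb_structure`: list with `atoms` (data frame
#'   with `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`, `b`,
#'   `o`, `het`) and `model`.
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM"))
    stop("empty-structure: no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("parse error: non-finite coordinates")
  ## altloc resolution: highest occupancy, ties by label order
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ][!duplicated(key[ord]), ]
  at <- at[order(as.integer(rownames(at))), ]  # restore file order
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z, b = at$b, o = at$o,
    het = at$type == "HETATM", stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, model = model), class = "pdb_structure")
}

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` and optionally `insert`, `b`, `o`, `het`.
#' @return A `pdb_structure`.
#' @export
pdb_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in%
                  names(atoms)))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  structure(list(atoms = atoms, model = 1), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms[!x$atoms$het, ]
  cat("Structure model: ", nrow(x$atoms), " atoms, ",
      length(unique(paste(a$chain, a$resno, a$insert))), " residues, chains ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a structure model to PDB text
#'
#' @param structure a `pdb_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, insert = a$insert,
                   resid = a$resid, elety = a$elety, o = a$o, b = a$b)
  invisible(path)
}

## C-alpha table for one chain (or all chains), polymer atoms only
ca_coords <- function(structure, chain = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  a <- a[!a$het & a$elety == "CA", ]
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  if (is.null(chain) && length(unique(a$chain)) > 1) a <- a
  rownames(a) <- NULL
  a
}

## atom xyz for (chain, resno, elety); NULL when absent
atom_xyz <- function(atoms, chain, resno, elety) {
  i <- which(atoms$chain == chain & atoms$resno == resno &
               atoms$elety == elety & !atoms$het)
  if (length(i) == 0) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}
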