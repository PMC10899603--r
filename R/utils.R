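#' @keywords internal
"_PACKAGE"

## Amino-acid alphabet used throughout; 'X' is treated as missing, '-' as gap.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
UNKNOWN <- "X"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators never leak global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## ---- 3D geometry primitives (rows are points, columns x/y/z) ----

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return Signed dihedral in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions `a`, `b`, `c`, returns the point `d` with
#' bond length `|cd| = bond`, angle b-c-d equal to `angle` and dihedral
#' a-b-c-d equal to `dihedral` (degrees). Standard natural-extension
#' (NeRF-style) construction.
#'
#' @param a,b,c numeric xyz vectors.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param dihedral torsion in degrees.
#' @return xyz vector of the placed atom.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

## small-sample corrected AIC for least-squares fits with p mean parameters
aicc_ls <- function(rss, n, p) {
  k <- p + 1  # + residual variance
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

## round to a number of significant figures (used for headline tank counts)
signif2 <- function(x, digits = 2) signif(x, digits)
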