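# (kappa, alpha) virtual-bond backbone angles on the FCC lattice.
#
# kappa_i is the bend angle at residue i formed by the Calpha positions of
# residues i - 2, i, i + 2; alpha_i is the signed dihedral of residues
# i - 1, i, i + 1, i + 2.  On the lattice both take a small discrete set of
# values; an empirical 13 x 6 preference matrix (kappa bins 30..150 by 10
# degrees, six alpha spaces) turns them into an angle-realism objective and
# a hard feasibility constraint.

.kappa_centers <- seq(30, 150, by = 10)
.alpha_centers <- c(60, 80, 180, -130, -110, -10)
.deg_tol <- 1e-9

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Virtual bend angle kappa at a residue
#'
#' The angle at `coords[i, ]` between the arms to residues i - 2 and i + 2,
#' in degrees.  Defined for 3 <= i <= n - 2 (1-based).  Exactly colinear
#' arms (0 or 180 degrees) are geometrically degenerate; the value is still
#' returned and callers treat it as out of the feasible 30-150 range.
#'
#' @param coords n x 3 coordinate matrix.
#' @param i Residue index, 3 <= i <= n - 2.
#' @return Angle in degrees, in \[0, 180\].
#' @export
kappa_angle <- function(coords, i) {
  n <- nrow(coords)
  if (i < 3 || i > n - 2) stop("kappa is defined for 3 <= i <= n - 2")
  u <- coords[i - 2, ] - coords[i, ]
  v <- coords[i + 2, ] - coords[i, ]
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Virtual dihedral angle alpha at a residue
#'
#' The signed dihedral of the four Calpha positions of residues i - 1, i,
#' i + 1, i + 2 (right-hand rule about the central bond), in
#' (-180, 180\].  Defined for 2 <= i <= n - 2.  Returns `NA` when three of
#' the four points are colinear (torsion undefined).
#'
#' @inheritParams kappa_angle
#' @param i Residue index, 2 <= i <= n - 2.
#' @return Angle in degrees, or `NA_real_` if degenerate.
#' @export
alpha_angle <- function(coords, i) {
  n <- nrow(coords)
  if (i < 2 || i > n - 2) stop("alpha is defined for 2 <= i <= n - 2")
  b1 <- coords[i, ] - coords[i - 1, ]
  b2 <- coords[i + 1, ] - coords[i, ]
  b3 <- coords[i + 2, ] - coords[i + 1, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1 * n1) < .deg_tol || sum(n2 * n2) < .deg_tol) return(NA_real_)
  y <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2 * b2))
  ang <- atan2(y, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' All defined (kappa, alpha) pairs of a conformation
#'
#' One pair per residue i with 3 <= i <= n - 2 (kappa needs i - 2 and
#' i + 2; alpha at the same i needs i - 1 .. i + 2), so a chain of n
#' residues contributes max(0, n - 4) rows.
#'
#' @param conformation An `fcc_conformation`, or a coordinate matrix.
#' @return Data frame with columns `i`, `kappa`, `alpha` (`alpha` is `NA`
#'   for degenerate fragments).
#' @export
angle_pairs <- function(conformation) {
  coords <- if (inherits(conformation, "fcc_conformation"))
    conformation$coords else as.matrix(conformation)
  n <- nrow(coords)
  idx <- if (n >= 5) 3:(n - 2) else integer(0)
  data.frame(i = idx,
             kappa = vapply(idx, function(i) kappa_angle(coords, i), 0),
             alpha = vapply(idx, function(i) alpha_angle(coords, i), 0))
}

#' The packaged (kappa, alpha) preference matrix
#'
#' Empirical backbone angle preferences binned for the FCC lattice: 13
#' kappa bins (centers 30 to 150 degrees, step 10) by 6 alpha spaces
#' (labelled 60, 80, 180, -130, -110, -10 degrees).  Larger values mark
#' angle combinations frequent in experimentally solved structures; the 30
#' degree row is all zero, so the sharpest lattice bends are always
#' infeasible under the angle constraint.
#'
#' @return A 13 x 6 numeric matrix with kappa-center row names and
#'   alpha-center column names.
#' @export
ka_preferences <- function() {
  path <- system.file("extdata", "ka_preferences.tsv", package = "fccfold",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  stopifnot(nrow(m) == 13, ncol(m) == 6, all(m >= 0))
  m
}

#' Bin a (kappa, alpha) pair
#'
#' kappa is rounded to the nearest 10-degree center; values rounding below
#' 30 or above 150 are unbinnable.  alpha is assigned to the nearest of the
#' six space centers by circular distance.
#'
#' @param kappa Bend angle in degrees, \[0, 180\].
#' @param alpha Signed dihedral in degrees, (-180, 180\], or `NA`.
#' @return A list with `kappa_bin` and `alpha_bin` (numeric centers), or
#'   both `NA` when the pair is unbinnable (kappa out of range or alpha
#'   undefined).
#' @export
bin_angle_pair <- function(kappa, alpha) {
  if (is.na(kappa) || is.na(alpha))
    return(list(kappa_bin = NA_real_, alpha_bin = NA_real_))
  kb <- round(kappa / 10) * 10
  if (kb < 30 || kb > 150)
    return(list(kappa_bin = NA_real_, alpha_bin = NA_real_))
  d <- abs((alpha - .alpha_centers + 180) %% 360 - 180)
  list(kappa_bin = kb, alpha_bin = .alpha_centers[which.min(d)])
}

#' Preference value of a binned pair
#'
#' @param kappa_bin,alpha_bin Bin centers as returned by
#'   [bin_angle_pair()]; `NA` (unbinnable) scores 0.
#' @param matrix Preference matrix, see [ka_preferences()].
#' @return Non-negative scalar.
#' @export
angle_preference <- function(kappa_bin, alpha_bin, matrix = ka_preferences()) {
  if (is.na(kappa_bin) || is.na(alpha_bin)) return(0)
  matrix[as.character(kappa_bin), as.character(alpha_bin)]
}

#' Backbone angle preference energy K^KA
#'
#' The negated sum of preference values over every residue position where
#' both kappa and alpha are defined.  Negation puts the term on a free
#' energy scale where lower is better, matching the contact energies.
#'
#' @param conformation An `fcc_conformation` with n >= 5 (shorter chains
#'   have no defined pairs and score 0, with a warning).
#' @param matrix Preference matrix.
#' @return Non-positive scalar.
#' @export
ka_energy <- function(conformation, matrix = ka_preferences()) {
  ap <- angle_pairs(conformation)
  if (nrow(ap) == 0) {
    warning("chain too short for any (kappa, alpha) pair; K^KA = 0")
    return(0)
  }
  -sum(vapply(seq_len(nrow(ap)), function(r) {
    b <- bin_angle_pair(ap$kappa[r], ap$alpha[r])
    angle_preference(b$kappa_bin, b$alpha_bin, matrix)
  }, 0))
}

#' Angle feasibility constraint (FCC')
#'
#' A conformation is angle-feasible when every defined (kappa, alpha) pair
#' is non-degenerate and bins to a strictly positive preference cell.
#' Chains too short to define any pair pass vacuously.
#'
#' @inheritParams ka_energy
#' @return Logical scalar.
#' @export
check_angle_constraint <- function(conformation, matrix = ka_preferences()) {
  ap <- angle_pairs(conformation)
  for (r in seq_len(nrow(ap))) {
    if (is.na(ap$alpha[r])) return(FALSE)
    k <- ap$kappa[r]
    if (k < .deg_tol || k > 180 - .deg_tol) return(FALSE)
    b <- bin_angle_pair(k, ap$alpha[r])
    if (is.na(b$kappa_bin)) return(FALSE)
    if (angle_preference(b$kappa_bin, b$alpha_bin, matrix) <= 0) return(FALSE)
  }
  TRUE
}

#' Enumerate all realizable (kappa, alpha) pairs
#'
#' Exhaustively enumerates every self-avoiding 5-point FCC fragment (first
#' point at the origin, first move fixed to label 1 to quotient out
#' translation and one direction choice; the lattice point group makes the
#' realized angle set independent of that choice), computes (kappa, alpha)
#' at the center residue, and drops degenerate fragments (colinear
#' endpoints or undefined torsion).
#'
#' @return Data frame with columns `moves` (the three free move labels,
#'   space-separated), `kappa`, `alpha`.
#' @export
enumerate_angle_pairs <- function() {
  res <- vector("list", 1728)
  k <- 0
  for (m2 in 1:12) for (m3 in 1:12) for (m4 in 1:12) {
    P <- matrix(0, 5, 3)
    P[2, ] <- .fcc_vec[1, ]
    P[3, ] <- P[2, ] + .fcc_vec[m2, ]
    P[4, ] <- P[3, ] + .fcc_vec[m3, ]
    P[5, ] <- P[4, ] + .fcc_vec[m4, ]
    if (anyDuplicated(P)) next
    ka <- kappa_angle(P, 3)
    if (ka < .deg_tol || ka > 180 - .deg_tol) next
    al <- alpha_angle(P, 3)
    if (is.na(al)) next
    k <- k + 1
    res[[k]] <- data.frame(moves = paste(1, m2, m3, m4), kappa = ka,
                           alpha = al)
  }
  do.call(rbind, res[seq_len(k)])
}

#' Discrete angle spaces realized on the lattice
#'
#' Clusters the realized values of [enumerate_angle_pairs()] with a merge
#' tolerance.  Because the lattice point group contains reflections, every
#' chiral fragment has a mirror image on the lattice, so realized alpha
#' values come in +/- pairs; the discrete alpha spaces are therefore the
#' clusters of |alpha| (mirror-identified), while kappa clusters plainly.
#'
#' @param pairs Output of [enumerate_angle_pairs()] (recomputed when
#'   missing).
#' @param tol Merge tolerance in degrees.
#' @return List with `kappa` (sorted cluster centers of kappa) and `alpha`
#'   (sorted cluster centers of |alpha|).
#' @export
angle_spaces <- function(pairs = enumerate_angle_pairs(), tol = 5) {
  cluster1d <- function(x) {
    x <- sort(unique(round(x, 6)))
    groups <- cumsum(c(TRUE, diff(x) > tol))
    as.numeric(tapply(x, groups, mean))
  }
  list(kappa = cluster1d(pairs$kappa), alpha = cluster1d(abs(pairs$alpha)))
}
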