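# Variation operators: rotation-based crossover, the generalized pull move,
# and K-site mutation.  All operators preserve self-avoidance; angle
# feasibility is enforced by an optional `valid` predicate so the
# multi-objective engine can discard constraint violations at the source.

# Rodrigues rotation matrix about unit axis, rounded to the exact integer
# lattice symmetry
.rot_mat <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  round(R)
}

#' The 17 crossover rotations
#'
#' The fixed-axis lattice rotations used by [rotation_crossover()]: the
#' square-based family (the three coordinate axes, each at 90, 180 and 270
#' degrees; 9 rotations) and the triangle-hexagon-based family (the four
#' body-diagonal 3-fold axes, each at 120 and 240 degrees; 8 rotations).
#' Every matrix is an integer orthogonal matrix with determinant +1, so it
#' maps the FCC lattice onto itself.
#'
#' @return A list of 17 named 3 x 3 integer matrices; names encode family,
#'   axis and angle, and each matrix carries a `family` attribute
#'   (`"square"` or `"trihex"`).
#' @export
crossover_rotations <- function() {
  out <- list()
  axes_sq <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  for (ax in names(axes_sq)) for (ang in c(90, 180, 270)) {
    m <- .rot_mat(axes_sq[[ax]], ang)
    attr(m, "family") <- "square"
    out[[paste0("square_", ax, "_", ang)]] <- m
  }
  axes_th <- list(ppp = c(1, 1, 1), ppm = c(1, 1, -1),
                  pmp = c(1, -1, 1), mpp = c(-1, 1, 1))
  for (ax in names(axes_th)) for (ang in c(120, 240)) {
    m <- .rot_mat(axes_th[[ax]], ang)
    attr(m, "family") <- "trihex"
    out[[paste0("trihex_", ax, "_", ang)]] <- m
  }
  out
}

.crossover_rots <- crossover_rotations()

#' Rotation-based crossover
#'
#' One-point crossover with rigid-body re-attachment: a crossover point G
#' is drawn uniformly; the head of `parent1` (residues 1..G) is kept, the
#' tail of `parent2` (residues G..n) is translated so its first point
#' coincides with the head's end, and each of the 17 lattice rotations
#' about G is applied to the tail.  Offspring that self-intersect (or fail
#' `valid`) are discarded, so a single crossover yields between 0 and 17
#' children.  Searching re-attachment orientations is what lifts the
#' success rate of naive one-point crossover on a rigid lattice chain.
#'
#' @param parent1,parent2 `fcc_conformation`s over the same sequence.
#' @param point Optional crossover point in 2..(n - 1); drawn uniformly
#'   when `NULL`.
#' @param valid Optional predicate `function(conformation) logical`;
#'   offspring failing it are discarded.
#' @return List of 0 to 17 `fcc_conformation` offspring.
#' @export
rotation_crossover <- function(parent1, parent2, point = NULL, valid = NULL) {
  if (parent1$sequence != parent2$sequence)
    stop("parents must share the same sequence")
  n <- nrow(parent1$coords)
  if (n < 3) return(list())
  g <- if (is.null(point)) sample(2:(n - 1), 1) else point
  stopifnot(g >= 2, g <= n - 1)
  head_coords <- parent1$coords[1:g, , drop = FALSE]
  pivot <- parent1$coords[g, ]
  tail_rel <- sweep(parent2$coords[g:n, , drop = FALSE], 2,
                    parent2$coords[g, ])
  kids <- list()
  for (R in .crossover_rots) {
    rot_tail <- tail_rel %*% t(R)
    coords <- rbind(head_coords,
                    sweep(rot_tail[-1, , drop = FALSE], 2, pivot, "+"))
    if (!.is_saw(coords)) next
    kid <- conformation_from_coords(parent1$sequence, coords)
    if (!is.null(valid) && !valid(kid)) next
    kids[[length(kids) + 1]] <- kid
  }
  kids
}

#' Generalized pull move
#'
#' Selects a random bonded pair (P_i, P_(i+1)), relocates P_(i+1) to an
#' unoccupied lattice point adjacent to P_i (when P_(i+2) exists the
#' candidate must also neighbour the old P_(i+1), which guarantees the
#' pulled chain stays a valid walk), then pulls each downstream residue
#' into its predecessor's former position until the chain reconnects.
#' When no candidate exists the conformation is returned unchanged.
#'
#' @param conformation An `fcc_conformation`.
#' @param valid Optional predicate; candidate results failing it are
#'   skipped (falling back to the unchanged input if none passes).
#' @return An `fcc_conformation`, always a valid self-avoiding walk.
#' @export
generalized_pull_move <- function(conformation, valid = NULL) {
  coords <- conformation$coords
  n <- nrow(coords)
  if (n < 2) return(conformation)
  i <- if (n == 2) 1 else sample(n - 1, 1)
  nb <- fcc_neighbors(coords[i, ])
  occ_key <- coords[, 1] * 1e6 + coords[, 2] * 1e3 + coords[, 3]
  nb_key <- nb[, 1] * 1e6 + nb[, 2] * 1e3 + nb[, 3]
  free <- !(nb_key %in% occ_key)
  if (i + 2 <= n) {
    # must also neighbour the old P_(i+1) so the shifted tail reconnects
    d <- sweep(nb, 2, coords[i + 1, ])
    free <- free & (rowSums(d * d) == 2)
  }
  cand <- which(free)
  if (!length(cand)) return(conformation)
  for (k in sample(length(cand))) {
    new_coords <- coords
    new_coords[i + 1, ] <- nb[cand[k], ]
    j <- i + 2
    while (j <= n) {
      dd <- coords[j, ] - new_coords[j - 1, ]
      if (sum(dd * dd) == 2) break
      new_coords[j, ] <- coords[j - 1, ]
      j <- j + 1
    }
    if (!.is_saw(new_coords)) next
    res <- conformation_from_coords(conformation$sequence, new_coords)
    if (!is.null(valid) && !valid(res)) next
    return(res)
  }
  conformation
}

#' K-site mutation
#'
#' Redraws the move labels of a random window of `k` consecutive positions
#' and re-decodes the chain; the window keeps changes local so the global
#' fold is not destroyed.  Mutants that self-intersect (or fail `valid`)
#' are rejected and the draw repeated up to `tries` times, after which the
#' input is returned unchanged.
#'
#' @param conformation An `fcc_conformation`.
#' @param k Window width in move positions (clamped to n - 1).
#' @param tries Retry bound.
#' @param valid Optional predicate applied to the mutant.
#' @return An `fcc_conformation`, always a valid self-avoiding walk.
#' @export
k_site_mutation <- function(conformation, k = 3, tries = 50, valid = NULL) {
  moves <- conformation$moves
  m <- length(moves)
  if (m < 1) return(conformation)
  k <- min(k, m)
  for (t in seq_len(tries)) {
    w <- sample(m - k + 1, 1)
    new_moves <- moves
    new_moves[w:(w + k - 1)] <- sample(12, k, replace = TRUE)
    steps <- .fcc_vec[new_moves, , drop = FALSE]
    coords <- rbind(c(0, 0, 0),
                    if (m == 1) steps else apply(steps, 2, cumsum))
    if (!.is_saw(coords)) next
    res <- structure(list(sequence = conformation$sequence,
                          moves = new_moves, coords = coords),
                     class = "fcc_conformation")
    dimnames(res$coords) <- list(NULL, c("x", "y", "z"))
    if (!is.null(valid) && !valid(res)) next
    return(res)
  }
  conformation
}
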