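# FCC lattice geometry and the 12-letter move alphabet.
#
# Lattice points are integer 3-vectors whose neighbours sit at the 12
# displacement vectors with two components in {-1,+1} and one 0 (squared
# step length 2).  A conformation is a self-avoiding walk (SAW) over these
# steps, encoded either as coordinates or as a string of direction labels
# 1..12.

.fcc_names <- c("FL", "FR", "FU", "FD", "BL", "BR", "BU", "BD",
                "LU", "LD", "RU", "RD")

# label order 1..12; BR is (+1, 0, -1) so that the 12 vectors are pairwise
# distinct and closed under negation
.fcc_vec <- matrix(c(
   1,  1,  0,
   1, -1,  0,
  -1,  1,  0,
  -1, -1,  0,
   1,  0,  1,
   1,  0, -1,
  -1,  0,  1,
  -1,  0, -1,
   0,  1,  1,
   0,  1, -1,
   0, -1,  1,
   0, -1, -1), ncol = 3, byrow = TRUE,
  dimnames = list(.fcc_names, c("x", "y", "z")))

# lattice step length in Angstrom after scaling (mean Calpha-Calpha distance)
.ca_step <- 3.8

#' The 12 FCC lattice directions
#'
#' Returns the move alphabet of the face-centered cubic lattice: 12 unit
#' steps, labelled 1 to 12, named by fold direction (front/back x
#' left/right/up/down).  Every vector has squared length 2 and the set is
#' closed under negation, so each direction has an inverse in the alphabet.
#'
#' @return A data frame with columns `label` (integer 1..12), `name`
#'   (two-letter direction code) and `x`, `y`, `z` (integer components).
#' @examples
#' fcc_directions()
#' @export
fcc_directions <- function() {
  data.frame(label = 1:12, name = .fcc_names,
             x = .fcc_vec[, 1], y = .fcc_vec[, 2], z = .fcc_vec[, 3],
             row.names = NULL)
}

#' Neighbours of an FCC lattice point
#'
#' @param point Integer 3-vector.
#' @return A 12 x 3 integer matrix: `point` plus each direction vector.
#' @examples
#' fcc_neighbors(c(0, 0, 0))
#' @export
fcc_neighbors <- function(point) {
  stopifnot(length(point) == 3, all(point == round(point)))
  sweep(.fcc_vec, 2, as.numeric(point), "+")
}

# squared distances between consecutive rows of a coordinate matrix
.step_sqlen <- function(coords) {
  d <- diff(coords)
  rowSums(d * d)
}

# TRUE iff coords is a valid FCC self-avoiding walk
.is_saw <- function(coords) {
  if (nrow(coords) < 1) return(FALSE)
  if (nrow(coords) == 1) return(TRUE)
  all(.step_sqlen(coords) == 2) && !anyDuplicated(coords)
}

# first duplicated row index, 0 if none
.first_collision <- function(coords) anyDuplicated(coords)

# map consecutive coordinate differences back to direction labels 1..12
.moves_from_coords <- function(coords) {
  d <- diff(coords)
  key <- d[, 1] * 16 + d[, 2] * 4 + d[, 3]
  dirkey <- .fcc_vec[, 1] * 16 + .fcc_vec[, 2] * 4 + .fcc_vec[, 3]
  m <- match(key, dirkey)
  if (anyNA(m)) stop("coordinate steps are not FCC unit steps")
  m
}

#' Construct a conformation from a sequence and coordinates
#'
#' @param sequence Amino-acid string (one-letter codes), length n.
#' @param coords n x 3 integer matrix of lattice points.
#' @return An object of class `fcc_conformation`: a list with elements
#'   `sequence`, `moves` (integer vector of length n - 1) and `coords`
#'   (n x 3 integer matrix, first point at the origin).
#' @export
conformation_from_coords <- function(sequence, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nchar(sequence)
  if (nrow(coords) != n)
    stop("sequence length (", n, ") does not match number of points (",
         nrow(coords), ")")
  moves <- .moves_from_coords(coords)
  if (.first_collision(coords) > 0)
    stop("self-intersecting walk: point ", .first_collision(coords),
         " revisits an occupied site")
  # canonicalize: translate first point to the origin
  coords <- sweep(coords, 2, coords[1, ])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(sequence = sequence, moves = moves, coords = coords),
            class = "fcc_conformation")
}

#' Decode a move string into a conformation
#'
#' Builds lattice coordinates by cumulative addition of direction vectors
#' from the origin, and checks self-avoidance.
#'
#' @param sequence Amino-acid string of length n.
#' @param moves Direction labels: an integer vector of length n - 1, or a
#'   single string of space-separated labels (e.g. `"1 12"`).
#' @return An `fcc_conformation` object.
#' @examples
#' decode_moves("AAA", "1 12")$coords
#' @export
decode_moves <- function(sequence, moves) {
  if (is.character(moves) && length(moves) == 1)
    moves <- as.integer(strsplit(trimws(moves), "[[:space:]]+")[[1]])
  moves <- as.integer(moves)
  n <- nchar(sequence)
  if (length(moves) != n - 1)
    stop("need ", n - 1, " moves for a length-", n, " sequence, got ",
         length(moves))
  if (anyNA(moves) || any(moves < 1L) || any(moves > 12L))
    stop("move symbols must be integers in 1..12")
  steps <- .fcc_vec[moves, , drop = FALSE]
  coords <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  if (n == 2) coords <- rbind(c(0, 0, 0), steps)  # apply() drops to vector
  coll <- .first_collision(coords)
  if (coll > 0)
    stop("self-intersecting walk: point ", coll, " revisits an occupied site")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(sequence = sequence, moves = moves, coords = coords),
            class = "fcc_conformation")
}

#' @export
print.fcc_conformation <- function(x, ...) {
  cat("FCC lattice conformation:", nchar(x$sequence), "residues\n")
  cat("  sequence:", x$sequence, "\n")
  cat("  moves:   ", paste(x$moves, collapse = " "), "\n")
  invisible(x)
}

#' Topological contact pairs of a conformation
#'
#' Two residues i < j are in contact when they are lattice neighbours
#' (squared distance 2) and are not adjacent along the chain (j >= i + 2).
#'
#' @param conformation An `fcc_conformation`.
#' @return A two-column integer matrix of (i, j) pairs, possibly 0-row.
#' @export
contact_pairs <- function(conformation) {
  coords <- conformation$coords
  n <- nrow(coords)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n < 3) return(out)
  d2 <- as.matrix(stats::dist(coords))^2
  hit <- which(upper.tri(d2) & abs(d2 - 2) < 1e-9, arr.ind = TRUE)
  keep <- hit[, 2] - hit[, 1] >= 2
  hit <- hit[keep, , drop = FALSE]
  if (nrow(hit)) {
    out <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    dimnames(out) <- list(NULL, c("i", "j"))
  }
  out
}

#' Scale lattice coordinates to Angstrom
#'
#' Multiplies integer lattice coordinates by 3.8 / sqrt(2) so that the
#' consecutive Calpha-Calpha distance equals 3.8 Angstrom, the mean spacing
#' observed in real protein backbones.
#'
#' @param conformation An `fcc_conformation`, or a bare coordinate matrix.
#' @return An n x 3 numeric matrix in Angstrom.
#' @export
scale_coordinates <- function(conformation) {
  coords <- if (inherits(conformation, "fcc_conformation"))
    conformation$coords else as.matrix(conformation)
  coords * (.ca_step / sqrt(2))
}

#' Random self-avoiding walk on the FCC lattice
#'
#' Grows a walk one step at a time, choosing uniformly among unoccupied
#' neighbours; a dead end triggers a full restart.  Intended for fixtures
#' and population initialization.
#'
#' @param n Number of residues (>= 2).
#' @param sequence Optional amino-acid string of length `n`; defaults to
#'   poly-alanine.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param max_restarts Attempt cap before giving up.
#' @return An `fcc_conformation`.
#' @export
random_saw <- function(n, sequence = NULL, seed = NULL, max_restarts = 1000) {
  if (n < 2) stop("need n >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequence)) sequence <- strrep("A", n)
  stopifnot(nchar(sequence) == n)
  for (attempt in seq_len(max_restarts)) {
    coords <- matrix(0, n, 3)
    ok <- TRUE
    for (i in 2:n) {
      cand <- fcc_neighbors(coords[i - 1, ])
      cand <- cand[sample.int(12), , drop = FALSE]
      placed <- FALSE
      for (k in 1:12) {
        p <- cand[k, ]
        occ <- FALSE
        for (j in seq_len(i - 1)) {
          if (p[1] == coords[j, 1] && p[2] == coords[j, 2] &&
              p[3] == coords[j, 3]) { occ <- TRUE; break }
        }
        if (!occ) { coords[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(conformation_from_coords(sequence, coords))
  }
  stop("failed to grow a self-avoiding walk of length ", n,
       " in ", max_restarts, " attempts")
}
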