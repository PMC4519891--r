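# Distance-matrix RMSD: structure similarity without superposition.

#' Distance-matrix RMSD (dRMSD)
#'
#' The root of the mean squared difference between the two structures'
#' pairwise Calpha distance matrices, over all choose(n, 2) pairs:
#'
#' \deqn{dRMSD = \sqrt{\sum_{i<j} (c_{ij}^{model} - c_{ij}^{ref})^2 /
#'   \binom{n}{2}}}
#'
#' Being distance-based, it needs no superposition and is invariant under
#' rigid motions and reflections of either argument.  Lattice models should
#' be passed through [scale_coordinates()] first so both structures are in
#' Angstrom.
#'
#' @param model_coords,ref_coords n x 3 numeric coordinate matrices (equal
#'   n >= 2), in Angstrom.
#' @return Non-negative scalar, in Angstrom.
#' @export
drmsd <- function(model_coords, ref_coords) {
  model_coords <- as.matrix(model_coords)
  ref_coords <- as.matrix(ref_coords)
  if (nrow(model_coords) != nrow(ref_coords))
    stop("coordinate sets differ in length (", nrow(model_coords), " vs ",
         nrow(ref_coords), ")")
  if (nrow(model_coords) < 2) stop("need at least 2 points")
  dm <- stats::dist(model_coords)
  dr <- stats::dist(ref_coords)
  sqrt(mean((dm - dr)^2))
}
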