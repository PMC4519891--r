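# Readers and writers: FASTA sequences, Calpha-only PDB, move-string
# files, and the packaged benchmark identifier list.

.aa_three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
               G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
               M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
               S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id` and `sequence` (uppercased); zero
#'   rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 ||
      !any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(data.frame(id = character(0), sequence = character(0)))
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  data.frame(id = names(recs),
             sequence = toupper(vapply(recs, `[[`, "", 1)),
             row.names = NULL)
}

#' Write sequences to a FASTA file
#'
#' @param ids,sequences Character vectors of equal length.
#' @param path Output path.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  seqinr::write.fasta(as.list(sequences), names = ids, file.out = path)
  invisible(path)
}

#' Read Calpha coordinates from a PDB file
#'
#' Extracts the Calpha ATOM records of one chain, in residue order.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; `NULL` takes the first chain present.
#' @return List with `coords` (n x 3 matrix, Angstrom), `sequence`
#'   (one-letter string) and `chain`.
#' @export
read_ca_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  if (length(sel$atom) == 0) stop("no Calpha records in ", path)
  atoms <- pdb$atom[sel$atom, ]
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available: ",
         paste(chains, collapse = ", "))
  atoms <- atoms[atoms$chain == chain, ]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  list(coords = coords,
       sequence = paste(bio3d::aa321(atoms$resid), collapse = ""),
       chain = chain)
}

#' Write a conformation (or coordinates) as a Calpha-only PDB file
#'
#' Lattice conformations are scaled to Angstrom via [scale_coordinates()]
#' first.  Output uses chain A, residue numbers 1..n, occupancy 1.00.
#'
#' @param x An `fcc_conformation`, or an n x 3 coordinate matrix in
#'   Angstrom.
#' @param path Output path.
#' @param sequence Sequence string when `x` is a bare matrix.
#' @export
write_ca_pdb <- function(x, path, sequence = NULL) {
  if (inherits(x, "fcc_conformation")) {
    coords <- scale_coordinates(x)
    sequence <- x$sequence
  } else {
    coords <- as.matrix(x)
    if (is.null(sequence)) sequence <- strrep("A", nrow(coords))
  }
  n <- nrow(coords)
  letters3 <- .aa_three[strsplit(toupper(sequence), "")[[1]]]
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = letters3, elety = rep("CA", n),
                   chain = rep("A", n), o = rep(1, n), b = rep(0, n),
                   elesy = rep("C", n))
  invisible(path)
}

#' Write conformations as a move-string file
#'
#' One record per line: `<id> TAB <sequence> TAB <space-separated moves>`.
#'
#' @param conformations A single `fcc_conformation` or a list of them.
#' @param path Output path.
#' @param ids Record identifiers (defaults to `c1`, `c2`, ...).
#' @export
write_moves <- function(conformations, path, ids = NULL) {
  if (inherits(conformations, "fcc_conformation"))
    conformations <- list(conformations)
  if (is.null(ids)) ids <- paste0("c", seq_along(conformations))
  lines <- vapply(seq_along(conformations), function(k) {
    cf <- conformations[[k]]
    paste(ids[k], cf$sequence, paste(cf$moves, collapse = " "), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a move-string file
#'
#' @param path File written by [write_moves()].
#' @return Named list of `fcc_conformation`s.
#' @export
read_moves <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("line ", k, ": expected 3 tab-separated fields")
    out[[parts[1]]] <- decode_moves(parts[2], parts[3])
  }
  out
}

#' The CB513-derived benchmark identifier list
#'
#' The 75 benchmark identifiers (4-character PDB codes with a chain
#' character or `-` suffix, transcribed verbatim) of the short,
#' low-similarity chains (22-88 residues) used to evaluate the lattice
#' predictors.  Sequences and native structures are not bundled; fetch
#' them separately and pass them as FASTA / PDB inputs.
#'
#' @return Character vector of length 75.
#' @export
benchmark_ids <- function() {
  path <- system.file("extdata", "cb513_benchmark_ids.txt",
                      package = "fccfold", mustWork = TRUE)
  readLines(path)
}
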