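# Contact-based statistical energies: the hydrophobic-polar (HP) model and
# general 20x20 residue contact potentials (CP).

.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
.hydrophobic <- c("C", "F", "I", "L", "M", "V", "W", "Y")

#' Hydrophobic-polar classification of a sequence
#'
#' C, F, I, L, M, V, W and Y are hydrophobic (H); the remaining twelve
#' standard residues (H, A, T, G, P, S, Q, R, N, D, E, K) are polar (P).
#'
#' @param sequence Amino-acid string in one-letter code.
#' @return A string over \{H, P\} of the same length.
#' @examples
#' classify_hp("CFILMVWY")
#' @export
classify_hp <- function(sequence) {
  if (nchar(sequence) == 0) return("")
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters, .aa_letters)
  if (length(bad))
    stop("unknown amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  paste(ifelse(letters %in% .hydrophobic, "H", "P"), collapse = "")
}

#' HP contact energy E^HP
#'
#' Minus the number of lattice contacts between two hydrophobic residues:
#' each H-H pair at squared lattice distance 2 with chain separation >= 2
#' contributes -1.
#'
#' @param conformation An `fcc_conformation`.
#' @return Non-positive integer.
#' @export
hp_energy <- function(conformation) {
  cp <- contact_pairs(conformation)
  if (nrow(cp) == 0) return(0)
  hp <- strsplit(classify_hp(conformation$sequence), "")[[1]]
  -sum(hp[cp[, 1]] == "H" & hp[cp[, 2]] == "H")
}

#' Contact-potential energy E^CP
#'
#' Minus the sum, over all lattice contacts, of the potential entry for the
#' residue pair, using a symmetric 20 x 20 matrix such as the Berrera or
#' Miyazawa-Jernigan statistical potentials (user-supplied).
#'
#' @param conformation An `fcc_conformation`.
#' @param contact_matrix Symmetric numeric matrix with one-letter row and
#'   column names covering every residue in the sequence.
#' @return Scalar energy.
#' @export
cp_energy <- function(conformation, contact_matrix) {
  letters <- strsplit(toupper(conformation$sequence), "")[[1]]
  missing <- setdiff(letters, rownames(contact_matrix))
  if (length(missing))
    stop("contact matrix lacks entries for: ",
         paste(unique(missing), collapse = ", "))
  cp <- contact_pairs(conformation)
  if (nrow(cp) == 0) return(0)
  -sum(contact_matrix[cbind(letters[cp[, 1]], letters[cp[, 2]])])
}

#' Read a contact-potential matrix from TSV
#'
#' Expects a header row and first column of one-letter residue codes and a
#' 20 x 20 numeric body; symmetry is validated on load.
#'
#' @param path File path.
#' @return A 20 x 20 symmetric numeric matrix.
#' @export
read_contact_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(.aa_letters %in% rownames(m)) || !all(.aa_letters %in% colnames(m)))
    stop("contact matrix must cover all 20 standard residues")
  m <- m[.aa_letters, .aa_letters]
  if (max(abs(m - t(m))) > 1e-9)
    stop("contact matrix is not symmetric")
  m
}

#' Write a contact-potential matrix to TSV
#'
#' @param matrix 20 x 20 symmetric matrix with residue-letter dimnames.
#' @param path File path.
#' @export
write_contact_matrix <- function(matrix, path) {
  df <- data.frame(aa = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
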