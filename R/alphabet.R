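# Canonical residue alphabet, fixed order. Position in this string is the
# one-hot index; everything outside it (X, B, Z, U, O, J, gaps) is the
# "unknown" class and encodes to the all-zero vector.
AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"
AA_LETTERS <- strsplit(AA_ALPHABET, "")[[1]]

# Window geometry of the detector: two 19-residue helix windows flanking a
# central residue, 39 encoded positions of 20 channels each.
HELIX_WINDOW <- 19L
WINDOW_POSITIONS <- 2L * HELIX_WINDOW + 1L   # 39
N_ALPHABET <- 20L
INPUT_SIZE <- WINDOW_POSITIONS * N_ALPHABET  # 780
N_HIDDEN <- 3L

#' Residue alphabet used by the detector
#'
#' The 20 canonical amino-acid one-letter codes in the fixed order that
#' defines the one-hot encoding of the network input layer. Any other
#' letter (ambiguity codes such as X, B, Z, or the rare U, O, J) belongs to
#' a single "unknown" class that encodes to the all-zero vector, so that
#' scanning never aborts on database sequences containing them.
#'
#' @return Character vector of the 20 canonical residues.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_LETTERS

# Integer indices (1..20, NA for unknown) for a residue string.
aa_indices <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  match(chars, AA_LETTERS)
}

#' One-hot encode a single residue
#'
#' Canonical residues map to a unit vector of length 20 (1 at the residue's
#' alphabet index); any non-canonical character maps to the all-zero vector.
#' Total function: never errors.
#'
#' @param residue Single character.
#' @return Numeric vector of length 20.
#' @export
#' @examples
#' encode_residue("A")
#' sum(encode_residue("X"))  # 0: unknown class
encode_residue <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  v <- numeric(N_ALPHABET)
  i <- match(toupper(residue), AA_LETTERS)
  if (!is.na(i)) v[i] <- 1
  v
}

#' One-hot encode a detection window
#'
#' Concatenates the 20-dimensional encodings of the residues at the given
#' sequence positions (position-major), producing the network input vector.
#' Positions holding non-canonical residues contribute all-zero blocks.
#'
#' @param residues Residue string (one sequence).
#' @param positions Integer vector of 1-based sequence positions, typically
#'   the 39 positions returned by [window_positions()].
#' @return Numeric 0/1 vector of length `20 * length(positions)`.
#' @export
encode_window <- function(residues, positions) {
  idx <- aa_indices(residues)[positions]
  v <- numeric(N_ALPHABET * length(positions))
  ok <- !is.na(idx)
  v[(which(ok) - 1L) * N_ALPHABET + idx[ok]] <- 1
  v
}

# Active input indices of a window (the sparse counterpart of
# encode_window): one index per canonical residue, none for unknowns.
window_active_indices <- function(aa_idx, positions) {
  a <- aa_idx[positions]
  ok <- !is.na(a)
  (which(ok) - 1L) * N_ALPHABET + a[ok]
}
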