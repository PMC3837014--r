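# Window-shift scanning. Each tested central residue is evaluated under
# four combinations of outward displacements of the two 19-residue helix
# windows, realizing helix-helix linkers of 1 to 3 residues; the maximum
# score and the winning displacement are reported.

# The four shift combinations in tie-break preference order
# (smallest implied linker first).
SHIFT_COMBOS <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))

shift_label <- function(combo) paste(combo[1], combo[2], sep = "/")

# Offsets of the 39 encoded positions relative to the center for a combo:
# H1 block of 19 ending at center-1-h1, the center itself, H2 block of 19
# starting at center+1+h2. The residues skipped by a shifted window are
# simply not encoded, keeping the input layer at 39 x 20.
window_offsets <- function(combo) {
  s1 <- combo[1]; s2 <- combo[2]
  c((-HELIX_WINDOW - s1):(-1L - s1), 0L, (1L + s2):(HELIX_WINDOW + s2))
}

#' Detection-window positions for a center and shift combination
#'
#' Returns the 39 sequence positions encoded when the detection window is
#' centred at `center` under shift combination `combo`: 19 positions for
#' the first helix ending at `center - 1 - h1_shift`, the center itself,
#' and 19 positions for the second helix starting at `center + 1 + h2_shift`.
#'
#' @param center 1-based center position.
#' @param combo Integer vector `c(h1_shift, h2_shift)`, each 0 or 1.
#' @param length Sequence length.
#' @return Integer vector of 39 positions, or `NULL` if any position falls
#'   outside `[1, length]`.
#' @export
#' @examples
#' window_positions(21, c(0L, 0L), 60)  # 2..20, 21, 22..40
#' window_positions(20, c(1L, 0L), 60)  # NULL: first helix would need position 0
window_positions <- function(center, combo, length) {
  stopifnot(combo[1] %in% 0:1, combo[2] %in% 0:1)
  pos <- center + window_offsets(as.integer(combo))
  if (pos[1] < 1L || pos[length(pos)] > length) return(NULL)
  pos
}

#' Score one position under all in-bounds shift combinations
#'
#' Evaluates the network on each shift combination whose window fits the
#' sequence and returns the maximum score together with the winning
#' combination. Ties prefer the smaller implied linker: (0,0), (1,0),
#' (0,1), (1,1).
#'
#' @param net An `ard_net`.
#' @param residues Residue string.
#' @param center 1-based position to test.
#' @param shifts If `FALSE`, only the unshifted combination (0,0) is
#'   evaluated (the fixed-linker mode of the predecessor detector).
#' @return List with `score` and `combo`, or `NULL` when no combination is
#'   in bounds.
#' @export
score_position <- function(net, residues, center, shifts = TRUE) {
  validate_net(net)
  L <- nchar(residues)
  ai <- aa_indices(residues)
  combos <- if (shifts) SHIFT_COMBOS else SHIFT_COMBOS[1]
  best <- NULL
  for (combo in combos) {
    pos <- window_positions(center, combo, L)
    if (is.null(pos)) next
    s <- nn_forward_idx(net, window_active_indices(ai, pos))
    if (is.null(best) || s > best$score) best <- list(score = s, combo = combo)
  }
  best
}

#' Scan a sequence into a per-residue score profile
#'
#' Slides the detection window over every scorable center (positions 20 to
#' L-19, those admitting the unshifted window), scores each under the
#' in-bounds shift combinations and records the maximum with its winning
#' shift. Sequences shorter than 39 residues yield an empty profile.
#'
#' @param net An `ard_net`.
#' @param residues Residue string.
#' @param id Sequence identifier stored in the profile.
#' @param shifts If `FALSE`, disable window shifts (combination (0,0) only).
#' @return A `score_profile`: data frame with columns `position`, `residue`,
#'   `score`, `shift`, ordered by position, sequence id in attribute `"id"`.
#' @export
scan_sequence <- function(net, residues, id = "seq", shifts = TRUE) {
  validate_net(net)
  L <- nchar(residues)
  chars <- strsplit(toupper(residues), "")[[1]]
  if (L < WINDOW_POSITIONS) {
    return(new_score_profile(integer(0), character(0), numeric(0),
                             character(0), id))
  }
  ai <- match(chars, AA_LETTERS)
  E <- matrix(0, N_ALPHABET, L)
  ok <- !is.na(ai)
  E[cbind(ai[ok], which(ok))] <- 1

  centers <- (HELIX_WINDOW + 1L):(L - HELIX_WINDOW)
  n <- length(centers)
  combos <- if (shifts) SHIFT_COMBOS else SHIFT_COMBOS[1]
  Warr <- array(net$W, dim = c(N_ALPHABET, WINDOW_POSITIONS, N_HIDDEN))
  scores <- matrix(-Inf, length(combos), n)
  for (k in seq_along(combos)) {
    combo <- combos[[k]]
    sub <- centers >= HELIX_WINDOW + 1L + combo[1] &
           centers <= L - HELIX_WINDOW - combo[2]
    if (!any(sub)) next
    cs <- centers[sub]
    offs <- window_offsets(combo)
    H <- matrix(net$b_h, N_HIDDEN, length(cs))
    for (s in seq_len(WINDOW_POSITIONS)) {
      Ws <- matrix(Warr[, s, ], N_ALPHABET, N_HIDDEN)
      H <- H + crossprod(Ws, E[, cs + offs[s], drop = FALSE])
    }
    h <- sigmoid(H)
    scores[k, sub] <- sigmoid(net$b_o + as.vector(crossprod(net$w_o, h)))
  }
  win <- apply(scores, 2L, which.max)  # first max = preference order
  best <- scores[cbind(win, seq_len(n))]
  labels <- vapply(combos, shift_label, character(1))[win]
  new_score_profile(centers, chars[centers], best, labels, id)
}
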