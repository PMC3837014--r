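#' Read protein sequences from a FASTA file
#'
#' Reads single- or multi-record FASTA. Sequence letters are upper-cased and
#' trailing `*` stop characters stripped; record order is preserved. The
#' identifier is the description line up to the first whitespace (UniProt /
#' PDB convention).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings; names are record ids.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDEFG"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ", paste(ids[empty], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write a per-residue score profile as TSV
#'
#' One row per scored position with columns `id`, `position` (1-based),
#' `residue`, `score` (4 decimals) and `shift` (winning window-shift label,
#' e.g. `"1/0"` for the first helix window displaced by one residue). Rows
#' are ordered by position. A profile with no scorable positions (sequence
#' shorter than the detection window) produces a header-only file.
#'
#' @param profile A `score_profile` as returned by [scan_sequence()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_profile()] for the inverse.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "score_profile"))
  df <- data.frame(
    id = rep(attr(profile, "id"), nrow(profile)),
    position = profile$position,
    residue = profile$residue,
    score = sprintf("%.4f", profile$score),
    shift = profile$shift,
    stringsAsFactors = FALSE
  )
  if (nrow(df)) df <- df[order(df$position), , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write profile to: ", path)
  invisible(path)
}

#' Read a score profile written by [write_profile()]
#'
#' @param path Path to a profile TSV.
#' @return A `score_profile` data frame (scores at the written 4-decimal
#'   precision), with the sequence id in attribute `"id"`.
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "numeric", "character"))
  id <- if (nrow(df)) df$id[1] else NA_character_
  out <- df[, c("position", "residue", "score", "shift")]
  structure(out, class = c("score_profile", "data.frame"), id = id)
}

#' Construct a score profile
#'
#' Builds the per-residue score container produced by [scan_sequence()];
#' exposed so profiles can also be assembled from externally computed
#' scores (for example to re-call hits on published per-position scores).
#'
#' @param position Integer vector of 1-based scored positions.
#' @param score Numeric scores in `[0, 1]`, parallel to `position`.
#' @param residue Residues at the scored positions (defaults to `"X"`).
#' @param shift Winning shift labels (defaults to `"0/0"`).
#' @param id Sequence identifier.
#' @return A `score_profile` data frame, ordered by position.
#' @export
score_profile <- function(position, score, residue = NULL, shift = NULL,
                          id = "seq") {
  stopifnot(length(position) == length(score),
            all(score >= 0 & score <= 1))
  if (is.null(residue)) residue <- rep("X", length(position))
  if (is.null(shift)) shift <- rep("0/0", length(position))
  ord <- order(position)
  new_score_profile(position[ord], residue[ord], score[ord], shift[ord], id)
}

new_score_profile <- function(position, residue, score, shift, id) {
  structure(
    data.frame(position = as.integer(position), residue = residue,
               score = score, shift = shift, stringsAsFactors = FALSE),
    class = c("score_profile", "data.frame"), id = id
  )
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Score profile for sequence '", attr(x, "id"), "': ",
      nrow(x), " scored positions\n", sep = "")
  if (nrow(x)) {
    cat("  max score ", sprintf("%.4f", max(x$score)),
        " at position ", x$position[which.max(x$score)], "\n", sep = "")
    utils::head(as.data.frame(x), 5) |> print()
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Plot a score profile
#'
#' Needle plot of per-residue detector scores against sequence position,
#' in the style used to display repeat-linker hits along a protein. An
#' optional horizontal line marks the calling threshold.
#'
#' @param x A `score_profile`.
#' @param threshold Optional calling threshold to draw (e.g. 0.87).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.score_profile <- function(x, threshold = NULL, ...) {
  graphics::plot(x$position, x$score, type = "h", ylim = c(0, 1),
                 xlab = "sequence position", ylab = "linker-midpoint score",
                 main = attr(x, "id"), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}
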