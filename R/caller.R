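# Turning score profiles into discrete hits and solenoid calls. A protein
# is called an alpha-solenoid when at least `min_hits` above-threshold hits
# chain with consecutive spacings inside the periodic range [30, 135].

#' Calling parameters
#'
#' Defaults are the published operating point: score threshold 0.87, a
#' minimum of 3 chained hits, consecutive-hit spacing within 30 to 135
#' residues (endpoints inclusive). The suppression radius controls
#' non-maximum suppression of adjacent above-threshold positions belonging
#' to the same linker; it is kept below the minimum spacing so suppression
#' can never merge hits from consecutive repeats.
#'
#' @param threshold Score threshold in (0, 1); hits require score >= threshold.
#' @param min_hits Minimum chain length for a positive call (>= 1).
#' @param spacing Length-2 numeric, inclusive `[min, max]` allowed distance
#'   between consecutive chained hits.
#' @param radius Non-maximum suppression radius in residues.
#' @return List of class `calling_params`.
#' @export
calling_params <- function(threshold = 0.87, min_hits = 3L,
                           spacing = c(30, 135), radius = 10L) {
  stopifnot(threshold > 0, threshold < 1, min_hits >= 1,
            length(spacing) == 2L, spacing[1] > 0, spacing[1] <= spacing[2],
            radius >= 0)
  structure(list(threshold = threshold, min_hits = as.integer(min_hits),
                 spacing = as.numeric(spacing), radius = as.numeric(radius)),
            class = "calling_params")
}

#' Discretize a score profile into hits
#'
#' Positions scoring at or above the threshold are kept, then non-maximum
#' suppression removes, among above-threshold positions within the
#' suppression radius of one another, all but the locally maximal one (ties
#' keep the smaller position). Without suppression the network often scores
#' several adjacent residues of a single linker above threshold, which
#' would fake periodicity.
#'
#' @param profile A `score_profile`.
#' @param params A [calling_params()].
#' @return Data frame of hits (`position`, `score`, `shift`), sorted by
#'   position.
#' @export
find_hits <- function(profile, params = calling_params()) {
  stopifnot(inherits(profile, "score_profile"))
  cand <- profile[profile$score >= params$threshold, , drop = FALSE]
  cand <- as.data.frame(cand)[, c("position", "score", "shift")]
  if (nrow(cand) <= 1L) return(cand[order(cand$position), , drop = FALSE])
  # consider candidates best-first (ties: smaller position), keep those not
  # within the radius of an already-kept stronger hit
  ord <- order(-cand$score, cand$position)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(cand$position[kept] - cand$position[i]) > params$radius))
      kept <- c(kept, i)
  }
  out <- cand[sort(kept), , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Longest periodically spaced chain of hits
#'
#' Finds the longest subsequence of the (position-sorted) hits whose every
#' consecutive pair is separated by a distance inside the spacing interval.
#' Ties on length are broken by higher total score, then by smaller start
#' position. Dynamic programming over hits, O(n^2).
#'
#' @param hits Data frame with columns `position` and `score`, sorted by
#'   position (as from [find_hits()]).
#' @param params A [calling_params()].
#' @return The chained subset of `hits` (possibly a single hit or empty).
#' @export
best_chain <- function(hits, params = calling_params()) {
  n <- nrow(hits)
  if (is.null(n) || n <= 1L) return(hits)
  if (is.unsorted(hits$position)) stop("hits must be sorted by position")
  lo <- params$spacing[1]; hi <- params$spacing[2]
  len <- rep(1L, n); tot <- hits$score; start <- hits$position
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gap <- hits$position[i] - hits$position[j]
      if (gap < lo || gap > hi) next
      cl <- len[j] + 1L
      ct <- tot[j] + hits$score[i]
      cs <- start[j]
      better <- cl > len[i] ||
        (cl == len[i] && (ct > tot[i] || (ct == tot[i] && cs < start[i])))
      if (better) {
        len[i] <- cl; tot[i] <- ct; start[i] <- cs; parent[i] <- j
      }
    }
  }
  best <- which(len == max(len))
  if (length(best) > 1L) best <- best[order(-tot[best], start[best])]
  i <- best[1]
  chain <- i
  while (!is.na(parent[i])) { i <- parent[i]; chain <- c(i, chain) }
  hits[chain, , drop = FALSE]
}

#' Classify a sequence as alpha-solenoid or not
#'
#' Composes [find_hits()] and [best_chain()]: the sequence is called an
#' alpha-solenoid when the best chain contains at least `min_hits` hits.
#'
#' @param profile A `score_profile`.
#' @param params A [calling_params()].
#' @return List of class `solenoid_call` with `id`, `is_solenoid`, `chain`
#'   (the best chain's hits) and `hits` (all hits after suppression).
#' @export
classify_profile <- function(profile, params = calling_params()) {
  hits <- find_hits(profile, params)
  chain <- best_chain(hits, params)
  structure(list(id = attr(profile, "id"),
                 is_solenoid = nrow(chain) >= params$min_hits,
                 chain = chain, hits = hits, params = params),
            class = "solenoid_call")
}

#' @export
print.solenoid_call <- function(x, ...) {
  cat("Sequence '", x$id, "': ",
      if (x$is_solenoid) "alpha-solenoid" else "no alpha-solenoid call",
      "\n", sep = "")
  cat("  hits above threshold ", x$params$threshold, ": ", nrow(x$hits),
      "; best chain length: ", nrow(x$chain), "\n", sep = "")
  if (nrow(x$chain))
    cat("  chain positions: ", paste(x$chain$position, collapse = "; "), "\n",
        sep = "")
  invisible(x)
}

# One-row summary used for tabular call output (Table-style:
# positions semicolon-joined).
call_row <- function(call) {
  data.frame(id = call$id,
             is_solenoid = call$is_solenoid,
             n_hits = nrow(call$hits),
             chain_positions = paste(call$chain$position, collapse = ";"),
             chain_scores = paste(sprintf("%.4f", call$chain$score),
                                  collapse = ";"),
             stringsAsFactors = FALSE)
}
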