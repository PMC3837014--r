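# Synthetic alpha-solenoid and background sequence generation with known
# linker annotations. The compositions are coarse biophysical caricatures
# (amphipathic helices, turn-biased linkers, average globular background),
# built to carry learnable signal for the detector pipeline, not to imitate
# any particular repeat family.

# Helix composition: hydrophobic residues on heptad a/d-like positions
# (3.6 residues/turn), polar/charged elsewhere. Proline is excluded.
HELIX_HYDROPHOBIC <- c("L", "A", "I", "V", "M", "F")
HELIX_POLAR <- c("E", "K", "Q", "R", "D", "N", "S", "T")

# Turn-biased linker composition.
LINKER_RESIDUES <- c("G", "P", "D", "N", "S")

# Average globular amino-acid frequencies (Swiss-Prot-style composition)
# used for background sequence and flanks.
BACKGROUND_FREQS <- c(
  A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
  I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
  R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
)

#' Generate one synthetic helix
#'
#' Residues follow an amphipathic pattern: hydrophobic residues (L, A, I,
#' V, M, F) at heptad-like a/d positions approximating the 3.6-residue
#' helical turn, polar/charged residues (E, K, Q, R, D, N, S, T) elsewhere.
#' Proline never occurs. Draws come from the current RNG stream; seed the
#' stream (or use [make_corpus()]) for reproducibility.
#'
#' @param length Helix length in residues (>= 1).
#' @return Residue string of the requested length.
#' @export
make_helix <- function(length) {
  stopifnot(length >= 1)
  i <- seq_len(length)
  hyd <- (i %% 7L) %in% c(1L, 4L)   # heptad a/d-like positions
  res <- character(length)
  res[hyd] <- sample(HELIX_HYDROPHOBIC, sum(hyd), replace = TRUE)
  res[!hyd] <- sample(HELIX_POLAR, sum(!hyd), replace = TRUE)
  paste(res, collapse = "")
}

#' Generate one synthetic helix-helix linker
#'
#' Residues are drawn uniformly from the turn-biased set G, P, D, N, S.
#'
#' @param length Linker length: 1, 2 or 3.
#' @return Residue string.
#' @export
make_linker <- function(length) {
  if (!(length %in% 1:3)) stop("linker length must be 1, 2 or 3")
  paste(sample(LINKER_RESIDUES, length, replace = TRUE), collapse = "")
}

#' Specification of a synthetic alpha-solenoid
#'
#' Defaults encode the canonical anatomy: repeat units of two helices
#' separated by a 1-3 residue linker, 0-2 residue inter-unit spacers, and
#' unit periods inside the 30-40 residue range expected of stacked helical
#' repeats. With the default 16-residue helices, consecutive linker
#' midpoints are 33-37 residues apart. Flanks are background-composition
#' sequence long enough that every annotated midpoint admits a full
#' detection window.
#'
#' @param n_units Number of repeat units (>= 1).
#' @param helix_len Helix length in residues (fixed).
#' @param linker_lens Linker lengths to draw from, a subset of 1:3.
#' @param spacer_lens Inter-unit spacer lengths to draw from.
#' @param flank_range Length-2 range of N-/C-flank lengths.
#' @param period_range Length-2 admissible range of consecutive midpoint
#'   gaps; generation errors out if the implied periods fall outside it.
#' @return List of class `solenoid_spec`.
#' @export
solenoid_spec <- function(n_units = 5L, helix_len = 16L, linker_lens = 1:3,
                          spacer_lens = 0:2, flank_range = c(25L, 60L),
                          period_range = c(30L, 40L)) {
  stopifnot(n_units >= 1, helix_len >= 1, all(linker_lens %in% 1:3),
            all(spacer_lens >= 0), length(flank_range) == 2L,
            flank_range[1] >= HELIX_WINDOW + 2L,
            length(period_range) == 2L)
  implied <- 2L * helix_len + range(linker_lens) + range(spacer_lens)
  if (implied[1] < period_range[1] || implied[2] > period_range[2])
    stop("implied unit periods [", implied[1], ", ", implied[2],
         "] fall outside the period range [", period_range[1], ", ",
         period_range[2], "]")
  structure(list(n_units = as.integer(n_units), helix_len = as.integer(helix_len),
                 linker_lens = as.integer(linker_lens),
                 spacer_lens = as.integer(spacer_lens),
                 flank_range = as.integer(flank_range),
                 period_range = as.integer(period_range)),
            class = "solenoid_spec")
}

random_background_string <- function(length) {
  paste(sample(names(BACKGROUND_FREQS), length, replace = TRUE,
               prob = BACKGROUND_FREQS), collapse = "")
}

#' Generate one synthetic alpha-solenoid record
#'
#' Builds `N-flank + [helix + linker + helix + spacer] x n + C-flank` and
#' records the true linker midpoints: the central linker residue, taking
#' the left of the two central residues for even linker lengths (a fixed
#' convention; the window-shift scheme absorbs the +/-1 ambiguity).
#'
#' @param spec A [solenoid_spec()].
#' @param id Record identifier.
#' @return List of class `synthetic_record` with `id`, `residues`,
#'   `midpoints` (1-based), `label = "solenoid"`.
#' @export
make_solenoid <- function(spec = solenoid_spec(), id = "sol") {
  stopifnot(inherits(spec, "solenoid_spec"))
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  n_flank <- pick(seq(spec$flank_range[1], spec$flank_range[2]))
  c_flank <- pick(seq(spec$flank_range[1], spec$flank_range[2]))
  parts <- random_background_string(n_flank)
  pos <- n_flank
  midpoints <- integer(spec$n_units)
  for (u in seq_len(spec$n_units)) {
    h1 <- make_helix(spec$helix_len)
    ll <- pick(spec$linker_lens)
    lk <- make_linker(ll)
    h2 <- make_helix(spec$helix_len)
    sp <- pick(spec$spacer_lens)
    midpoints[u] <- pos + spec$helix_len + ((ll + 1L) %/% 2L)
    parts <- paste0(parts, h1, lk, h2,
                    if (sp > 0L) random_background_string(sp) else "")
    pos <- pos + 2L * spec$helix_len + ll + sp
  }
  parts <- paste0(parts, random_background_string(c_flank))
  structure(list(id = id, residues = parts, midpoints = midpoints,
                 label = "solenoid"), class = "synthetic_record")
}

#' Generate one background (non-repeat) record
#'
#' Residues are drawn i.i.d. from an average globular composition; the
#' record carries no linker annotations.
#'
#' @param length Sequence length.
#' @param id Record identifier.
#' @return List of class `synthetic_record` with empty `midpoints` and
#'   `label = "background"`.
#' @export
make_background <- function(length, id = "bg") {
  stopifnot(length >= 1)
  structure(list(id = id, residues = random_background_string(length),
                 midpoints = integer(0), label = "background"),
            class = "synthetic_record")
}

#' Generate a labeled synthetic corpus with a train/test split
#'
#' Generates `n_solenoid` solenoid records (unit counts drawn uniformly
#' from `unit_range`) and `n_background` background records (lengths drawn
#' uniformly from `background_lens`), then splits each class 50/50 into
#' disjoint train and test sets. Entirely determined by `seed`.
#'
#' @param n_solenoid,n_background Record counts (>= 0).
#' @param spec A [solenoid_spec()]; its `n_units` field is overridden per
#'   record by a draw from `unit_range`.
#' @param seed Integer seed.
#' @param unit_range Length-2 range of repeat-unit counts per solenoid.
#' @param background_lens Length-2 range of background sequence lengths.
#' @param train_fraction Fraction of each class assigned to training.
#' @return List of class `solenoid_corpus` with elements
#'   `train` (list `sequences`, `midpoints`) usable as a training corpus,
#'   `test` (list `sequences`, `labels`) usable as a labeled set,
#'   and `records` (data frame `id`, `label`, `split`).
#' @export
make_corpus <- function(n_solenoid, n_background, spec = solenoid_spec(),
                        seed = 1L, unit_range = c(3L, 10L),
                        background_lens = c(150L, 500L),
                        train_fraction = 0.5) {
  stopifnot(n_solenoid >= 0, n_background >= 0,
            train_fraction >= 0, train_fraction <= 1)
  withr::with_seed(as.integer(seed), {
    recs <- vector("list", n_solenoid + n_background)
    for (i in seq_len(n_solenoid)) {
      s <- spec
      s$n_units <- sample(seq(unit_range[1], unit_range[2]), 1L)
      recs[[i]] <- make_solenoid(s, id = sprintf("sol%04d", i))
    }
    for (i in seq_len(n_background)) {
      len <- sample(seq(background_lens[1], background_lens[2]), 1L)
      recs[[n_solenoid + i]] <- make_background(len, id = sprintf("bg%04d", i))
    }
    ids <- vapply(recs, `[[`, character(1), "id")
    labels <- vapply(recs, `[[`, character(1), "label")
    split <- rep("test", length(recs))
    for (lab in unique(labels)) {
      k <- which(labels == lab)
      n_train <- round(train_fraction * length(k))
      split[sample(k, n_train)] <- "train"
    }
    seqs <- stats::setNames(vapply(recs, `[[`, character(1), "residues"), ids)
    mids <- stats::setNames(lapply(recs, `[[`, "midpoints"), ids)
    tr <- split == "train"
    structure(list(
      train = list(sequences = seqs[tr], midpoints = mids[tr]),
      test = list(sequences = seqs[!tr],
                  labels = data.frame(id = ids[!tr],
                                      is_positive = labels[!tr] == "solenoid"),
                  midpoints = mids[!tr]),
      records = data.frame(id = ids, label = labels, split = split,
                           stringsAsFactors = FALSE)
    ), class = "solenoid_corpus")
  })
}

#' @export
print.solenoid_corpus <- function(x, ...) {
  tab <- table(x$records$label, x$records$split)
  cat("Synthetic corpus:", nrow(x$records), "records\n")
  print(tab)
  invisible(x)
}

#' Write a corpus half to FASTA + annotation TSV
#'
#' The annotation TSV has one row per record: id, semicolon-joined linker
#' midpoints (empty for background), label.
#'
#' @param corpus A `solenoid_corpus`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, typically `"train"` or `"test"`.
#' @param split Which split to write.
#' @return Invisibly, the paths written (fasta, annotations, labels).
#' @export
write_corpus <- function(corpus, dir, prefix = "train",
                         split = c("train", "test")) {
  split <- match.arg(split)
  stopifnot(inherits(corpus, "solenoid_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- corpus$records[corpus$records$split == split, , drop = FALSE]
  half <- if (split == "train") corpus$train else corpus$test
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  write_fasta(half$sequences[rec$id], fasta)
  mids <- half$midpoints
  if (is.null(mids)) mids <- stats::setNames(vector("list", nrow(rec)), rec$id)
  ann <- file.path(dir, paste0(prefix, "_annotations.tsv"))
  ann_df <- data.frame(
    id = rec$id,
    midpoints = vapply(rec$id, function(i)
      paste(mids[[i]], collapse = ";"), character(1)),
    label = rec$label, stringsAsFactors = FALSE)
  utils::write.table(ann_df, ann, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- file.path(dir, paste0(prefix, "_labels.tsv"))
  utils::write.table(
    data.frame(id = rec$id, label = as.integer(rec$label == "solenoid")),
    lab, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, annotations = ann, labels = lab))
}

#' Read an annotation TSV into a training corpus
#'
#' @param fasta Path to the corpus FASTA.
#' @param annotations_tsv Path to the annotation TSV written by
#'   [write_corpus()] (columns id, semicolon-joined midpoints, label).
#' @return List with `sequences` and `midpoints`, usable by
#'   [extract_examples()] and [solenoid_net()].
#' @export
read_training_corpus <- function(fasta, annotations_tsv) {
  seqs <- read_fasta(fasta)
  if (!file.exists(annotations_tsv))
    stop("annotation file not found: ", annotations_tsv)
  ann <- utils::read.table(annotations_tsv, sep = "\t", header = TRUE,
                           colClasses = "character")
  missing <- setdiff(ann$id, names(seqs))
  if (length(missing))
    stop("annotated id without a sequence: ", paste(missing, collapse = ", "))
  mids <- stats::setNames(lapply(ann$midpoints, function(m) {
    if (!nzchar(m)) integer(0)
    else sort(as.integer(strsplit(m, ";")[[1]]))
  }), ann$id)
  list(sequences = seqs[ann$id], midpoints = mids)
}
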