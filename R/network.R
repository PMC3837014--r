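# The detector network is a fixed 780-3-1 multilayer perceptron with
# logistic activations on both layers: 39 window positions x 20 residue
# channels in, 3 hidden units, a single output trained towards 1 at repeat
# linker midpoints and 0 elsewhere.

sigmoid <- function(z) stats::plogis(z)

#' Initialize detector network parameters
#'
#' All weights and biases are drawn independently from a uniform
#' distribution on `[-scale, scale]`. Draw order is fixed (input-to-hidden
#' weights column-major, hidden biases, hidden-to-output weights, output
#' bias) so a given seed always produces the identical network.
#'
#' @param seed Integer seed for the random draws, or `NULL` to draw from the
#'   current RNG stream (used internally when a caller manages the stream).
#' @param scale Non-negative half-width of the uniform initialization.
#' @return An object of class `ard_net`: list with `W` (780 x 3 input-hidden
#'   weights), `b_h` (3 hidden biases), `w_o` (3 hidden-output weights),
#'   `b_o` (output bias).
#' @export
#' @examples
#' net <- init_network(seed = 1)
#' dim(net$W)
init_network <- function(seed = NULL, scale = 0.1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0)
  draw <- function() {
    W <- matrix(stats::runif(INPUT_SIZE * N_HIDDEN, -scale, scale),
                nrow = INPUT_SIZE, ncol = N_HIDDEN)
    b_h <- stats::runif(N_HIDDEN, -scale, scale)
    w_o <- stats::runif(N_HIDDEN, -scale, scale)
    b_o <- stats::runif(1L, -scale, scale)
    structure(list(W = W, b_h = b_h, w_o = w_o, b_o = b_o), class = "ard_net")
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

validate_net <- function(net) {
  if (!is.list(net) || !all(c("W", "b_h", "w_o", "b_o") %in% names(net)))
    stop("not a detector network object")
  if (!identical(dim(net$W), c(INPUT_SIZE, N_HIDDEN)) ||
      length(net$b_h) != N_HIDDEN || length(net$w_o) != N_HIDDEN ||
      length(net$b_o) != 1L)
    stop("network dimensions do not match the 780-3-1 architecture")
  invisible(net)
}

#' Forward pass of the detector network
#'
#' Computes `sigmoid(b_o + w_o . sigmoid(b_h + W' x))` for one encoded
#' window. The logistic output is strictly inside (0, 1).
#'
#' @param net An `ard_net`.
#' @param window Numeric vector of length 780 (one-hot window encoding from
#'   [encode_window()]).
#' @return Scalar score in (0, 1).
#' @export
nn_forward <- function(net, window) {
  validate_net(net)
  if (length(window) != INPUT_SIZE)
    stop("window has length ", length(window), ", expected ", INPUT_SIZE)
  h <- sigmoid(net$b_h + as.vector(crossprod(net$W, window)))
  sigmoid(net$b_o + sum(net$w_o * h))
}

# Sparse forward: idx are the active (value 1) input indices.
nn_forward_idx <- function(net, idx) {
  h <- sigmoid(net$b_h + .colSums(net$W[idx, ], length(idx), N_HIDDEN))
  sigmoid(net$b_o + sum(net$w_o * h))
}

#' Analytic gradients of the squared-error loss
#'
#' Gradient of `0.5 * (output - target)^2` with respect to every network
#' parameter, by back-propagation. Exposed so the analytic gradient can be
#' checked against finite differences.
#'
#' @param net An `ard_net`.
#' @param window Numeric input vector of length 780 (any values; training
#'   windows are 0/1).
#' @param target Scalar target (0 or 1 in training).
#' @return List with components `W`, `b_h`, `w_o`, `b_o` matching the
#'   parameter shapes, plus `output` (the forward score) and `loss`.
#' @export
nn_gradients <- function(net, window, target) {
  validate_net(net)
  if (length(window) != INPUT_SIZE)
    stop("window has length ", length(window), ", expected ", INPUT_SIZE)
  h <- sigmoid(net$b_h + as.vector(crossprod(net$W, window)))
  o <- sigmoid(net$b_o + sum(net$w_o * h))
  d_o <- (o - target) * o * (1 - o)
  d_h <- d_o * net$w_o * h * (1 - h)
  list(W = outer(window, d_h), b_h = d_h,
       w_o = d_o * h, b_o = d_o,
       output = o, loss = 0.5 * (o - target)^2)
}

#' Training configuration
#'
#' @param learn_rate Positive learning rate for online gradient descent.
#' @param epochs Number of passes over the training examples (>= 1).
#' @param neg_ratio Negative:positive sampling ratio (>= 1) used by
#'   [extract_examples()]; `Inf` (the default) takes every candidate
#'   negative window, which constrains the decision boundary far better
#'   than a small sample and correspondingly suppresses false hits on
#'   non-repeat sequence.
#' @param init_scale Half-width of the uniform weight initialization.
#' @param seed Integer seed controlling example sampling, initialization and
#'   per-epoch shuffling, or `NA` to use the current RNG stream.
#' @return List of class `training_config`.
#' @export
training_config <- function(learn_rate = 0.1, epochs = 500L, neg_ratio = Inf,
                            init_scale = 0.1, seed = NA_integer_) {
  stopifnot(learn_rate > 0, epochs >= 1, neg_ratio >= 1, init_scale >= 0)
  structure(list(learn_rate = learn_rate, epochs = as.integer(epochs),
                 neg_ratio = neg_ratio, init_scale = init_scale,
                 seed = seed),
            class = "training_config")
}

#' Extract supervised training examples from an annotated corpus
#'
#' One positive example is taken per annotated linker midpoint: the
#' unshifted detection window centred on the midpoint, target 1. Negative
#' examples (target 0) come from positions more than 2 residues away from
#' every annotated midpoint of their sequence (positions next to a midpoint
#' are ambiguous given 1-3 residue linkers): with a finite `neg_ratio`,
#' `neg_ratio` negatives per positive are sampled uniformly without
#' replacement; with `neg_ratio = Inf` every candidate position becomes a
#' negative. Only positions admitting a full unshifted window are used.
#' Windows are stored sparsely as columns of active one-hot input indices.
#'
#' @param corpus A training corpus: list with `sequences` (named character
#'   vector) and `midpoints` (named list of sorted 1-based integer vectors,
#'   empty for unannotated/background sequences).
#' @param cfg A [training_config()]; its `neg_ratio` and `seed` are used.
#' @return List of class `training_examples` with fields `idx` (39 x n
#'   integer matrix of active input indices per example, 0 marking unknown
#'   residues), `y` (targets), `id`, `center` (provenance).
#' @export
extract_examples <- function(corpus, cfg = training_config()) {
  stopifnot(is.list(corpus), !is.null(corpus$sequences))
  seqs <- corpus$sequences
  mids <- corpus$midpoints
  if (is.null(mids)) mids <- stats::setNames(vector("list", length(seqs)), names(seqs))
  n_pos_total <- sum(lengths(mids[names(seqs)]))
  if (n_pos_total == 0L)
    stop("corpus has no annotated linker midpoints; cannot build training examples")

  # 39 x n index matrix for the unshifted windows at the given centers
  window_matrix <- function(aa_idx, centers) {
    offs <- window_offsets(c(0L, 0L))
    A <- matrix(aa_idx[outer(offs, centers, "+")],
                nrow = WINDOW_POSITIONS, ncol = length(centers))
    A <- A + (seq_len(WINDOW_POSITIONS) - 1L) * N_ALPHABET
    A[is.na(A)] <- 0L
    A
  }

  build <- function() {
    pos_mats <- list(); pos_id <- list(); pos_center <- list()
    cand_id <- list(); cand_center <- list()
    ai_cache <- lapply(seqs, aa_indices)
    for (id in names(seqs)) {
      L <- nchar(seqs[[id]])
      if (L < WINDOW_POSITIONS) next
      centers <- (HELIX_WINDOW + 1L):(L - HELIX_WINDOW)
      m <- mids[[id]]
      if (length(m)) {
        bad <- m[m < HELIX_WINDOW + 1L | m > L - HELIX_WINDOW]
        if (length(bad))
          stop("annotated midpoint without a full detection window in '", id,
               "': ", paste(bad, collapse = ", "))
        pos_mats[[id]] <- window_matrix(ai_cache[[id]], m)
        pos_id[[id]] <- rep(id, length(m)); pos_center[[id]] <- m
        keep <- centers[vapply(centers, function(p) all(abs(p - m) > 2L),
                               logical(1))]
      } else {
        keep <- centers
      }
      cand_id[[id]] <- rep(id, length(keep))
      cand_center[[id]] <- keep
    }
    cand_id <- unlist(cand_id, use.names = FALSE)
    cand_center <- unlist(cand_center, use.names = FALSE)
    n_pos <- sum(lengths(pos_center))
    if (length(cand_id) == 0L) stop("no candidate negative positions in corpus")
    if (is.finite(cfg$neg_ratio)) {
      n_neg <- as.integer(round(cfg$neg_ratio * n_pos))
      take <- if (n_neg <= length(cand_id)) sample.int(length(cand_id), n_neg)
              else sample.int(length(cand_id), n_neg, replace = TRUE)
      cand_id <- cand_id[take]; cand_center <- cand_center[take]
    }
    groups <- split(seq_along(cand_id), cand_id)
    neg_mats <- lapply(groups, function(k)
      window_matrix(ai_cache[[cand_id[k[1]]]], cand_center[k]))
    perm <- unlist(groups, use.names = FALSE)
    neg_idx <- do.call(cbind, neg_mats)[, order(perm), drop = FALSE]
    neg_center <- cand_center
    structure(list(
      idx = cbind(do.call(cbind, pos_mats), neg_idx),
      y = c(rep(1, n_pos), rep(0, length(cand_id))),
      id = c(unlist(pos_id, use.names = FALSE), cand_id),
      center = c(unlist(pos_center, use.names = FALSE), neg_center)
    ), class = "training_examples")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) build()
  else withr::with_seed(as.integer(cfg$seed), build())
}

#' Train the detector network by back-propagation
#'
#' Online stochastic gradient descent on the squared error
#' `0.5 * (output - target)^2`, visiting the examples in a fresh random
#' order each epoch. The per-epoch mean squared error is recorded.
#'
#' @param net Starting `ard_net` (typically from [init_network()]).
#' @param examples A `training_examples` object from [extract_examples()].
#' @param cfg A [training_config()]; `learn_rate`, `epochs` and `seed` are
#'   used. With `seed = NA` the current RNG stream drives the shuffling.
#' @return The trained `ard_net`, with the per-epoch MSE history in
#'   attribute `"history"`.
#' @export
train_network <- function(net, examples, cfg = training_config()) {
  validate_net(net)
  stopifnot(inherits(examples, "training_examples"))
  n <- length(examples$y)
  if (n == 0L) stop("no training examples")
  run <- function() {
    res <- .train_sgd(net$W, net$b_h, net$w_o, net$b_o,
                      examples$idx, examples$y,
                      as.integer(cfg$epochs), cfg$learn_rate)
    structure(list(W = res$W, b_h = res$b_h, w_o = res$w_o, b_o = res$b_o),
              class = "ard_net", history = res$mse)
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) run()
  else withr::with_seed(as.integer(cfg$seed), run())
}

#' Save a detector network to a JSON model file
#'
#' Structured text serialization recording the architecture (39 window
#' positions, 20 residue channels, 3 hidden units, 1 output), the alphabet
#' order, all parameters, and optional training metadata. Doubles are
#' written as decimal strings with 17 significant digits so that
#' `load_model(save_model(net))` is bit-identical.
#'
#' @param net An `ard_net`.
#' @param path Output path.
#' @param metadata Optional named list of training metadata to embed.
#' @return Invisibly, `path`.
#' @export
save_model <- function(net, path, metadata = NULL) {
  validate_net(net)
  num <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(
    model = "alpha-solenoid repeat detector",
    architecture = list(window_positions = WINDOW_POSITIONS,
                        alphabet_size = N_ALPHABET,
                        hidden = N_HIDDEN, output = 1L),
    alphabet = AA_ALPHABET,
    weights = list(input_hidden = num(net$W),   # column-major 780 x 3
                   hidden_bias = num(net$b_h),
                   hidden_output = num(net$w_o),
                   output_bias = num(net$b_o))
  )
  if (!is.null(metadata)) obj$training <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a detector network saved by [save_model()]
#'
#' Validates the recorded architecture and parameter counts before
#' reconstructing the network; a file whose dimensions do not match the
#' 780-3-1 architecture is rejected.
#'
#' @param path Path to a model JSON file.
#' @return An `ard_net`, with any embedded training metadata in attribute
#'   `"metadata"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- obj$architecture
  if (is.null(arch) ||
      !identical(as.integer(arch$window_positions), WINDOW_POSITIONS) ||
      !identical(as.integer(arch$alphabet_size), N_ALPHABET) ||
      !identical(as.integer(arch$hidden), N_HIDDEN) ||
      !identical(as.integer(arch$output), 1L))
    stop("model file has unsupported architecture (expected 39 x 20 input, ",
         "3 hidden, 1 output): ", path)
  w <- obj$weights
  W <- as.numeric(w$input_hidden)
  if (length(W) != INPUT_SIZE * N_HIDDEN ||
      length(w$hidden_bias) != N_HIDDEN ||
      length(w$hidden_output) != N_HIDDEN ||
      length(w$output_bias) != 1L)
    stop("model file parameter counts do not match the declared architecture: ",
         path)
  net <- structure(list(W = matrix(W, INPUT_SIZE, N_HIDDEN),
                        b_h = as.numeric(w$hidden_bias),
                        w_o = as.numeric(w$hidden_output),
                        b_o = as.numeric(w$output_bias)),
                   class = "ard_net")
  if (!is.null(obj$training)) attr(net, "metadata") <- obj$training
  net
}

#' @export
print.ard_net <- function(x, ...) {
  cat("Alpha-solenoid repeat detector network (39 x 20 input, 3 hidden, 1 output)\n")
  cat("  parameters:", length(x$W) + length(x$b_h) + length(x$w_o) + 1L, "\n")
  h <- attr(x, "history")
  if (!is.null(h))
    cat("  trained", length(h), "epochs; final MSE", sprintf("%.5f", h[length(h)]), "\n")
  invisible(x)
}
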