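#' Fit an alpha-solenoid repeat detector
#'
#' Trains the 780-3-1 sigmoid network to recognise repeat-linker midpoints
#' from an annotated corpus: weights are initialized uniformly, supervised
#' examples are extracted (one positive per annotated midpoint, sampled
#' negatives elsewhere), and the network is trained by online
#' back-propagation on the squared error. A single seed drives
#' initialization, negative sampling and per-epoch shuffling sequentially,
#' so a fit is fully reproducible.
#'
#' @param corpus Training corpus: list with `sequences` (named character
#'   vector) and `midpoints` (named list of 1-based annotated linker
#'   midpoints; empty vectors mark background sequences), e.g. the `train`
#'   element of [make_corpus()] or the result of [read_training_corpus()].
#' @param epochs Training epochs.
#' @param learn_rate Learning rate of the online gradient descent.
#' @param neg_ratio Negative:positive example sampling ratio.
#' @param init_scale Half-width of the uniform weight initialization.
#' @param seed Integer seed (mandatory: the fit is stochastic).
#' @return An object of class `solenoid_net`: list with `net` (the trained
#'   `ard_net`), `history` (per-epoch MSE), `examples` (provenance of the
#'   training examples), `config` and `call`.
#' @seealso [predict.solenoid_net()], [pr_sweep()], [make_corpus()]
#' @export
#' @examples
#' corpus <- make_corpus(6, 12, seed = 42)
#' fit <- solenoid_net(corpus$train, epochs = 30, seed = 1)
#' print(fit)
solenoid_net <- function(corpus, epochs = 500L, learn_rate = 0.1,
                         neg_ratio = Inf, init_scale = 0.1, seed) {
  if (missing(seed)) stop("a seed is required: training is stochastic")
  cfg <- training_config(learn_rate = learn_rate, epochs = epochs,
                         neg_ratio = neg_ratio, init_scale = init_scale,
                         seed = as.integer(seed))
  fit <- withr::with_seed(cfg$seed, {
    net0 <- init_network(seed = NULL, scale = cfg$init_scale)
    inner <- cfg; inner$seed <- NA_integer_   # stay on the single stream
    ex <- extract_examples(corpus, inner)
    net <- train_network(net0, ex, inner)
    list(net = net, examples = ex)
  })
  structure(list(net = structure(fit$net, history = NULL),
                 history = attr(fit$net, "history"),
                 examples = data.frame(id = fit$examples$id,
                                       center = fit$examples$center,
                                       target = fit$examples$y,
                                       stringsAsFactors = FALSE),
                 example_idx = fit$examples$idx,
                 config = cfg,
                 call = match.call()),
            class = "solenoid_net")
}

# Accept either a bare network or a fitted model everywhere downstream.
as_ard_net <- function(x) {
  if (inherits(x, "solenoid_net")) return(x$net)
  validate_net(x)
  x
}

#' @export
print.solenoid_net <- function(x, ...) {
  cat("Alpha-solenoid repeat detector (39 x 20 - 3 - 1 sigmoid network)\n")
  cat("  trained on ", sum(x$examples$target == 1), " linker-midpoint and ",
      sum(x$examples$target == 0), " background windows\n", sep = "")
  cat("  epochs: ", x$config$epochs,
      ", learning rate: ", x$config$learn_rate,
      ", seed: ", x$config$seed, "\n", sep = "")
  cat("  final training MSE: ",
      sprintf("%.5f", x$history[length(x$history)]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.solenoid_net <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    n_positive = sum(object$examples$target == 1),
    n_negative = sum(object$examples$target == 0),
    config = object$config,
    mse_first = object$history[1],
    mse_final = object$history[length(object$history)],
    resid_quantiles = stats::quantile(res, c(0, 0.25, 0.5, 0.75, 1))
  )
  class(out) <- "summary.solenoid_net"
  out
}

#' @export
print.summary.solenoid_net <- function(x, ...) {
  cat("Alpha-solenoid repeat detector fit\n")
  cat("  training windows: ", x$n_positive, " positive / ", x$n_negative,
      " negative\n", sep = "")
  cat("  MSE: ", sprintf("%.5f", x$mse_first), " (first epoch) -> ",
      sprintf("%.5f", x$mse_final), " (final epoch)\n", sep = "")
  cat("  residual quantiles (target - fitted):\n")
  print(round(x$resid_quantiles, 4))
  invisible(x)
}

#' Extract network parameters from a fitted detector
#'
#' @param object A `solenoid_net`.
#' @param ... Ignored.
#' @return Named list: `input_hidden` (780 x 3), `hidden_bias`,
#'   `hidden_output`, `output_bias`.
#' @export
coef.solenoid_net <- function(object, ...) {
  list(input_hidden = object$net$W, hidden_bias = object$net$b_h,
       hidden_output = object$net$w_o, output_bias = object$net$b_o)
}

#' Fitted scores for the training windows
#'
#' @param object A `solenoid_net`.
#' @param ... Ignored.
#' @return Numeric vector of network outputs for each training example.
#' @export
fitted.solenoid_net <- function(object, ...) {
  idx <- object$example_idx
  vapply(seq_len(ncol(idx)), function(j) {
    ii <- idx[, j]
    nn_forward_idx(object$net, ii[ii > 0L])
  }, numeric(1))
}

#' Training residuals (target minus fitted score)
#'
#' @param object A `solenoid_net`.
#' @param ... Ignored.
#' @export
residuals.solenoid_net <- function(object, ...) {
  object$examples$target - fitted(object)
}

#' Score or classify sequences with a fitted detector
#'
#' With `type = "profile"` every sequence is scanned into a per-residue
#' score profile; with `type = "call"` the profiles are additionally
#' discretized and chained into solenoid calls, returning one row per
#' sequence in the tabular style `id`, `is_solenoid`, `n_hits`,
#' `chain_positions` (semicolon-joined), `chain_scores`.
#'
#' @param object A `solenoid_net`.
#' @param newdata Named character vector of residue strings, a single
#'   unnamed string, or a FASTA path.
#' @param type `"profile"` or `"call"`.
#' @param params A [calling_params()] (used for calls).
#' @param shifts Use window shifts (default) or fixed linker length 1.
#' @param ... Ignored.
#' @return For `"profile"`, a list of `score_profile` objects (a single
#'   profile if one unnamed sequence was given); for `"call"`, a data frame.
#' @export
predict.solenoid_net <- function(object, newdata, type = c("profile", "call"),
                                 params = calling_params(), shifts = TRUE,
                                 ...) {
  type <- match.arg(type)
  single <- FALSE
  if (is.character(newdata) && length(newdata) == 1L && file.exists(newdata) &&
      is.null(names(newdata))) {
    newdata <- read_fasta(newdata)
  } else if (is.character(newdata) && is.null(names(newdata))) {
    if (length(newdata) == 1L) single <- TRUE
    names(newdata) <- paste0("seq", seq_along(newdata))
  }
  profiles <- mapply(function(s, id) scan_sequence(object$net, s, id, shifts),
                     newdata, names(newdata), SIMPLIFY = FALSE)
  if (type == "profile") {
    if (single) return(profiles[[1]])
    return(profiles)
  }
  do.call(rbind, lapply(profiles, function(p) call_row(classify_profile(p, params))))
}

#' Plot the training history of a fitted detector
#'
#' @param x A `solenoid_net`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.solenoid_net <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "mean squared error",
                 main = "Detector training history", ...)
  invisible(x)
}
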