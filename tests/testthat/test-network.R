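test_that("initialization is seed-deterministic and respects the scale", {
  expect_equal(init_network(seed = 1), init_network(seed = 1))
  n1 <- init_network(seed = 1); n2 <- init_network(seed = 2)
  expect_false(isTRUE(all.equal(n1$W, n2$W)))
  z <- init_network(seed = 3, scale = 0)
  expect_true(all(z$W == 0) && all(z$b_h == 0) && all(z$w_o == 0) && z$b_o == 0)
  expect_true(all(abs(n1$W) <= 0.1))
})

test_that("forward pass matches the closed-form sigmoid composition", {
  # zero network: hidden outputs all 0.5, zero output weights -> sigma(0)
  z <- init_network(seed = 1, scale = 0)
  expect_equal(nn_forward(z, rep(0, 780)), 0.5)
  expect_equal(nn_forward(z, encode_window(strrep("A", 39), 1:39)), 0.5)

  # hand-set weights, longhand oracle computed with plain arithmetic
  net <- init_network(seed = 1, scale = 0)
  win <- encode_window(strrep("A", 39), 1:39)      # active: (0:38)*20 + 1
  act <- which(win == 1)
  net$W[act[1:5], 1] <- 0.3
  net$W[act[1:2], 2] <- -0.7
  net$b_h <- c(0.1, -0.2, 0.4)
  net$w_o <- c(1.5, -2, 0.25)
  net$b_o <- -0.3
  h <- plogis(c(0.1 + 5 * 0.3, -0.2 + 2 * -0.7, 0.4))
  oracle <- plogis(-0.3 + sum(c(1.5, -2, 0.25) * h))
  expect_equal(nn_forward(net, win), oracle)
})

test_that("forward output stays strictly inside (0,1) and checks dimensions", {
  net <- init_network(seed = 9, scale = 2)
  for (i in 1:20) {
    win <- encode_window(paste(sample(c(aa_alphabet(), "X"), 39, TRUE),
                               collapse = ""), 1:39)
    s <- nn_forward(net, win)
    expect_true(s > 0 && s < 1)
  }
  expect_error(nn_forward(net, rep(0, 779)), "length")
})

test_that("example extraction honors counts, exclusion zone and determinism", {
  corpus <- small_corpus()$train
  cfg <- training_config(neg_ratio = 3, seed = 5)
  ex <- extract_examples(corpus, cfg)
  n_pos <- sum(ex$y == 1)
  expect_equal(n_pos, sum(lengths(corpus$midpoints)))
  expect_equal(sum(ex$y == 0), 3L * n_pos)
  # no negative center within 2 residues of any midpoint of its sequence
  for (k in which(ex$y == 0)) {
    m <- corpus$midpoints[[ex$id[k]]]
    if (length(m)) expect_true(all(abs(ex$center[k] - m) > 2))
  }
  expect_equal(extract_examples(corpus, cfg), ex)
  # all-negatives mode uses every eligible candidate
  ex_all <- extract_examples(corpus, training_config(neg_ratio = Inf))
  expect_gt(sum(ex_all$y == 0), 10 * n_pos)
})

test_that("extraction fails informatively on unusable corpora", {
  bg <- list(sequences = c(b1 = strrep("A", 100)), midpoints = list(b1 = integer(0)))
  expect_error(extract_examples(bg), "no annotated")
  edge <- list(sequences = c(s1 = strrep("A", 100)), midpoints = list(s1 = 5L))
  expect_error(extract_examples(edge), "full detection window")
})

test_that("backprop training separates a trivially separable toy problem", {
  # positives: all-alanine windows; negatives: all-leucine windows
  a_col <- (0:38) * 20L + match("A", aa_alphabet())
  l_col <- (0:38) * 20L + match("L", aa_alphabet())
  ex <- structure(list(
    idx = cbind(matrix(a_col, 39, 10), matrix(l_col, 39, 10)),
    y = rep(c(1, 0), each = 10),
    id = rep(c("a", "l"), each = 10),
    center = rep(20L, 20)), class = "training_examples")
  net <- train_network(init_network(seed = 1), ex,
                       training_config(epochs = 200, seed = 1))
  hist <- attr(net, "history")
  expect_lt(hist[200], 0.05)
  expect_lt(hist[200], hist[1])
  dense <- function(ii) { v <- numeric(780); v[ii] <- 1; v }
  expect_gt(nn_forward(net, dense(a_col)), 0.9)
  expect_lt(nn_forward(net, dense(l_col)), 0.1)
})

test_that("training is seed-deterministic and loss decreases on real corpora", {
  corpus <- small_corpus()$train
  cfg <- training_config(epochs = 40, neg_ratio = 3, seed = 8)
  ex <- extract_examples(corpus, cfg)
  net0 <- init_network(seed = 8)
  n1 <- train_network(net0, ex, cfg)
  n2 <- train_network(net0, ex, cfg)
  expect_equal(n1, n2)
  hist <- attr(n1, "history")
  expect_lt(hist[length(hist)], hist[1])
})

test_that("one SGD step equals the analytic gradient update", {
  net <- init_network(seed = 3)
  win <- encode_window(strrep("ACDLKV", 7), 1:39)
  idx <- matrix(which(win == 1), ncol = 1)
  ex <- structure(list(idx = idx, y = 1, id = "x", center = 20L),
                  class = "training_examples")
  lr <- 0.1
  stepped <- train_network(net, ex, training_config(epochs = 1, learn_rate = lr,
                                                    seed = 1))
  g <- nn_gradients(net, win, 1)
  expect_equal(stepped$W, net$W - lr * g$W)
  expect_equal(stepped$b_h, net$b_h - lr * g$b_h)
  expect_equal(stepped$w_o, net$w_o - lr * g$w_o)
  expect_equal(stepped$b_o, net$b_o - lr * g$b_o)
})

test_that("analytic gradients agree with finite differences", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      net <- init_network(seed = NULL, scale = 0.5)
      win <- encode_window(paste(sample(aa_alphabet(), 39, TRUE), collapse = ""),
                           1:39)
      y <- sample(0:1, 1)
      g <- nn_gradients(net, win, y)
      eps <- 1e-6
      loss_at <- function(net) {
        o <- nn_forward(net, win); 0.5 * (o - y)^2
      }
      # spot-check a random subset of input-hidden weights plus all the rest
      for (i in sample(which(win == 1), 5)) for (j in 1:3) {
        up <- net; up$W[i, j] <- up$W[i, j] + eps
        dn <- net; dn$W[i, j] <- dn$W[i, j] - eps
        fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_lt(abs(fd - g$W[i, j]) / max(abs(fd), 1e-8), 1e-4)
      }
      for (j in 1:3) {
        up <- net; up$w_o[j] <- up$w_o[j] + eps
        dn <- net; dn$w_o[j] <- dn$w_o[j] - eps
        fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_lt(abs(fd - g$w_o[j]) / max(abs(fd), 1e-8), 1e-4)
      }
      up <- net; up$b_o <- up$b_o + eps
      dn <- net; dn$b_o <- dn$b_o - eps
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(fd - g$b_o) / max(abs(fd), 1e-8), 1e-4)
    }
  })
})

test_that("model serialization round-trips bit-identically and validates", {
  net <- init_network(seed = 77, scale = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(net, path, metadata = list(epochs = 10))
  back <- load_model(path)
  expect_identical(back$W, net$W)
  expect_identical(back$b_h, net$b_h)
  expect_identical(back$w_o, net$w_o)
  expect_identical(back$b_o, net$b_o)
  expect_equal(attr(back, "metadata")$epochs, 10)
  # the file records the fixed architecture
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(obj$architecture),
               c(window_positions = 39, alphabet_size = 20, hidden = 3, output = 1))
  # truncated parameters are rejected
  obj$weights$input_hidden <- obj$weights$input_hidden[-1]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "parameter counts")
  obj$architecture$hidden <- 4
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "architecture")
})
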