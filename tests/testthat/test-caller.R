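test_that("hit discretization applies threshold and non-maximum suppression", {
  prof <- fake_profile(c(100, 102, 150), c(0.9, 0.95, 0.9))
  hits <- find_hits(prof, calling_params(threshold = 0.87, radius = 10))
  expect_equal(hits$position, c(102, 150))
  # everything below threshold -> no hits
  low <- fake_profile(c(100, 150), c(0.5, 0.8))
  expect_equal(nrow(find_hits(low, calling_params(threshold = 0.87))), 0L)
  # just outside the suppression radius: both kept
  pair <- fake_profile(c(100, 111), c(0.9, 0.9))
  expect_equal(find_hits(pair, calling_params())$position, c(100, 111))
  # inside the radius with equal scores: the smaller position survives
  tie <- fake_profile(c(100, 105), c(0.9, 0.9))
  expect_equal(find_hits(tie, calling_params())$position, 100)
  # threshold is inclusive
  exact <- fake_profile(200, 0.87)
  expect_equal(nrow(find_hits(exact, calling_params())), 1L)
})

test_that("best_chain finds the longest periodically spaced subsequence", {
  mk_hits <- function(pos, score = rep(0.9, length(pos)))
    data.frame(position = pos, score = score,
               shift = rep("0/0", length(pos)))
  # the published LRRK2 hit positions chain completely
  lrrk2 <- mk_hits(c(360, 408, 452, 494))
  chain <- best_chain(lrrk2, calling_params())
  expect_equal(nrow(chain), 4L)
  expect_equal(chain$position, c(360, 408, 452, 494))
  # a too-long gap breaks the chain
  broken <- mk_hits(c(1, 40, 200, 240, 280))
  expect_equal(best_chain(broken, calling_params())$position, c(200, 240, 280))
  # degenerate inputs pass through
  expect_equal(nrow(best_chain(mk_hits(numeric(0)), calling_params())), 0L)
  expect_equal(best_chain(mk_hits(50), calling_params())$position, 50)
  # equal length: higher total score wins, then smaller start
  two <- mk_hits(c(100, 140, 300, 340), c(0.9, 0.9, 0.99, 0.99))
  expect_equal(best_chain(two, calling_params())$position, c(300, 340))
  flat <- mk_hits(c(100, 140, 300, 340), rep(0.9, 4))
  expect_equal(best_chain(flat, calling_params())$position, c(100, 140))
})

test_that("chain length matches exhaustive enumeration on random hit sets", {
  withr::with_seed(99, {
    for (i in 1:60) {
      n <- sample(2:12, 1)
      pos <- sort(sample(1:500, n))
      hits <- data.frame(position = pos, score = runif(n, 0.87, 1))
      dp <- nrow(best_chain(hits, calling_params()))
      expect_equal(dp, chain_oracle_length(pos), info = paste(pos, collapse = ","))
    }
  })
})

test_that("classification applies the minimum-hits chaining rule", {
  lrrk2 <- fake_profile(c(360, 408, 452, 494), rep(0.9, 4), length = 600,
                        id = "LRRK2")
  call <- classify_profile(lrrk2, calling_params())
  expect_true(call$is_solenoid)
  expect_equal(nrow(call$chain), 4L)
  # two hits only -> negative under a minimum of 3
  two <- fake_profile(c(100, 140), c(0.9, 0.9))
  expect_false(classify_profile(two, calling_params())$is_solenoid)
  # hits spaced 29 apart violate the minimum spacing consecutively, but
  # alternate hits sit 58 apart and chain validly -- the rule constrains
  # consecutive chain members, not adjacent hits
  tight <- fake_profile(100 + 29 * (0:4), rep(0.95, 5), length = 300)
  cl <- classify_profile(tight, calling_params())
  expect_true(cl$is_solenoid)
  expect_equal(cl$chain$position, 100 + 58 * (0:2))
  expect_equal(chain_oracle_length(100 + 29 * (0:4)), 3L)
  # gaps beyond the maximum spacing never chain
  wide <- fake_profile(c(100, 250, 400), rep(0.95, 3), length = 450)
  expect_false(classify_profile(wide, calling_params())$is_solenoid)
  # spacings too short to chain even by skipping (suppression disabled)
  close3 <- fake_profile(c(100, 110, 120), rep(0.95, 3), length = 200)
  expect_false(classify_profile(close3,
                                calling_params(radius = 0))$is_solenoid)
})

test_that("calls are monotone in threshold and minimum hits", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(3:10, 1)
      prof <- fake_profile(sort(sample(30:400, n)), runif(n, 0.8, 1),
                           length = 450)
      hits_by_th <- integer(0); called <- logical(0)
      for (th in c(0.80, 0.85, 0.90, 0.95)) {
        p <- calling_params(threshold = th)
        hits_by_th <- c(hits_by_th, nrow(find_hits(prof, p)))
        called <- c(called, classify_profile(prof, p)$is_solenoid)
      }
      expect_true(all(diff(hits_by_th) <= 0))
      expect_true(all(diff(called) <= 0))  # never negative -> positive
      for (mh in 1:4) {
        lo <- classify_profile(prof, calling_params(min_hits = mh))$is_solenoid
        hi <- classify_profile(prof, calling_params(min_hits = mh + 1))$is_solenoid
        expect_true(lo >= hi)
      }
    }
  })
})
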