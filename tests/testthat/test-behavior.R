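test_that("dprime matches normal-quantile arithmetic and corrections", {
  expect_equal(dprime(15, 15, 15, 15), 0)
  # H = 0.69, F = 0.31 with large N so no correction bites
  expect_equal(dprime(690, 310, 310, 690),
               qnorm(0.69) - qnorm(0.31), tolerance = 1e-9)
  expect_equal(dprime(690, 310, 310, 690), 0.99, tolerance = 0.01)
  # perfect performance: 1/(2N) clamping
  expect_equal(dprime(30, 0, 0, 30),
               qnorm(59 / 60) - qnorm(1 / 60), tolerance = 1e-9)
  expect_equal(dprime(30, 0, 0, 30), 2 * qnorm(0.9833), tolerance = 0.01)
  expect_error(dprime(0, 0, 3, 4), "at least one")
  expect_error(dprime(5, 0, 0, 5, correction = "none"), "extreme")
})

test_that("dprime is antisymmetric under swapping hit and FA rates", {
  set.seed(61)
  for (i in 1:20) {
    h <- sample(0:20, 1); m <- 20 - h
    f <- sample(0:20, 1); cr <- 20 - f
    expect_equal(dprime(h, m, f, cr), -dprime(f, cr, h, m), tolerance = 1e-12)
  }
})

test_that("group_test reproduces the one-sample t arithmetic", {
  z <- group_test(rep(0, 10))
  expect_equal(z$t, 0); expect_equal(z$p, 0.5)
  # construct a vector with the exact mean/SD of a published-style summary
  n <- 21
  raw <- scale(rnorm(n))            # mean 0, sd 1 exactly
  d <- 1.3866 + 0.5116 * as.numeric(raw)
  g <- group_test(d)
  expect_equal(g$t, 1.3866 / (0.5116 / sqrt(21)), tolerance = 1e-6)
  expect_equal(g$t, 12.42, tolerance = 0.01)
  expect_equal(g$cohen_d, 1.3866 / 0.5116, tolerance = 1e-6)
  expect_lt(g$p, 1e-9)
  expect_error(group_test(rep(1.2, 5)), "zero variance")
  expect_error(group_test(0.5), "at least 2")
})

test_that("categorization matrices normalize rows and use 20% chance", {
  cats <- emotion_categories()
  # perfect responder
  tb <- data.frame(participant = 1,
                   true_category = rep(cats, each = 10),
                   response = rep(cats, each = 10))
  cm <- categorization_matrix(tb)
  expect_equal(unname(cm$matrix), diag(5))
  expect_equal(cm$chance, 0.2)
  expect_true(all(abs(rowSums(cm$matrix) - 1) < 1e-12))
  # uniform random responder converges to chance in every cell
  set.seed(77)
  tbr <- data.frame(participant = 1,
                    true_category = sample(cats, 20000, replace = TRUE),
                    response = sample(cats, 20000, replace = TRUE))
  cmr <- categorization_matrix(tbr)
  expect_true(all(abs(cmr$matrix - 0.2) < 0.02))
  expect_error(categorization_matrix(
    data.frame(true_category = "joy", response = "fear")), "unknown")
})

test_that("one-vs-rest d' recovers generating sensitivity from simulation", {
  tb <- simulate_behavior(1.2, 10000, seed = 31, participant = 3)
  sc <- score_detection(tb)
  expect_equal(sc$participant, 3)
  expect_equal(sc$dprime, 1.2, tolerance = 0.1)
  # multi-class table: a responder who is perfect on fear, random elsewhere
  set.seed(32)
  cats <- emotion_categories()
  truec <- sample(cats, 4000, replace = TRUE)
  resp <- ifelse(truec == "fear", "fear", sample(setdiff(cats, "fear"),
                                                 4000, replace = TRUE))
  cd <- categorization_dprime(
    data.frame(participant = 1, true_category = truec, response = resp,
               stringsAsFactors = FALSE))
  expect_gt(cd$dprime[cd$category == "fear"], 3)
  expect_lt(abs(cd$dprime[cd$category == "anger"]), 0.3)
})

test_that("rating summaries are descriptive per category", {
  tb <- data.frame(true_category = rep(c("fear", "happiness"), each = 50),
                   valence = c(rnorm(50, 2, 0.3), rnorm(50, 4, 0.3)))
  tb$valence <- pmin(pmax(tb$valence, 1), 5)
  rs <- rating_summary(tb)
  expect_equal(rs$n, c(50, 50))
  expect_lt(rs$mean[rs$category == "fear"], rs$mean[rs$category == "happiness"])
  expect_error(rating_summary(data.frame(true_category = "fear", valence = 9)),
               "ratings")
})
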