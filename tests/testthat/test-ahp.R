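test_that("pairwise_matrix fills reciprocals and validates input", {
  j <- data.frame(row_id = "A", col_id = "B", value = 3)
  A <- pairwise_matrix(j, c("A", "B"))
  expect_equal(A, matrix(c(1, 1 / 3, 3, 1), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B"))))

  j3 <- data.frame(row_id = c("A", "A", "B"), col_id = c("B", "C", "C"),
                   value = c(2, 4, 2))
  A3 <- pairwise_matrix(j3, c("A", "B", "C"))
  expect_equal(unname(A3),
               matrix(c(1, 1/2, 1/4, 2, 1, 1/2, 4, 2, 1), 3, 3))

  expect_error(pairwise_matrix(j3[1:2, ], c("A", "B", "C")), "missing judgment")
  expect_error(pairwise_matrix(rbind(j3, j3[1, ]), c("A", "B", "C")),
               "duplicate")
  off <- data.frame(row_id = "A", col_id = "B", value = 3.7)
  expect_error(pairwise_matrix(off, c("A", "B")), "Saaty grid")
  expect_silent(pairwise_matrix(off, c("A", "B"), strict = FALSE))
})

test_that("eigenvector method recovers known priority vectors", {
  A2 <- matrix(c(1, 1 / 3, 3, 1), 2, 2)
  e2 <- principal_eigenvector(A2)
  expect_equal(unname(e2$weights), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(e2$lambda_max, 2, tolerance = 1e-12)

  A3 <- matrix(c(1, 1/2, 1/4, 2, 1, 1/2, 4, 2, 1), 3, 3)
  e3 <- principal_eigenvector(A3)
  expect_equal(unname(e3$weights), c(4, 2, 1) / 7, tolerance = 1e-10)
  expect_equal(e3$lambda_max, 3, tolerance = 1e-10)

  # equal row sums force the uniform Perron vector
  Ac <- matrix(c(1, 1/2, 2, 2, 1, 1/2, 1/2, 2, 1), 3, 3)
  ec <- principal_eigenvector(Ac)
  expect_equal(unname(ec$weights), rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(ec$lambda_max, 3.5, tolerance = 1e-10)
})

test_that("eigenvector is invariant under simultaneous permutation", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    A <- random_reciprocal(n)
    p <- sample(n)
    w <- principal_eigenvector(A)$weights
    wp <- principal_eigenvector(A[p, p])$weights
    expect_equal(unname(wp), unname(w[p]), tolerance = 1e-9)
  }
})

test_that("consistency ratio follows the CI/RI definition", {
  A3 <- matrix(c(1, 1/2, 1/4, 2, 1, 1/2, 4, 2, 1), 3, 3)
  r <- consistency(A3)
  expect_lt(r$cr, 1e-10)

  Ac <- matrix(c(1, 1/2, 2, 2, 1, 1/2, 1/2, 2, 1), 3, 3)
  rc <- consistency(Ac)
  expect_equal(rc$ci, 0.25, tolerance = 1e-10)
  expect_equal(rc$ri, 0.58)
  expect_equal(rc$cr, 0.25 / 0.58, tolerance = 1e-10)

  # 2x2 reciprocal matrices are always consistent; CR defined as 0
  r2 <- consistency(matrix(c(1, 1 / 9, 9, 1), 2, 2))
  expect_identical(r2$cr, 0)
  expect_error(consistency(matrix(1, 1, 1)), "1 x 1")
})

test_that("matrices built from exact weight ratios are consistent and recoverable", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:9, 1)
    w <- runif(n, 0.05, 1); w <- w / sum(w)
    A <- consistent_matrix(w)
    e <- principal_eigenvector(A)
    expect_lt(max(abs(e$weights - w)), 1e-10)
    expect_lt(consistency(A)$cr, 1e-10)
    expect_gte(e$lambda_max, n - 1e-10)
  }
})

test_that("screening partitions respondents by CR threshold on the level-two block", {
  h <- toy_hierarchy()
  good <- consistent_matrix(c(a = 0.5, b = 0.3, c = 0.2))
  # mildly inconsistent: 0.1 < CR < 0.2
  bad <- matrix(c(1, 9, 1/3, 1/9, 1, 1/7, 3, 7, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cr_bad <- consistency(bad)$cr
  expect_gt(cr_bad, 0.1)
  expect_lt(cr_bad, 0.2)

  mats <- list(r1 = list(goal = good), r2 = list(goal = bad))
  strict <- screen_respondents(mats, h, threshold = 0.1)
  expect_identical(strict$included, "r1")
  expect_identical(strict$excluded, "r2")
  lenient <- screen_respondents(mats, h, threshold = 0.2)
  expect_setequal(lenient$included, c("r1", "r2"))
  expect_error(screen_respondents(list(r1 = list()), h), "missing screening")
})

test_that("exclusion fraction grows with judgment noise", {
  h <- study_hierarchy()
  frac_excluded <- vapply(c(0.1, 0.3, 0.6), function(sig) {
    cfg <- synthetic_config(hierarchy = h, sigma = sig, n_respondents = 25,
                            seed = 400)
    sim <- simulate_study(cfg)
    fit <- ahp(sim$judgments, h, cr_threshold = 0.1)
    length(fit$inclusion$excluded) /
      (length(fit$inclusion$excluded) + length(fit$inclusion$included))
  }, numeric(1))
  expect_true(all(diff(frac_excluded) >= 0))
  expect_gt(frac_excluded[3], frac_excluded[1])
})

test_that("ahp() reports incomplete respondents instead of guessing", {
  h <- study_hierarchy()
  sim <- simulate_study(synthetic_config(hierarchy = h, n_respondents = 5,
                                         seed = 19))
  # drop one block for one respondent
  drop <- sim$judgments$respondent_id == "r3" & sim$judgments$block_id == "social"
  fit <- ahp(sim$judgments[!drop, ], h, cr_threshold = 1)
  expect_identical(fit$inclusion$incomplete, "r3")
  expect_false("r3" %in% fit$inclusion$included)
})

test_that("two-respondent fixture matches an independently scripted pipeline", {
  h <- toy_hierarchy()
  A1 <- pairwise_matrix(
    data.frame(row_id = c("a", "a", "b"), col_id = c("b", "c", "c"),
               value = c(2, 4, 2)), c("a", "b", "c"))
  A2 <- pairwise_matrix(
    data.frame(row_id = c("a", "a", "b"), col_id = c("b", "c", "c"),
               value = c(1, 2, 3)), c("a", "b", "c"))
  j <- rbind(
    data.frame(respondent_id = "r1", block_id = "goal",
               row_id = c("a", "a", "b"), col_id = c("b", "c", "c"),
               value = c(2, 4, 2)),
    data.frame(respondent_id = "r2", block_id = "goal",
               row_id = c("a", "a", "b"), col_id = c("b", "c", "c"),
               value = c(1, 2, 3)))

  # oracle: dense eigensolver and hand-rolled geometric means
  w1 <- eigen_oracle(A1)$weights
  w2 <- eigen_oracle(A2)$weights
  aip_expect <- exp((log(w1) + log(w2)) / 2)
  aip_expect <- aip_expect / sum(aip_expect)
  aij_mat <- sqrt(A1 * A2)
  aij_expect <- eigen_oracle(aij_mat)$weights

  fit_aip <- ahp(j, h, mode = "AIP", cr_threshold = 1)
  fit_aij <- ahp(j, h, mode = "AIJ")
  expect_equal(unname(fit_aip$local$goal), aip_expect, tolerance = 1e-9)
  expect_equal(unname(fit_aij$local$goal), aij_expect, tolerance = 1e-9)
})
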