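test_that("AIJ geometric aggregation preserves reciprocity and known values", {
  m <- function(v) matrix(c(1, 1 / v, v, 1), 2, 2)
  # opposite extreme judgments cancel to 1; {2, 8} average to 4
  expect_equal(aggregate_judgments(list(m(9), m(1 / 9)))[1, 2], 1)
  expect_equal(aggregate_judgments(list(m(2), m(8)))[1, 2], 4)
  A <- random_reciprocal(4)
  expect_equal(aggregate_judgments(list(A, A, A)), A)

  set.seed(41)
  for (rep in 1:20) {
    mats <- replicate(sample(2:6, 1), random_reciprocal(5), simplify = FALSE)
    G <- aggregate_judgments(mats, "geometric")
    expect_lt(max(abs(G * t(G) - 1)), 1e-12)
  }
})

test_that("AIJ arithmetic/median aggregate the elicited upper triangle and warn", {
  m <- function(v) matrix(c(1, 1 / v, v, 1), 2, 2)
  expect_warning(G <- aggregate_judgments(list(m(2), m(8)), "arithmetic"),
                 "reciprocity")
  expect_equal(G[1, 2], 5)
  expect_equal(G[2, 1], 1 / 5)  # mirrored, not the mean of the reciprocals
  expect_warning(M <- aggregate_judgments(list(m(2), m(4), m(9)), "median"),
                 "reciprocity")
  expect_equal(M[1, 2], 4)
  expect_error(aggregate_judgments(list()), "no matrices")
  expect_error(aggregate_judgments(list(m(2), random_reciprocal(3))),
               "share block")
})

test_that("AIP aggregation matches hand results and renormalizes", {
  v1 <- c(0.8, 0.2); v2 <- c(0.2, 0.8)
  expect_equal(unname(aggregate_priorities(list(v1, v2))), c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(unname(aggregate_priorities(list(v1, v1, v1))), v1,
               ignore_attr = TRUE)
  expect_equal(unname(aggregate_priorities(list(c(0.6, 0.4), c(0.2, 0.8)),
                                           "arithmetic")),
               c(0.4, 0.6), ignore_attr = TRUE)
  w <- aggregate_priorities(list(v1, v2), "geometric")
  expect_equal(sum(w), 1)
  expect_lt(sum(attr(w, "raw")), 1)  # geometric means lose mass pre-normalization
})

test_that("geometric aggregate never exceeds the arithmetic aggregate", {
  set.seed(43)
  for (rep in 1:50) {
    W <- matrix(runif(5 * 4, 0.01, 1), 5, 4)
    W <- W / rowSums(W)
    g <- attr(aggregate_priorities(W, "geometric"), "raw")
    a <- attr(aggregate_priorities(W, "arithmetic"), "raw")
    expect_true(all(g <= a + 1e-12))
  }
})

test_that("AIP geometric aggregation satisfies the Pareto axiom", {
  set.seed(44)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    W <- matrix(runif(n * 4, 0.01, 1), n, 4)
    W <- W / rowSums(W)
    agg <- aggregate_priorities(W, "geometric")
    for (i in 1:3) {
      for (j in (i + 1):4) {
        if (all(W[, i] > W[, j])) expect_gt(agg[i], agg[j])
        if (all(W[, i] < W[, j])) expect_lt(agg[i], agg[j])
      }
    }
  }
})

test_that("all six scenarios coincide for a homogeneous consistent cohort", {
  h <- study_hierarchy()
  cfg <- synthetic_config(hierarchy = h, true_local = ongrid_true_local(),
                          kappa = 1e9, sigma = 0, n_respondents = 6, seed = 5)
  sim <- simulate_study(cfg)
  fits <- list()
  for (mode in c("AIJ", "AIP")) {
    for (central in c("geometric", "arithmetic", "median")) {
      fits[[paste(mode, central)]] <- suppressWarnings(
        ahp(sim$judgments, h, mode = mode, central = central))
    }
  }
  ref <- fits[[1]]$global
  for (f in fits[-1]) expect_equal(f$global, ref, tolerance = 1e-9)
  # and individual CRs are zero: the matrices are exactly consistent
  expect_lt(max(fits[["AIJ geometric"]]$consistency$cr), 1e-10)
  for (rep in fits[["AIJ geometric"]]$group_consistency) expect_lt(rep$cr, 1e-10)
})

test_that("competition ranking handles ties and tolerance", {
  rt <- rank_table(c(m = 0.4548, s = 0.1575, r = 0.1314, e = 0.0913))
  expect_equal(stats::setNames(rt$rank, rt$item),
               c(m = 1L, s = 2L, r = 3L, e = 4L))
  expect_equal(rank_table(c(a = 1, b = 1, c = 1))$rank, rep(1L, 3))
  expect_equal(rank_table(c(a = 3, b = 2, c = 2, d = 1))$rank,
               c(1L, 2L, 2L, 4L))
  # weights within tie_tol tie; just outside do not
  expect_equal(rank_table(c(a = 0.5, b = 0.5 - 1e-10, c = 0.2))$rank,
               c(1L, 1L, 3L))
  expect_equal(rank_table(c(a = 0.5, b = 0.5 - 1e-6, c = 0.2))$rank,
               c(1L, 2L, 3L))
})

test_that("rank spans across the six aggregation scenarios match the shipped table", {
  tab <- read.csv(system.file("extdata", "aggregation_rank_table.csv",
                              package = "prefrank"))
  # every scenario column is a complete ranking of the 13 criteria
  for (col in setdiff(names(tab), "item")) {
    expect_setequal(tab[[col]], 1:13)
  }
  expect_equal(rank_span(tab, "selfhelp"), c(min = 7, max = 13))
  expect_equal(rank_span(tab, "studies"), c(min = 5, max = 11))
  expect_equal(rank_span(tab, "medical"), c(min = 1, max = 1))
  expect_error(rank_span(tab, "nonesuch"), "not present")
  # identical tables give a zero-width span
  rt <- rank_table(c(a = 3, b = 2, c = 1))
  expect_equal(rank_span(list(rt, rt, rt), "b"), c(min = 2, max = 2))
})

test_that("rank reversal detection reports moved items sorted by shift", {
  rt <- rank_table(c(a = 3, b = 2, c = 1))
  expect_identical(nrow(rank_reversals(rt, rt)), 0L)

  swapped <- rank_table(c(a = 3, b = 1, c = 2))
  rr <- rank_reversals(rt, swapped)
  expect_setequal(rr$item, c("b", "c"))
  expect_true(all(abs(rr$delta) == 1))

  # the threshold-change pattern at level three: law counseling climbs 13 -> 9
  # while psychosocial counseling falls 10 -> 13
  strict <- c(med = 1, diag = 2, treat = 3, soc = 4, res = 5, ev = 6, self = 7,
              pat = 8, stud = 9, psych = 10, reg = 11, resu = 12, law = 13)
  lenient <- c(med = 1, diag = 2, treat = 3, soc = 4, res = 5, ev = 6, self = 7,
               pat = 8, law = 9, resu = 10, reg = 11, stud = 12, psych = 13)
  rr2 <- rank_reversals(strict, lenient)
  expect_equal(rr2$item[1], "law")
  expect_equal(rr2[rr2$item == "law", c("rank_a", "rank_b")],
               data.frame(rank_a = 13, rank_b = 9),
               ignore_attr = TRUE)
  expect_equal(rr2[rr2$item == "psych", c("rank_a", "rank_b")],
               data.frame(rank_a = 10, rank_b = 13),
               ignore_attr = TRUE)
  expect_true(all(diff(abs(rr2$delta)) <= 0))
  expect_error(rank_reversals(strict, lenient[-1]), "different item sets")
})
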