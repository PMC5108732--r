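test_that("tau-b reproduces textbook values", {
  expect_equal(kendall_tau_b(1:4, 1:4)$tau_b, 1)
  expect_equal(kendall_tau_b(1:4, 4:1)$tau_b, -1)
  r <- kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$tau_b, 2 / 3, tolerance = 1e-12)
  expect_equal(r$concordant, 5)
  expect_equal(r$discordant, 1)
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
  expect_error(kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "entirely tied")
})

test_that("tau-b equals brute-force pair enumeration on all small permutation pairs", {
  for (n in 2:4) {
    perms <- all_perms(n)
    for (i in seq_len(nrow(perms))) {
      for (j in seq_len(nrow(perms))) {
        x <- perms[i, ]; y <- perms[j, ]
        expect_identical(kendall_tau_b(x, y, p_method = "none")$tau_b,
                         tau_b_oracle(x, y))
      }
    }
  }
})

test_that("tau-b equals the oracle and base R on random tied vectors", {
  set.seed(71)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- kendall_tau_b(x, y, p_method = "none")$tau_b
    expect_equal(got, tau_b_oracle(x, y), tolerance = 1e-14)
    expect_equal(got, cor(x, y, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("tau-b is antisymmetric and permutation invariant", {
  set.seed(72)
  for (rep in 1:25) {
    n <- 8
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(n)  # untied
    if (length(unique(x)) < 2) next
    t1 <- kendall_tau_b(x, y, p_method = "none")$tau_b
    expect_equal(kendall_tau_b(x, max(y) + 1 - y, p_method = "none")$tau_b, -t1)
    p <- sample(n)
    expect_equal(kendall_tau_b(x[p], y[p], p_method = "none")$tau_b, t1)
  }
})

test_that("p-values agree with cor.test and the exact method is symmetric", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  got <- kendall_tau_b(x, y, p_method = "normal")
  ref <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE,
                                   continuity = FALSE))
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)

  ex <- kendall_tau_b(x, y, p_method = "exact")
  ref_ex <- cor.test(x, y, method = "kendall", exact = TRUE)
  expect_equal(ex$p_value, unname(ref_ex$p.value), tolerance = 1e-10)
  expect_error(kendall_tau_b(1:9, 9:1, p_method = "exact"), "n <= 8")
})

test_that("pooled tau-b accumulates within-respondent pairs only", {
  x <- list(c(1, 2, 3, 4)); y <- list(c(1, 3, 2, 4))
  expect_equal(pooled_tau(x, y)$tau_b, kendall_tau_b(x[[1]], y[[1]])$tau_b)

  xs <- replicate(5, sample(4), simplify = FALSE)
  expect_equal(pooled_tau(xs, xs)$tau_b, 1)

  # pairs never cross respondents: two respondents with opposite rankings
  # pool to tau 0 even though concatenation would not
  xs2 <- list(1:4, 1:4); ys2 <- list(1:4, 4:1)
  expect_equal(pooled_tau(xs2, ys2)$tau_b, 0)
  expect_equal(pooled_tau(xs2, ys2)$n_pairs, 12)
  expect_error(pooled_tau(list(), list()), "no respondents")
})

test_that("pooled tau-b of independent random rankings is near zero", {
  set.seed(73)
  taus <- vapply(1:5, function(k) {
    xs <- replicate(200, sample(4), simplify = FALSE)
    ys <- replicate(200, sample(4), simplify = FALSE)
    pooled_tau(xs, ys, p_method = "none")$tau_b
  }, numeric(1))
  expect_lt(abs(mean(taus)), 0.05)
})

test_that("card aggregation uses median ranks with competition re-ranking", {
  cards <- data.frame(
    respondent_id = rep(c("r1", "r2", "r3"), each = 3),
    criterion_id = rep(c("a", "b", "c"), 3),
    rank = c(1, 2, 3, 1, 3, 2, 1, 2, 2))
  agg <- aggregate_cards(cards)
  r <- stats::setNames(agg$rank, agg$item)
  expect_equal(r[["a"]], 1L)
  # b and c share median rank 2 -> tied at position 2
  expect_equal(r[["b"]], 2L)
  expect_equal(r[["c"]], 2L)
})

test_that("the method comparison table lines up methods per block", {
  fixture <- read.csv(system.file("extdata", "method_comparison.csv",
                                  package = "prefrank"))
  # per-block BWS values are unit-rescaled: one 1, one 0 in every block
  for (b in unique(fixture$block)) {
    v <- fixture$bws_value[fixture$block == b]
    expect_equal(sum(v == 1), 1)
    expect_equal(sum(v == 0), 1)
  }
  # at level two the three methods agree on medical(1) and social(2)
  lvl2 <- fixture[fixture$block == "goal", ]
  expect_equal(unlist(lvl2[lvl2$item == "medical",
                           c("bws_rank", "ahp_rank", "card_rank")]),
               c(bws_rank = 1, ahp_rank = 1, card_rank = 1))
  expect_equal(unlist(lvl2[lvl2$item == "social",
                           c("bws_rank", "ahp_rank", "card_rank")]),
               c(bws_rank = 2, ahp_rank = 2, card_rank = 2))

  h <- study_hierarchy()
  sim <- simulate_study(synthetic_config(hierarchy = h, n_respondents = 8,
                                         seed = 9))
  fit <- ahp(sim$judgments, h, cr_threshold = 1)
  bfit <- bws(sim$bws_choices, sim$bws_design)
  tab <- method_comparison(fit, bfit, cards = sim$cards)
  expect_setequal(tab$item, elicited_nodes(h))
  # internal cross-check: rank columns equal rank_table of each method's scores
  for (b in names(h$blocks)) {
    sub <- tab[tab$block == b, ]
    rt <- rank_table(fit$local[[b]])
    expect_equal(stats::setNames(sub$ahp_rank, sub$item),
                 stats::setNames(rt$rank[match(sub$item, rt$item)], sub$item))
  }
  # single-method input leaves explicit gaps
  partial <- method_comparison(fit, NULL, hierarchy = h)
  expect_true(all(is.na(partial$bws_value)))
  expect_false(anyNA(partial$ahp_rank))
})
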