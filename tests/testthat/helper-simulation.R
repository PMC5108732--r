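# Monte-Carlo harnesses for the calibration studies (BCa coverage of the
# AIP-geometric level-two weight, and true-ranking recovery).

# One cohort's log estimated level-two weights: latent Dirichlet weights ->
# noisy snapped judgment matrix -> eigenvector, per respondent.
level2_log_weights <- function(n, kappa, sigma, seed,
                               h = prefrank::info_hierarchy()) {
  cfg <- prefrank::synthetic_config(hierarchy = h, kappa = kappa,
                                    sigma = sigma, n_respondents = n,
                                    seed = seed)
  W <- prefrank::sample_respondent_weights(cfg)$goal
  t(apply(W, 1, function(w) {
    A <- prefrank::judgments_from_weights(w, sigma)
    log(prefrank::principal_eigenvector(A)$weights)
  }))
}

# Empirical coverage of the nominal (1 - alpha) BCa interval for the largest
# level-two global weight. The estimand is the population value of the
# statistic itself (the normalized geometric mean of estimated weights),
# approximated once from a large cohort.
bca_coverage_study <- function(n_rep = 300, n = 30, kappa = 50, sigma = 0.15,
                               B = 1000, alpha = 0.05, seed = 101,
                               n_pop = 20000) {
  pop <- level2_log_weights(n_pop, kappa, sigma, seed)
  mu <- colMeans(pop)
  theta_all <- exp(mu) / sum(exp(mu))
  node <- which.max(theta_all)
  theta <- theta_all[node]

  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    logW <- level2_log_weights(n, kappa, sigma, seed + r)
    obs_all <- exp(colMeans(logW))
    obs <- (obs_all / sum(obs_all))[node]
    idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
    counts <- t(apply(idx, 1, tabulate, nbins = n))
    LM <- counts %*% logW / n
    S <- exp(LM)
    stat <- S[, node] / rowSums(S)
    loo <- (matrix(colSums(logW), n, ncol(logW), byrow = TRUE) - logW) /
      (n - 1)
    J <- exp(loo)
    jack <- J[, node] / rowSums(J)
    ci <- prefrank::bca_interval(stat, obs, jack, alpha = alpha)
    hits[r] <- theta >= ci$lower && theta <= ci$upper
  }
  list(coverage = mean(hits), theta = theta, node = node, n_rep = n_rep)
}

# Mean tau-b between the true global ranking and the AIP-geometric recovered
# ranking over replicated synthetic cohorts (well-separated profile).
recovery_study <- function(sigma, n_rep = 100, n = 30, kappa = 50,
                           seed = 7000, true_local = separated_true_local()) {
  h <- prefrank::info_hierarchy()
  taus <- vapply(seq_len(n_rep), function(r) {
    cfg <- prefrank::synthetic_config(hierarchy = h, true_local = true_local,
                                      kappa = kappa, sigma = sigma,
                                      n_respondents = n, seed = seed + r)
    sim <- prefrank::simulate_study(cfg)
    fit <- prefrank::ahp(sim$judgments, h, cr_threshold = 1)
    true_rt <- prefrank::rank_table(sim$true_global)
    got <- stats::setNames(fit$ranking$rank, fit$ranking$item)
    prefrank::kendall_tau_b(stats::setNames(true_rt$rank, true_rt$item),
                            got[true_rt$item], p_method = "none")$tau_b
  }, numeric(1))
  mean(taus)
}
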