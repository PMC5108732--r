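# Independent oracles and small fixtures shared across tests.

# dense eigensolver oracle for the Perron vector (independent of the
# package's power iteration)
eigen_oracle <- function(A) {
  e <- eigen(A)
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < 0)) v <- -v / sum(-v)
  list(weights = v, lambda_max = Re(e$values[i]))
}

# brute-force tau-b by explicit pair enumeration
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- (x[i] - x[j]) * (y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  tie_pairs <- function(v) {
    sum(vapply(split(v, v), function(g) length(g) * (length(g) - 1) / 2,
               numeric(1)))
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
}

# perfectly consistent reciprocal matrix from a positive weight vector
consistent_matrix <- function(w) {
  A <- outer(w, w, `/`)
  dimnames(A) <- list(names(w), names(w))
  A
}

# random reciprocal matrix with Saaty-grid upper triangle
random_reciprocal <- function(n) {
  A <- diag(n)
  grid <- prefrank::saaty_scale()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- sample(grid, 1)
      A[i, j] <- v
      A[j, i] <- 1 / v
    }
  }
  A
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# well-separated true-weight profile for recovery tests: pairwise weight
# gaps large relative to sampling noise, so the generative model's ranking
# is identifiable (the shipped study-median profile intentionally contains
# near-ties, which Saaty-grid quantization cannot resolve)
separated_true_local <- function() {
  list(goal = c(medical = 0.52, research = 0.24, events = 0.10, social = 0.14),
       medical = c(diagnosis = 0.65, treatment = 0.24, patterns = 0.11),
       research = c(studies = 0.70, results = 0.21, registries = 0.09),
       social = c(law = 0.58, psychosocial = 0.30, selfhelp = 0.12))
}

# on-grid profile: every within-block ratio lies exactly on the Saaty grid,
# so sigma = 0 produces exactly consistent matrices
ongrid_true_local <- function() {
  list(goal = c(medical = 8, research = 4, events = 1, social = 2) / 15,
       medical = c(diagnosis = 4, treatment = 2, patterns = 1) / 7,
       research = c(studies = 4, results = 2, registries = 1) / 7,
       social = c(law = 4, psychosocial = 2, selfhelp = 1) / 7)
}

study_hierarchy <- function() prefrank::info_hierarchy()

# tiny two-level hierarchy for cheap unit tests
toy_hierarchy <- function() {
  prefrank::criteria_hierarchy(data.frame(
    id = c("goal", "a", "b", "c"),
    label = c("Goal", "A", "B", "C"),
    parent = c(NA, "goal", "goal", "goal"),
    queried = c(TRUE, FALSE, FALSE, FALSE)))
}
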