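# Shared fixtures and independent brute-force oracles used across tests.

# standard dynamic frame grid: 115 frames at 2.5 s
frame_times <- function() (0:114) * 2.5

# default population AIF on the frame grid
fixture_aif <- function(times = frame_times()) population_aif(times)

# --- enumeration oracles (independent of the package implementations) ----

# exact two-sided Mann-Whitney p by enumerating all label arrangements
bf_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

# exact two-sided Spearman p by full permutation of y
bf_spearman_p <- function(x, y) {
  rho_obs <- stats::cor(x, y, method = "spearman")
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perms(y), function(p) stats::cor(x, p, method = "spearman"),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Benjamini-Hochberg by the direct step-up definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  adj
}

# pairwise-concordance AUC (positive class = "high"-like second sample)
bf_auc <- function(neg, pos) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
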