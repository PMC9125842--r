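# Brute-force oracles for the rank statistics, independent of stats::

# Mann-Whitney U and exact two-sided p by enumerating every assignment
# of the pooled observations to the two groups (no ties assumed)
mw_enum <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + length(y), m)
  us <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(u = u_obs, p = p)
}

# Wilcoxon signed-rank V and exact two-sided p by enumerating all 2^n
# sign patterns (non-zero, untied |d| assumed)
wsr_enum <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  p <- min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
  list(v = v_obs, p = p)
}

# Spearman coefficient from the rank-difference formula (untied data)
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) {
    return(matrix(1))
  }
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exact two-sided permutation p-value for Spearman's coefficient
spearman_perm_p <- function(x, y) {
  r_obs <- abs(spearman_formula(x, y))
  pm <- perms(length(y))
  rs <- apply(pm, 1, function(i) spearman_formula(x, y[i]))
  mean(abs(rs) >= r_obs - 1e-12)
}
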