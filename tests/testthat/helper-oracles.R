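# Independent oracles, deliberately written as direct enumerations that
# share no code with the package implementations they check.

# Per-branch UniFrac by explicit recursion over the tree.
oracle_tips_under <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) oracle_tips_under(tree, k)))
}

oracle_unifrac <- function(a, b, tree, weighted = FALSE, normalized = FALSE) {
  pa <- a / sum(a); pb <- b / sum(b)
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- oracle_tips_under(tree, tree$edge[k, 2])
    len <- tree$edge.length[k]
    if (weighted) {
      qa <- sum(pa[tips]); qb <- sum(pb[tips])
      num <- num + len * abs(qa - qb)
      den <- den + len * (qa + qb)
    } else {
      ia <- any(a[tips] > 0); ib <- any(b[tips] > 0)
      num <- num + len * as.numeric(xor(ia, ib))
      den <- den + len * as.numeric(ia || ib)
    }
  }
  if (weighted && !normalized) num else num / den
}

# Efron partial log-likelihood for a single covariate, summed term by term.
oracle_efron_loglik <- function(beta, start, stop, event, x) {
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    D <- which(event == 1 & stop == t)
    R <- which(start < t & t <= stop)
    d <- length(D)
    ll <- ll + sum(x[D] * beta)
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum(exp(x[R] * beta)) - (l / d) * sum(exp(x[D] * beta)))
  }
  ll
}

# Exact Mann-Whitney p-value by enumerating all group assignments.
oracle_rank_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  centre <- length(x) * (length(pooled) + 1) / 2
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-9)
}

# Smallest covering subset size by exhaustive search (hitting-set oracle).
oracle_min_cover_size <- function(profiles, target, detect_threshold,
                                  demotion_factor, max_size = 3) {
  others <- setdiff(rownames(profiles), target)
  cand <- colnames(profiles)[profiles[target, ] >= detect_threshold]
  resolves <- function(o, j) profiles[j, o] < detect_threshold / demotion_factor
  for (k in seq_len(max_size)) {
    sets <- utils::combn(cand, k, simplify = FALSE)
    for (s in sets) {
      ok <- all(vapply(others, function(j)
        any(vapply(s, resolves, logical(1), j = j)), logical(1)))
      if (ok) return(k)
    }
  }
  Inf
}
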