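# Independent oracles and small fixture builders, kept deliberately naive:
# explicit set operations, double loops and choose()-based enumeration,
# never the code paths they check.

make_fc <- function(values, genes, compounds, system_id = "sys",
                    condition = c(dose = "high", time = "24h")) {
  m <- matrix(values, nrow = length(genes), ncol = length(compounds),
              dimnames = list(genes, compounds))
  fold_change_matrix(m, system_id, condition)
}

# random topk signature over a gene universe
rand_signature <- function(id, universe, k) {
  picked <- sample(universe, 2L * k)
  tgx_signature(id, up = picked[seq_len(k)], down = picked[k + seq_len(k)],
                mode = "topk", k = k)
}

# random threshold signature (possibly empty)
rand_threshold_signature <- function(id, universe) {
  n_up <- sample(0:5, 1L)
  n_down <- sample(0:5, 1L)
  picked <- sample(universe, n_up + n_down)
  tgx_signature(id, up = picked[seq_len(n_up)],
                down = picked[n_up + seq_len(n_down)], mode = "threshold")
}

# brute-force direction-aware Dice from explicit set intersections
dice_oracle <- function(a, b) {
  n_up <- sum(a$up %in% b$up)
  n_down <- sum(a$down %in% b$down)
  denom <- length(a$up) + length(a$down) + length(b$up) + length(b$down)
  if (denom == 0) return(0)
  2 * (n_up + n_down) / denom
}

# brute-force AUC: fraction of concordant positive-negative score pairs,
# ties counting 1/2
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# hypergeometric upper tail P(X >= k) by direct enumeration of the pmf
hyper_tail_oracle <- function(k, K, n, N) {
  lo <- max(0L, n + K - N)
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- max(k, lo):hi
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# BH step-up from the definition: adj(i) = min_{j >= i} p(j) * m / j,
# capped at 1, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  raw <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
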