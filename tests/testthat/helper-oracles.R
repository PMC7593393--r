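# Independent brute-force oracle: exhaustive within-subject TANOVA p for a
# 2-condition design, written directly from the definitions.
oracle_tanova_2cond <- function(maps) {
  # maps: n x 2 x K (single time point)
  n <- dim(maps)[1]
  K <- dim(maps)[3]
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  norm <- function(x) x / psd(x)
  X <- maps
  for (s in seq_len(n)) for (c in 1:2) X[s, c, ] <- norm(maps[s, c, ])
  gm <- apply(X, 3, mean)
  effect_for <- function(swap) {
    m1 <- colMeans(t(vapply(seq_len(n), function(s) X[s, if (swap[s]) 2 else 1, ], numeric(K))))
    m2 <- colMeans(t(vapply(seq_len(n), function(s) X[s, if (swap[s]) 1 else 2, ], numeric(K))))
    psd(m1 - gm) + psd(m2 - gm)
  }
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  effects <- apply(swaps, 1, effect_for)
  obs <- effect_for(rep(FALSE, n))
  list(p = mean(effects >= obs - 1e-12), obs = obs, effects = effects)
}
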