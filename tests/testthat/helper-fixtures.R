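# Shared fixtures: random sequences, a small fast architecture, and a
# finite-difference oracle for saliency gradients.

random_dna <- function(l, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), l, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Minimal legal architecture (l = 100) for fast training tests.
tiny_arch <- function(pool_1 = 10, n_filters_1 = 6) {
  architecture_spec(100, n_filters_1 = n_filters_1, filter_size_1 = 9,
                    pool_1 = pool_1, n_filters_2 = 8, filter_size_2 = 5,
                    hidden_units = 16)
}

tiny_training <- function(epochs = 3, seed = 1L, dropout = 0.5) {
  training_spec(epochs = epochs, seed = seed, dropout = dropout)
}

# Separable toy dataset: promoters all-G, enhancers all-A.
separable_dataset <- function(n_per_class, l) {
  seqs <- c(replicate(n_per_class, strrep("G", l)),
            replicate(n_per_class, strrep("A", l)))
  tss_dataset(seqs, rep(c(1L, 0L), each = n_per_class))
}

# Central finite difference of the pre-sigmoid score with respect to one
# input coordinate. Returns NA at kinks (ReLU zero crossings / max-pool
# argmax switches), detected by disagreement of the one-sided differences:
# there the analytic gradient and any finite difference legitimately
# differ, so the oracle abstains.
fd_score_grad <- function(model, x, i, ch, eps = 1e-3) {
  f <- function(m) predict(model, m, type = "score")
  xp <- x; xp[i, ch] <- xp[i, ch] + eps
  xm <- x; xm[i, ch] <- xm[i, ch] - eps
  f0 <- f(x); fp <- f(xp); fm <- f(xm)
  fwd <- (fp - f0) / eps
  bwd <- (f0 - fm) / eps
  if (abs(fwd - bwd) > 0.05 * (abs(fwd) + abs(bwd)) + 1e-8) return(NA_real_)
  (fp - fm) / (2 * eps)
}

# O(n^2) pairwise AUC oracle: P(score_pos > score_neg) + 0.5 P(tie).
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
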