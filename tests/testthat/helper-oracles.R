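# Independent oracles and fixture builders. Everything here is written as
# naive, literal computation, deliberately separate from the package code
# paths it checks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Second, independently-typed transcription of the Hellberg z1-z3 scales
# (from the Sandberg et al. 1998 reproduction), used to cross-check the
# packaged data file against transcription errors.
zscale_reference <- function() {
  m <- rbind(
    A = c( 0.07, -1.73,  0.09), R = c( 2.88,  2.52, -3.44),
    N = c( 3.22,  1.45,  0.84), D = c( 3.64,  1.13,  2.36),
    C = c( 0.71, -0.97,  4.13), Q = c( 2.18,  0.53, -1.14),
    E = c( 3.08,  0.39, -0.07), G = c( 2.23, -5.36,  0.30),
    H = c( 2.41,  1.74,  1.11), I = c(-4.44, -1.68, -1.03),
    L = c(-4.19, -1.03, -0.98), K = c( 2.84,  1.41, -3.14),
    M = c(-2.49, -0.27, -0.41), F = c(-4.92,  1.30,  0.45),
    P = c(-1.22,  0.88,  2.23), S = c( 1.96, -1.63,  0.57),
    T = c( 0.92, -2.09, -1.40), W = c(-4.75,  3.65,  0.85),
    Y = c(-1.39,  2.32,  0.01), V = c(-2.69, -2.53, -1.29))
  colnames(m) <- c("z1", "z2", "z3")
  m
}

# literal quadruple-loop ACC: pairs (j,k) in the frozen layout order,
# lags 1..L, explicit sum over positions
acc_oracle <- function(zmat, L = 5L) {
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3),
                c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  n <- nrow(zmat)
  out <- numeric(0)
  for (p in pairs) {
    for (l in seq_len(L)) {
      s <- 0
      for (i in seq_len(n - l)) {
        s <- s + zmat[i, p[1]] * zmat[i + l, p[2]]
      }
      out <- c(out, s / (n - l))
    }
  }
  as.numeric(out)
}

# exhaustive-distance kNN: compute every training distance, sort fully
knn_oracle <- function(X, labels, q, k, threshold = 0.5,
                       metric = "euclidean") {
  d <- apply(X, 1L, function(r) {
    if (metric == "euclidean") sqrt(sum((r - q)^2)) else sum(abs(r - q))
  })
  d <- unname(d)
  ord <- order(d, seq_along(d))
  idx <- ord[seq_len(k)]
  score <- sum(labels[idx] == "allergen") / k
  list(score = score,
       verdict = if (score >= threshold) "Probable Allergen"
                 else "Probable Non-allergen",
       idx = idx, dist = d[idx])
}

# O(n^2) pair-count AUC with half credit for ties
auc_oracle <- function(scores, is_pos) {
  ps <- scores[is_pos]
  ns <- scores[!is_pos]
  tot <- 0
  for (a in ps) {
    for (b in ns) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(ps) * length(ns))
}

rand_seq <- function(len, freqs = NULL) {
  paste(sample(AA20, len, replace = TRUE, prob = freqs), collapse = "")
}

# tiny labelled FASTA fixture written into `dir`; returns the two paths
write_tiny_fixture <- function(dir, n_per_class = 10L, seed = 99L) {
  ds <- generate_synthetic(synthetic_spec(
    n_per_class = n_per_class, length_range = c(30L, 60L), seed = seed))
  fa <- file.path(dir, "tiny.fasta")
  lab <- file.path(dir, "tiny.tsv")
  write_labeled_fasta(ds, fa, lab)
  list(fasta = fa, labels = lab, dataset = ds)
}
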