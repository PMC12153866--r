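# Independent oracles reused across test files. They deliberately use plain
# loops / base table arithmetic, never the package's own code paths.

# Elementwise epsilon-rule relevance propagation for one sample through a
# relu-affine stack (weights W, biases b), explaining the argmax output.
oracle_lrp <- function(W, b, x, eps) {
  acts <- list(x)
  for (l in seq_along(W)) {
    z <- as.numeric(x %*% W[[l]]) + b[[l]]
    x <- if (l < length(W)) pmax(z, 0) else z
    acts[[l + 1L]] <- x
  }
  out <- acts[[length(W) + 1L]]
  ti <- which.max(out)
  R <- numeric(length(out)); R[ti] <- out[ti]
  for (l in rev(seq_along(W))) {
    a <- acts[[l]]
    Rin <- numeric(length(a))
    z <- as.numeric(a %*% W[[l]]) + b[[l]]
    for (j in seq_along(z)) {
      denom <- if (z[j] >= 0) z[j] + eps else z[j] - eps
      for (i in seq_along(a)) {
        Rin[i] <- Rin[i] + a[i] * W[[l]][i, j] / denom * R[j]
      }
    }
    R <- Rin
  }
  list(relevance = R, pre_softmax = out[ti])
}

# One-vs-rest precision/recall/F1/MCC from first principles.
oracle_metrics <- function(truth, pred, cl) {
  tp <- sum(truth == cl & pred == cl); fp <- sum(truth != cl & pred == cl)
  fn <- sum(truth == cl & pred != cl); tn <- sum(truth != cl & pred != cl)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- sqrt((tp + fn)) * sqrt((tp + fp)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(precision = prec, recall = rec, f1 = f1, mcc = mcc)
}
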