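# Independent brute-force double-loop implementation of the lagged
# correlation estimator; the oracle the vectorized implementation is
# checked against.
ccf_bruteforce <- function(yA, yB, nlag) {
  L <- length(yA)
  Z <- sqrt(var(yA) * var(yB))
  am <- mean(yA); bm <- mean(yB)
  out <- numeric(2 * nlag + 1)
  for (t in -nlag:nlag) {
    acc <- 0
    if (t >= 0) {
      for (s in 1:(L - t)) acc <- acc + (yA[s + t] - am) * (yB[s] - bm)
    } else {
      for (s in (1 - t):L) acc <- acc + (yA[s + t] - am) * (yB[s] - bm)
    }
    out[t + nlag + 1] <- acc / (L * Z)
  }
  out
}
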