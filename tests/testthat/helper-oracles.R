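## Independent oracles used to validate the analytic implementations.

## Two-sided Fisher p by brute-force enumeration of every table with the
## observed margins; probabilities from binomial coefficients, not dhyper.
fisherOracle <- function(cA, nA, cB, nB) {
  K <- cA + cB
  N <- nA + nB
  supp <- max(0, K - nB):min(K, nA)
  prob <- vapply(supp, function(x) {
    choose(nA, x) * choose(nB, K - x) / choose(N, K)
  }, numeric(1))
  pObs <- choose(nA, cA) * choose(nB, K - cA) / choose(N, K)
  min(1, sum(prob[prob <= pObs * (1 + 1e-7)]))
}

## Upper-tail binomial P(X >= c) by explicit term-by-term summation in
## log space (no pbinom).
binomTailOracle <- function(c, n, p0) {
  if (c <= 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  k <- c:n
  sum(exp(lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)))
}
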