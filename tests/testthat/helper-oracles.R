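# independent oracles, deliberately brute force

# one-sided Fisher exact: tail of the hypergeometric by direct enumeration
# over all tables with the observed margins, using only choose()
fisher_tail_oracle <- function(kA, nA, kB, nB) {
  m <- kA + kB
  N <- nA + nB
  js <- kA:min(nA, m)
  if (length(js) == 0L || kA > min(nA, m)) return(0)
  sum(choose(m, js) * choose(N - m, nA - js)) / choose(N, nA)
}

# AUROC by counting concordant positive/negative pairs (ties count half)
auroc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}
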