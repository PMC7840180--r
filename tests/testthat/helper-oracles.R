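# Independent reference implementations used to validate the package's
# estimators. They re-derive each quantity from its definition and share
# no code with the implementation under test.

# discrete joint-histogram mutual information by direct summation
mi_oracle <- function(f, m) {
  tab <- table(f, m)
  p <- tab / sum(tab)
  pf <- rowSums(p); pm <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pf[i] * pm[j]))
  }
  as.numeric(s)
}
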