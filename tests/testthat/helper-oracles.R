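# Independent oracles used by several test files.

brute_force_theils_u <- function(x, y) {
  # enumerate the joint distribution directly, no shared code with theils_u()
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  n <- length(x)
  hx <- H(table(x) / n)
  if (hx == 0) return(1)
  hxy <- 0
  for (yv in unique(y)) {
    sel <- y == yv
    hxy <- hxy + sum(sel) / n * H(table(x[sel]) / sum(sel))
  }
  (hx - hxy) / hx
}
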