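# Independent brute-force oracles. These deliberately use naive factorial
# arithmetic and explicit enumeration, not the package's log-gamma /
# dhyper code paths.

# exact HWE p by enumerating every heterozygote count with plain factorials
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- min(2 * n0 + n1, 2 * n2 + n1)
  if (na == 0) return(1)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  w <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- (2 * n - na - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)) *
      2^h
  }, numeric(1))
  p <- w / sum(w)
  obs <- p[hets == n1]
  sum(p[p <= obs * (1 + 1e-9)])
}

# two-sided Fisher p by enumerating every table with the observed margins,
# using choose() directly
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; n1 <- a + c; tot <- a + b + c + d
  if (m1 == 0 || m1 == tot || n1 == 0 || n1 == tot) return(1)
  supp <- max(0, n1 + m1 - tot):min(m1, n1)
  w <- choose(m1, supp) * choose(tot - m1, n1 - supp)
  p <- w / sum(w)
  obs <- p[supp == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# AUC by explicit enumeration of all case-control pairs
oracle_auc <- function(scores, y) {
  cases <- scores[y]; ctrls <- scores[!y]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  tot / (length(cases) * length(ctrls))
}
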