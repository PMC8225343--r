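# Independent oracles used to freeze expected values. These deliberately
# avoid the package's computational paths.

# stationary sampling log-probability by adaptive quadrature of the Wright
# density mixed with the binomial kernel, through the inverse-CDF
# substitution E[e^{g x}] = int_0^1 exp(g * qbeta(u, s1, s2)) du, which is
# bounded and smooth
oracle_log_pmf <- function(k, n, a, b, g) {
  Eexp <- function(s1, s2)
    integrate(function(u) exp(g * qbeta(u, s1, s2)),
              0, 1, rel.tol = 1e-11, abs.tol = 0)$value
  lchoose(n, k) + lbeta(b + k, a + n - k) - lbeta(b, a) +
    log(Eexp(b + k, a + n - k)) - log(Eexp(b, a))
}

# textbook Benjamini-Hochberg by explicit rank computation: adjusted p of
# the i-th order statistic is min over j >= i of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  stepped <- rev(cummin(rev(sorted * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(stepped, 1)
  adj
}

# hypergeometric projection by exhaustive subset enumeration (n <= ~10)
oracle_projection <- function(k, n, n_prime) {
  alleles <- c(rep(1L, k), rep(0L, n - k))
  subs <- utils::combn(n, n_prime)
  counts <- apply(subs, 2, function(ix) sum(alleles[ix]))
  tabulate(counts + 1L, nbins = n_prime + 1L) / ncol(subs)
}

# beta-binomial log-pmf from the Pochhammer form (neutral limit of the model)
oracle_beta_binom <- function(k, n, alpha, beta) {
  lchoose(n, k) + lbeta(beta + k, alpha + n - k) - lbeta(beta, alpha)
}

# build a tiny state matrix from a list of per-gene state vectors
toy_state_matrix <- function(gene_states) {
  genes <- names(gene_states)
  nA <- length(gene_states[[1]])
  mat <- do.call(rbind, gene_states)
  dimnames(mat) <- list(genes, sprintf("acc%03d", seq_len(nA)))
  mat
}

# write a temporary allc-style table and return its path
write_allc_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
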