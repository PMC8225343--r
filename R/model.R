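#' Mutation-selection-drift model parameters
#'
#' Parameters of the stationary model for a biallelic epiallele (UM vs gbM)
#' in a randomly mating diploid population of constant effective size at
#' mutation-selection equilibrium, with semi-dominant alleles and independent
#' genes. `mu` is the epimutation rate UM -> gbM, `nu` the rate gbM -> UM,
#' and `s` the selection coefficient of the favored state given by
#' `orientation`. The composite parameters `alpha = 4*Ne*mu`,
#' `beta = 4*Ne*nu` and `gamma = 4*Ne*s` are always derived from the rates
#' and `Ne`, never stored independently.
#'
#' @param mu,nu Epimutation rates per generation (non-negative).
#' @param s Selection coefficient of the favored state (non-negative).
#' @param Ne Effective population size (> 0).
#' @param orientation `"UM_advantage"` or `"gbM_advantage"`.
#' @return A list of class `model_params` with elements `mu`, `nu`, `s`,
#'   `Ne`, `orientation`, `alpha`, `beta`, `gamma`.
#' @export
model_params <- function(mu, nu, s = 0, Ne,
                         orientation = c("UM_advantage", "gbM_advantage")) {
  orientation <- match.arg(orientation)
  stopifnot(mu > 0, nu > 0, s >= 0, Ne > 0)
  structure(list(mu = mu, nu = nu, s = s, Ne = Ne, orientation = orientation,
                 alpha = 4 * Ne * mu, beta = 4 * Ne * nu, gamma = 4 * Ne * s),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Stationary epiallele model (", x$orientation, ")\n",
      sprintf("  mu = %.4g, nu = %.4g, s = %.4g, Ne = %.4g\n",
              x$mu, x$nu, x$s, x$Ne),
      sprintf("  alpha = %.4g, beta = %.4g, gamma = 4*Ne*s = %.4g\n",
              x$alpha, x$beta, x$gamma), sep = "")
  invisible(x)
}

# Full log-pmf vector over k = 0..n of the stationary sampling distribution
#
#   p_k = C(n,k) 1F1(b+k, a+b+n, g) (b)_k (a)_{n-k} / [1F1(b, a+b, g) (a+b)_n]
#
# where k counts the favored allele (shape b), a = 4Ne*mu(away), b =
# 4Ne*nu(toward), g = 4Ne*s. Evaluated through the Kummer integral
# representation expanded as a Poisson-weighted mixture of beta functions,
#   int x^{b+k-1} (1-x)^{a+n-k-1} e^{gx} dx = sum_j g^j/j! B(b+k+j, a+n-k),
# entirely in log space; negative g is routed through the reflection
# p(k; a, b, g) = p(n-k; b, a, -g). Finite and accurate for n up to
# several hundred and |g| in the thousands.
stationary_log_pmf <- function(n, alpha, beta, gamma) {
  stopifnot(n >= 1, alpha > 0, beta > 0, is.finite(gamma))
  if (gamma < 0) return(rev(stationary_log_pmf(n, beta, alpha, -gamma)))
  a <- alpha; b <- beta; g <- gamma
  Jmax <- ceiling(g + 10 * sqrt(g + 1) + 25)
  j <- 0:Jmax
  lw <- if (g == 0) c(0, rep(-Inf, Jmax)) else j * log(g) - lgamma(j + 1)
  k <- 0:n
  cj <- lw - lgamma(a + b + n + j)
  M <- lgamma(outer(k + b, j, "+"))
  M <- sweep(M, 2, cj, "+")
  mx <- M[cbind(seq_len(n + 1L), max.col(M, ties.method = "first"))]
  lI <- lgamma(a + n - k) + mx + log(rowSums(exp(M - mx)))
  lZt <- lw + lgamma(b + j) - lgamma(a + b + j)
  mz <- max(lZt)
  lZ <- lgamma(a) + mz + log(sum(exp(lZt - mz)))
  out <- lchoose(n, k) + lI - lZ
  if (any(!is.finite(out)))
    stop("non-finite stationary log-pmf at n=", n, " alpha=", a,
         " beta=", b, " gamma=", g)
  out
}

#' Log sampling probability of an epiallele count under selection
#'
#' Log of the stationary probability that a sample of `n` haploid gene
#' copies contains `k` copies of the favored (UM) state, under reversible
#' epimutation (`alpha = 4*Ne*mu` toward gbM, `beta = 4*Ne*nu` toward UM)
#' and genic selection `gamma = 4*Ne*s` for the UM state. At `gamma = 0`
#' this is exactly the beta-binomial `C(n,k) (beta)_k (alpha)_{n-k} /
#' (alpha+beta)_n`; a negative `gamma` favors gbM.
#'
#' @param k Count(s) of the UM state, `0 <= k <= n` (vectorized).
#' @param n Sample size.
#' @param alpha,beta Scaled epimutation rates (> 0).
#' @param gamma Scaled selection coefficient of the UM state (any sign).
#' @return Log probabilities, same length as `k`.
#' @export
epiallele_log_pmf <- function(k, n, alpha, beta, gamma = 0) {
  stopifnot(all(k >= 0), all(k <= n))
  stationary_log_pmf(n, alpha, beta, gamma)[k + 1L]
}

# signed gamma puts both orientations on the UM-count axis: a gbM advantage
# of gamma is the reflection p(k; alpha, beta, -gamma)
signed_gamma <- function(params)
  if (params$orientation == "UM_advantage") params$gamma else -params$gamma

#' Log-likelihood of a projected SFS under the stationary model
#'
#' `sum_k d_k log p_k` over the full spectrum including the fixed classes
#' k = 0 and k = n'. The projected counts `d_k` are real valued and enter as
#' exponents of the per-class probabilities. For
#' `orientation = "gbM_advantage"` the roles of alpha and beta are exchanged
#' internally while k keeps counting UM copies.
#'
#' @param sfs A `projected_sfs`.
#' @param params A [model_params()].
#' @return The log-likelihood; `-Inf` (with a warning) if some class with
#'   `d_k > 0` has zero probability.
#' @export
sfs_log_likelihood <- function(sfs, params) {
  stopifnot(inherits(sfs, "projected_sfs"), inherits(params, "model_params"))
  lp <- stationary_log_pmf(sfs$n_prime, params$alpha, params$beta,
                           signed_gamma(params))
  if (any(!is.finite(lp) & sfs$d > 0)) {
    warning("zero model probability for an observed frequency class")
    return(-Inf)
  }
  sum(sfs$d * lp)
}

#' Expected projected SFS under fitted parameters
#'
#' @param params A [model_params()].
#' @param n_prime Sample size of the spectrum.
#' @param total Total count to distribute (e.g. retained genes).
#' @return Numeric vector `total * p_k`, k = 0..n_prime.
#' @export
expected_sfs <- function(params, n_prime, total = 1) {
  total * exp(stationary_log_pmf(n_prime, params$alpha, params$beta,
                                 signed_gamma(params)))
}

#' Sample an SFS from the stationary model
#'
#' Multinomial draw of `n_genes` genes over the frequency classes
#' k = 0..n_prime.
#'
#' @param params A [model_params()].
#' @param n_prime Sample size.
#' @param n_genes Number of genes to draw.
#' @param seed Optional integer seed.
#' @param label Label stored on the spectrum.
#' @return A `projected_sfs` with integer counts.
#' @export
simulate_sfs <- function(params, n_prime, n_genes, seed = NULL,
                         label = "simulated") {
  if (!is.null(seed)) set.seed(seed)
  p <- exp(stationary_log_pmf(n_prime, params$alpha, params$beta,
                              signed_gamma(params)))
  d <- if (n_genes > 0) as.numeric(rmultinom(1, n_genes, p))
       else numeric(n_prime + 1)
  new_projected_sfs(d, n_prime, "gene", label,
                    list(input = n_genes, retained = n_genes))
}

#' Watterson's per-site diversity estimator
#'
#' `theta_w = (S / L) / a_n` with `a_n = sum_{i=1}^{n-1} 1/i`, where `S` is
#' the number of segregating sites, `L` the number of surveyed sites and `n`
#' the number of sampled chromosomes (twice the number of diploid
#' individuals when both alleles are sequenced).
#'
#' @param S Segregating-site count.
#' @param n_chromosomes Sampled chromosome count (>= 2).
#' @param L Surveyed sites.
#' @return Per-site Watterson theta.
#' @export
watterson_theta <- function(S, n_chromosomes, L) {
  stopifnot(n_chromosomes >= 2, L > 0, S >= 0)
  (S / L) / sum(1 / seq_len(n_chromosomes - 1))
}

#' Effective population size from Watterson's theta
#'
#' Inverts `theta = 4 Ne mu` for a per-site mutation rate `mu`.
#'
#' @param theta Per-site diversity.
#' @param mu_bp Per-site per-generation mutation rate (> 0).
#' @return Effective population size estimate.
#' @export
ne_from_theta <- function(theta, mu_bp) {
  stopifnot(mu_bp > 0, theta >= 0)
  theta / (4 * mu_bp)
}
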