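#' MCMC configuration for the stationary-model fit
#'
#' Random-walk Metropolis over `log(mu)`, `log(nu)`, `log(s)` with
#' independent Gaussian steps, one parameter updated per generation in
#' rotation. Priors are uniform on the log scale with hard bounds
#' (`prior_bounds`); proposal scales are adapted toward 40% acceptance
#' during burn-in (Robbins-Monro) and frozen afterwards, and the
#' post-burn-in acceptance rates are flagged when they fall outside
#' `target_acceptance`.
#'
#' @param n_generations Chain length (default 100000).
#' @param burn_in_fraction Fraction discarded as burn-in (default 0.25).
#' @param thinning Keep one sample every `thinning` generations after
#'   burn-in (default 100; the defaults give 750 posterior samples).
#' @param proposal_scales Named initial step SDs on the log scale for
#'   `mu`, `nu`, `s`.
#' @param target_acceptance Acceptable per-parameter acceptance interval.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param n_chains Independent chains from random starting points
#'   (default 3).
#' @param prior_bounds Hard support of each rate parameter (default
#'   `c(1e-12, 1e-3)`, generous around typical epimutation-rate estimates
#'   of 1e-8 to 1e-6).
#' @param start_bounds Range the random starting points are drawn from,
#'   log-uniformly (default `c(1e-9, 1e-5)`).
#' @param adapt Adapt proposal scales during burn-in (default TRUE).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 1e5L, burn_in_fraction = 0.25,
                        thinning = 100L,
                        proposal_scales = c(mu = 1, nu = 1, s = 1),
                        target_acceptance = c(0.20, 0.70),
                        seed = NULL, n_chains = 3L,
                        prior_bounds = c(1e-12, 1e-3),
                        start_bounds = c(1e-9, 1e-5),
                        adapt = TRUE) {
  stopifnot(burn_in_fraction > 0, burn_in_fraction < 1, thinning >= 1,
            all(proposal_scales > 0), prior_bounds[1] > 0,
            prior_bounds[1] < prior_bounds[2])
  structure(list(n_generations = as.integer(n_generations),
                 burn_in_fraction = burn_in_fraction,
                 thinning = as.integer(thinning),
                 proposal_scales = proposal_scales,
                 target_acceptance = target_acceptance,
                 seed = seed, n_chains = as.integer(n_chains),
                 prior_bounds = prior_bounds, start_bounds = start_bounds,
                 adapt = adapt),
            class = "mcmc_config")
}

# one chain; returns thinned samples and per-parameter acceptance
run_one_chain <- function(sfs, Ne, orientation, config, chain_seed) {
  set.seed(chain_seed)
  lb <- log(config$prior_bounds[1]); ub <- log(config$prior_bounds[2])
  theta <- runif(3, log(config$start_bounds[1]), log(config$start_bounds[2]))
  names(theta) <- c("mu", "nu", "s")
  lam <- config$proposal_scales[c("mu", "nu", "s")]
  loglik <- function(th) {
    pr <- model_params(mu = exp(th[1]), nu = exp(th[2]), s = exp(th[3]),
                       Ne = Ne, orientation = orientation)
    sfs_log_likelihood(sfs, pr)
  }
  ll <- loglik(theta)
  G <- config$n_generations
  burn <- floor(G * config$burn_in_fraction)
  n_keep <- floor((G - burn) / config$thinning)
  samp <- matrix(NA_real_, n_keep, 5,
                 dimnames = list(NULL, c("mu", "nu", "s", "gamma", "loglik")))
  acc <- prop <- c(mu = 0, nu = 0, s = 0)   # post-burn-in tallies
  tune_n <- c(0, 0, 0)
  consec_rej <- 0L
  si <- 0L
  for (g in seq_len(G)) {
    j <- (g - 1L) %% 3L + 1L
    cand <- theta
    cand[j] <- cand[j] + rnorm(1, 0, lam[j])
    accept <- FALSE
    if (cand[j] >= lb && cand[j] <= ub) {
      llc <- loglik(cand)
      if (is.finite(llc) && log(runif(1)) < llc - ll) {
        theta <- cand; ll <- llc; accept <- TRUE
      }
    }
    if (g <= burn && config$adapt) {
      tune_n[j] <- tune_n[j] + 1
      lam[j] <- lam[j] * exp(tune_n[j]^-0.6 * ((accept) - 0.4))
    } else {
      prop[j] <- prop[j] + 1
      acc[j] <- acc[j] + accept
    }
    consec_rej <- if (accept) 0L else consec_rej + 1L
    if (consec_rej >= 1000L)
      stop("1000 consecutive rejections: proposal scales misconfigured ",
           "(current scales: ", paste(sprintf("%.3g", lam), collapse = ", "),
           ")")
    if (g > burn && (g - burn) %% config$thinning == 0L) {
      si <- si + 1L
      samp[si, ] <- c(exp(theta), 4 * Ne * exp(theta[3]), ll)
    }
  }
  list(samples = data.table::as.data.table(samp[seq_len(si), , drop = FALSE]),
       acceptance = acc / pmax(prop, 1), scales = lam)
}

#' Fit the stationary selection model to an SFS by MCMC
#'
#' Runs `config$n_chains` independent random-walk Metropolis chains over
#' `log(mu)`, `log(nu)`, `log(s)` targeting the likelihood of
#' [sfs_log_likelihood()] with log-uniform priors. `Ne` is fixed; the scaled
#' selection coefficient `gamma = 4*Ne*s` is tracked as a derived chain
#' statistic. Posterior means and 95% credible intervals (2.5/97.5
#' percentiles) are computed on the pooled thinned post-burn-in samples.
#'
#' @param sfs A `projected_sfs`.
#' @param Ne Fixed effective population size.
#' @param orientation Which state the selection coefficient favors.
#' @param config An [mcmc_config()].
#' @return An object of class `posterior_summary`: a list with `summary`
#'   (data.table of mean/lower/upper per parameter), `acceptance` (per chain
#'   x parameter), `acceptance_ok`, `verdict`, `chains` (thinned samples
#'   with a `chain` column), `per_chain_mean_gamma`, `orientation`, `Ne`,
#'   and `seed`.
#' @export
run_mcmc <- function(sfs, Ne, orientation = "UM_advantage",
                     config = mcmc_config()) {
  stopifnot(inherits(sfs, "projected_sfs"), sum(sfs$d) > 0)
  seed <- if (is.null(config$seed)) sample.int(2^30, 1) else config$seed
  chains <- vector("list", config$n_chains)
  accmat <- matrix(NA_real_, config$n_chains, 3,
                   dimnames = list(NULL, c("mu", "nu", "s")))
  for (cc in seq_len(config$n_chains)) {
    res <- run_one_chain(sfs, Ne, orientation, config, seed + cc - 1L)
    res$samples[, chain := cc]
    chains[[cc]] <- res$samples
    accmat[cc, ] <- res$acceptance
  }
  pooled <- data.table::rbindlist(chains)
  qs <- function(v) c(mean = mean(v), lower = unname(quantile(v, 0.025)),
                      upper = unname(quantile(v, 0.975)))
  summ <- data.table::rbindlist(lapply(c("mu", "nu", "s", "gamma"),
    function(p) c(list(parameter = p), as.list(qs(pooled[[p]])))))
  g <- summ[parameter == "gamma"]
  verdict <- significance_verdict(g$mean, g$lower, g$upper)
  ta <- config$target_acceptance
  structure(list(summary = summ,
                 acceptance = accmat,
                 acceptance_ok = all(accmat > ta[1] & accmat < ta[2]),
                 verdict = verdict,
                 chains = pooled,
                 per_chain_mean_gamma = vapply(chains, function(x)
                   mean(x$gamma), 0),
                 orientation = orientation, Ne = Ne, seed = seed),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$orientation, ", Ne = ", format(x$Ne),
      ", ", nrow(x$chains), " pooled samples)\n", sep = "")
  print(x$summary)
  cat("verdict:", x$verdict, "\n")
  if (!x$acceptance_ok)
    cat("NOTE: some acceptance rates fall outside the target interval\n")
  invisible(x)
}

#' Fit both selection orientations and keep the stronger one
#'
#' Fits the model once with the UM state favored and once with the gbM
#' state favored, and reports the orientation with the higher posterior-mean
#' `4*Ne*s`.
#'
#' @param sfs A `projected_sfs`.
#' @param Ne Fixed effective population size.
#' @param config An [mcmc_config()].
#' @return The selected `posterior_summary`, with both fits attached as
#'   `$fits`.
#' @export
fit_both_orientations <- function(sfs, Ne, config = mcmc_config()) {
  fits <- list(
    UM_advantage  = run_mcmc(sfs, Ne, "UM_advantage", config),
    gbM_advantage = run_mcmc(sfs, Ne, "gbM_advantage", config))
  gm <- vapply(fits, function(f)
    f$summary[parameter == "gamma", mean], 0)
  best <- fits[[names(which.max(gm))]]
  best$fits <- fits
  best
}

#' Significance rule for the scaled selection coefficient
#'
#' Compares the posterior of `4*Ne*s` to 1: values below 1 are effectively
#' neutral. Selection on the methylation state is called when both the
#' posterior mean and the lower 95% credible bound exceed 1; no selection
#' when mean and upper bound sit below 1; otherwise the result is
#' nonsignificant (the interval straddles 1).
#'
#' @param mean Posterior mean of `4*Ne*s`.
#' @param lower,upper 95% credible bounds.
#' @return `"selection_on_state"`, `"no_selection"` or `"nonsignificant"`.
#' @export
significance_verdict <- function(mean, lower, upper) {
  stopifnot(lower <= upper)
  if (mean > 1 && lower > 1) "selection_on_state"
  else if (mean < 1 && upper < 1) "no_selection"
  else "nonsignificant"
}

#' Pearson chi-squared goodness of fit of an SFS to model expectations
#'
#' Frequency classes are cumulated along the k axis until each pooled cell
#' reaches an expected count of `min_expected` (a short final cell is folded
#' into its neighbour), then the Pearson statistic is computed on the pooled
#' cells with `df = cells - 1`.
#'
#' @param observed A `projected_sfs` (or numeric vector of class counts).
#' @param expected Expected counts on the same classes, e.g. from
#'   [expected_sfs()]; rescaled to the observed total.
#' @param min_expected Pooling threshold (default 5).
#' @return List with `statistic`, `df`, `p_value`, `n_cells`.
#' @export
gof_chisq <- function(observed, expected, min_expected = 5) {
  obs <- if (inherits(observed, "projected_sfs")) observed$d else observed
  stopifnot(length(obs) == length(expected))
  expected <- expected * sum(obs) / sum(expected)
  grp <- integer(length(obs))
  gid <- 1L
  csum <- 0
  for (i in seq_along(obs)) {
    grp[i] <- gid; csum <- csum + expected[i]
    if (csum >= min_expected) { gid <- gid + 1L; csum <- 0 }
  }
  if (csum > 0 && csum < min_expected && gid > 1L)
    grp[grp == gid] <- gid - 1L     # fold a short final cell into the tail
  O <- tapply(obs, grp, sum); E <- tapply(expected, grp, sum)
  if (length(O) < 2L) {
    warning("fewer than 2 cells after pooling; GOF undefined")
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_cells = length(O)))
  }
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), n_cells = length(O))
}
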