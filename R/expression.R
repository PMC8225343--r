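# long-format join of expression and state matrices; optionally drops genes
# fixed for a single state (those carry no within-gene contrast)
expression_long <- function(expr, states, drop_fixed = TRUE) {
  stopifnot(is.matrix(expr))
  genes <- intersect(rownames(expr), rownames(states))
  accs <- intersect(colnames(expr), colnames(states))
  if (!length(genes) || !length(accs))
    stop("expression and state matrices share no genes/accessions")
  e <- expr[genes, accs, drop = FALSE]
  s <- states[genes, accs, drop = FALSE]
  d <- data.table::data.table(
    gene_id = rep(genes, times = length(accs)),
    accession = rep(accs, each = length(genes)),
    state = as.vector(s), count = as.vector(e))
  d <- d[state %in% c("gbM", "UM", "mCHG", "mCHH") & !is.na(count)]
  if (drop_fixed) {
    poly <- d[, data.table::uniqueN(state), by = gene_id][V1 >= 2L, gene_id]
    d <- d[gene_id %in% poly]
  }
  d[, state := factor(state, c("gbM", "UM", "mCHG", "mCHH"))]
  d[, state := droplevels(state)]
  d[, y := log(count + 1)]
  d[]
}

# adjacent-pair contrasts along the expression hierarchy, bonferroni-adjusted
hierarchy_contrasts <- function(fit, levels_present) {
  emm <- emmeans::emmeans(fit, "state", lmer.df = "asymptotic")
  ord <- c("gbM", "UM", "mCHG", "mCHH")
  present <- ord[ord %in% levels_present]
  cons <- list()
  for (i in seq_len(length(present) - 1L)) {
    a <- present[i]; b <- present[i + 1L]
    v <- as.numeric(levels_present == a) - as.numeric(levels_present == b)
    cons[[paste(a, "-", b)]] <- v
  }
  ct <- emmeans::contrast(emm, method = cons, adjust = "bonferroni")
  as.data.frame(ct)
}

#' Mixed-model contrasts of expression between gene methylation states
#'
#' Fits `log(count + 1) ~ state + (1 | gene)` by maximum likelihood on all
#' gene x accession cells with a determined state, after removing genes
#' fixed for a single state. The overall state effect is tested by a
#' likelihood-ratio comparison against the intercept-only mixed model, and
#' adjacent pairs along the expected hierarchy gbM > UM > mCHG > mCHH are
#' contrasted on the estimated marginal means with Bonferroni adjustment
#' (asymptotic z tests).
#'
#' @param expr Genes x accessions matrix of raw read counts.
#' @param states Matching state matrix.
#' @return List with `chisq`, `df`, `p_state` (the LRT of the state effect),
#'   `contrasts` (`data.table`: contrast, estimate, SE, z_ratio, p_adj),
#'   `n_genes`, `n_obs`.
#' @export
state_expression_contrasts <- function(expr, states) {
  d <- expression_long(expr, states)
  if (nlevels(d$state) < 2L)
    stop("fewer than two methylation states present; no contrast possible")
  fit <- lme4::lmer(y ~ state + (1 | gene_id), data = d, REML = FALSE)
  fit0 <- lme4::lmer(y ~ 1 + (1 | gene_id), data = d, REML = FALSE)
  lrt <- 2 * (logLik(fit) - logLik(fit0))
  df <- nlevels(d$state) - 1L
  ctr <- hierarchy_contrasts(fit, levels(d$state))
  list(chisq = as.numeric(lrt), df = df,
       p_state = pchisq(as.numeric(lrt), df, lower.tail = FALSE),
       contrasts = data.table::data.table(
         contrast = ctr$contrast, estimate = ctr$estimate, SE = ctr$SE,
         z_ratio = ctr$z.ratio, p_adj = ctr$p.value),
       n_genes = data.table::uniqueN(d$gene_id), n_obs = nrow(d))
}

#' Permutation calibration of the state-expression test
#'
#' Globally permutes the methylation-state labels across all gene x
#' accession cells (without replacement), refits the state model and records
#' the likelihood-ratio p-value, `n_perm` times. Permutation destroys any
#' state-expression link while preserving the label multiset and the
#' per-gene expression structure, so the fraction of permutations
#' significant at `alpha` measures the calibration of the test.
#'
#' @param expr,states As in [state_expression_contrasts()].
#' @param n_perm Number of permutations (default 1001).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional seed for the permutation stream.
#' @return List with `fraction_significant`, `n_significant`, `p_values`,
#'   `min_p`, `n_perm`.
#' @export
permutation_calibration <- function(expr, states, n_perm = 1001L,
                                    alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm == 0L)
    return(list(fraction_significant = numeric(0), n_significant = 0L,
                p_values = numeric(0), min_p = NA_real_, n_perm = 0L))
  d <- expression_long(expr, states)
  fit0 <- lme4::lmer(y ~ 1 + (1 | gene_id), data = d, REML = FALSE)
  ll0 <- as.numeric(logLik(fit0))
  df <- nlevels(d$state) - 1L
  pvals <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    d[, state := sample(state)]
    fb <- lme4::lmer(y ~ state + (1 | gene_id), data = d, REML = FALSE)
    lrt <- 2 * (as.numeric(logLik(fb)) - ll0)
    pvals[b] <- pchisq(lrt, df, lower.tail = FALSE)
  }
  list(fraction_significant = mean(pvals < alpha),
       n_significant = sum(pvals < alpha),
       p_values = pvals, min_p = min(pvals), n_perm = n_perm)
}

#' Within-gene comparison of median expression of gbM vs UM epialleles
#'
#' For every gene with at least one UM and one gbM accession, compares the
#' median expression of the two epiallele groups and counts genes where the
#' gbM median is strictly higher. Genes with exactly tied medians are
#' excluded from the sign test (standard sign-test convention); the
#' remaining count is tested against 0.5 with a two-sided exact binomial
#' test. The comparison depends on expression only through within-gene
#' ranks, so it is invariant to monotone transforms.
#'
#' @param expr,states As in [state_expression_contrasts()].
#' @return List with `n_gbM_higher`, `n_genes` (eligible genes), `n_ties`,
#'   `proportion` (among non-tied genes), `p_value`.
#' @export
paired_median_comparison <- function(expr, states) {
  d <- expression_long(expr, states, drop_fixed = FALSE)
  d <- d[state %in% c("gbM", "UM")]
  meds <- d[, .(m_gbM = as.numeric(median(count[state == "gbM"])),
                m_UM = as.numeric(median(count[state == "UM"])),
                n_gbM = sum(state == "gbM"), n_UM = sum(state == "UM")),
            by = gene_id]
  meds <- meds[n_gbM >= 1L & n_UM >= 1L]
  if (nrow(meds) == 0L) stop("no gene has both a UM and a gbM accession")
  higher <- sum(meds$m_gbM > meds$m_UM)
  ties <- sum(meds$m_gbM == meds$m_UM)
  n_test <- nrow(meds) - ties
  p <- if (n_test > 0) binom.test(higher, n_test, 0.5)$p.value else NA_real_
  list(n_gbM_higher = higher, n_genes = nrow(meds), n_ties = ties,
       proportion = if (n_test > 0) higher / n_test else NA_real_,
       p_value = p)
}

#' Expression-variability comparison between gbM and UM epialleles
#'
#' Tests the homeostasis hypothesis that gbM stabilizes expression. For
#' genes with at least two accessions of each epiallele, the larger group is
#' randomly downsampled to the size of the smaller, the coefficient of
#' variation of raw counts is computed per group, and a one-sided paired
#' Wilcoxon signed-rank test asks whether CV(gbM) < CV(UM). Genes with zero
#' mean expression in either matched group are skipped and tallied.
#'
#' @param expr,states As in [state_expression_contrasts()].
#' @param seed Optional seed for the downsampling.
#' @return List with `p_value`, `n_UM_more_variable`, `n_genes`,
#'   `n_skipped`, `all_tied`.
#' @export
cv_comparison <- function(expr, states, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- expression_long(expr, states, drop_fixed = FALSE)
  d <- d[state %in% c("gbM", "UM")]
  cnt <- d[, .(n_gbM = sum(state == "gbM"), n_UM = sum(state == "UM")),
           by = gene_id]
  eligible <- cnt[n_gbM >= 2L & n_UM >= 2L, gene_id]
  cv_g <- cv_u <- numeric(0)
  skipped <- 0L
  for (g in eligible) {
    x_g <- d[gene_id == g & state == "gbM", count]
    x_u <- d[gene_id == g & state == "UM", count]
    m <- min(length(x_g), length(x_u))
    if (length(x_g) > m) x_g <- sample(x_g, m)
    if (length(x_u) > m) x_u <- sample(x_u, m)
    if (mean(x_g) == 0 || mean(x_u) == 0) { skipped <- skipped + 1L; next }
    cv_g <- c(cv_g, sd(x_g) / mean(x_g))
    cv_u <- c(cv_u, sd(x_u) / mean(x_u))
  }
  if (!length(cv_g)) stop("no gene eligible for the CV comparison")
  all_tied <- all(cv_g == cv_u)
  p <- if (all_tied) 1 else
    suppressWarnings(wilcox.test(cv_g, cv_u, paired = TRUE,
                                 alternative = "less")$p.value)
  list(p_value = p, n_UM_more_variable = sum(cv_u > cv_g),
       n_genes = length(cv_g), n_skipped = skipped, all_tied = all_tied)
}

#' Joint models of CG dinucleotide count, methylation state and expression
#'
#' Two mixed models disentangle sequence (number of CG dinucleotides, #CG)
#' from epiallelic state: `#CG ~ state + (1 | gene)` estimates how #CG
#' differs between states (gbM - UM contrast reported), and
#' `log(count + 1) ~ #CG + state + (1 | gene)` asks whether state predicts
#' expression once #CG is accounted for, reporting the #CG slope and the
#' state contrasts. A constant #CG drops the covariate with a warning.
#'
#' @param expr,states As in [state_expression_contrasts()].
#' @param cg_counts Genes x accessions matrix of #CG values.
#' @return List with elements `cg_model` (LRT and gbM-UM contrast on #CG)
#'   and `expression_model` (`cg_slope`, `cg_slope_se`, state contrasts).
#' @export
cg_count_models <- function(expr, states, cg_counts) {
  d <- expression_long(expr, states)
  idx <- cbind(match(d$gene_id, rownames(cg_counts)),
               match(d$accession, colnames(cg_counts)))
  d[, cg := as.numeric(cg_counts[idx])]
  d <- d[!is.na(cg)]
  # state effect on #CG
  f5 <- lme4::lmer(cg ~ state + (1 | gene_id), data = d, REML = FALSE)
  f5n <- lme4::lmer(cg ~ 1 + (1 | gene_id), data = d, REML = FALSE)
  lrt5 <- 2 * (as.numeric(logLik(f5)) - as.numeric(logLik(f5n)))
  df5 <- nlevels(d$state) - 1L
  emm5 <- emmeans::emmeans(f5, "state", lmer.df = "asymptotic")
  lv <- levels(d$state)
  v <- as.numeric(lv == "gbM") - as.numeric(lv == "UM")
  c5 <- as.data.frame(emmeans::contrast(emm5, method = list(`gbM - UM` = v)))
  # expression on #CG + state
  if (sd(d$cg) == 0) {
    warning("#CG is constant; dropping it from the expression model")
    f6 <- lme4::lmer(y ~ state + (1 | gene_id), data = d, REML = FALSE)
    slope <- c(NA_real_, NA_real_)
  } else {
    f6 <- lme4::lmer(y ~ cg + state + (1 | gene_id), data = d, REML = FALSE)
    sm <- summary(f6)$coefficients
    slope <- sm["cg", c("Estimate", "Std. Error")]
  }
  c6 <- hierarchy_contrasts(f6, lv)
  list(cg_model = list(chisq = lrt5, df = df5,
                       p_state = pchisq(lrt5, df5, lower.tail = FALSE),
                       gbM_minus_UM = c5$estimate, SE = c5$SE,
                       p_value = c5$p.value),
       expression_model = list(cg_slope = unname(slope[1]),
                               cg_slope_se = unname(slope[2]),
                               contrasts = data.table::as.data.table(c6)))
}
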