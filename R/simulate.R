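#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study conditions the analysis assumes: epiallele
#' frequencies drawn from the mutation-selection-drift stationary
#' distribution with the all-genes epimutation rates (`mu = 6.2e-8` UM->gbM,
#' `nu = 2.09e-7` gbM->UM, `Ne = 341000`, giving `alpha = 0.085`,
#' `beta = 0.285`), class-specific selection (`s = 1.2e-6` favoring gbM in
#' ancestrally gbM genes, `s = 1.39e-6` favoring UM in ancestrally UM
#' genes), bisulfite read counts with a 0.0041 no-conversion rate, sparse
#' mCHG/mCHH contamination, and expression counts whose state shifts
#' reproduce the hierarchy gbM > UM > mCHG > mCHH with a gbM-UM difference
#' of 0.0563 log units.
#'
#' @param n_accessions,n_genes Sample dimensions.
#' @param frac_ancestral_gbM Fraction of genes that are ancestrally gbM
#'   (default 0.3, matching the observed ~3:7 split of polarized genes).
#' @param mu,nu,Ne Shared epimutation rates and effective size.
#' @param s_gbM_class,s_UM_class Selection coefficients of the favored state
#'   within each ancestral class.
#' @param mCHG_rate,mCHH_rate Per-cell contamination probabilities
#'   (defaults 0.02, 0.01).
#' @param missing_rate Per-cell probability of a missing state (no data).
#' @param cg_sites_range,chg_sites_range,chh_sites_range Per-gene site-count
#'   ranges (uniform integer draws).
#' @param p_meth_gbM,p_meth_UM Within-gene CG-site methylation probability
#'   for gbM (0.85) and UM (0.05, the CG background) epialleles.
#' @param p_chg_bg,p_chh_bg Background CHG/CHH site methylation
#'   probabilities.
#' @param p_meth_contaminated Site methylation probability in the defining
#'   context of mCHG/mCHH cells.
#' @param coverage_mean Poisson mean read coverage per site (floor 0, so
#'   low-coverage sites exercising the <=2-read rule do occur).
#' @param nonconversion_rate Read-level error for truly unmethylated sites.
#' @param meth_read_rate Read-level methylated fraction for truly methylated
#'   sites.
#' @param expr_log_mean,expr_gene_sd Baseline log-expression and per-gene
#'   random-intercept SD.
#' @param expr_state_shifts Named log-scale shifts per state; defaults give
#'   gbM-UM = 0.0563, UM-mCHG = 0.1093, mCHG-mCHH = 0.2275.
#' @param expr_noise `"nbinom"` (default; deliberately mismatched with the
#'   Gaussian fit model to test robustness) or `"gaussian_log"` for exact
#'   recovery tests.
#' @param nb_size Negative-binomial dispersion (size) parameter.
#' @param gaussian_sd Residual SD for the `gaussian_log` noise model.
#' @param expr_gbM_sd_factor Multiplier on the residual scale of gbM cells
#'   (default 1; values < 1 make gbM expression less variable, emulating a
#'   homeostatic effect of gene body methylation).
#' @param expr_cg_slope Log-expression slope per CG dinucleotide when a #CG
#'   matrix is supplied to [simulate_expression()].
#' @param cg_base_mean,cg_gbM_shift,cg_sd #CG dinucleotide generator: gene
#'   baseline mean, gbM-UM shift (default 1.338) and cell-level SD.
#' @param outgroup_discordance Probability that a single outgroup replicate
#'   call flips state.
#' @param seed Master seed; each generator derives sub-seeds from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_accessions = 200L, n_genes = 2000L,
                              frac_ancestral_gbM = 0.3,
                              mu = 6.2e-8, nu = 2.09e-7, Ne = 341000,
                              s_gbM_class = 1.2e-6, s_UM_class = 1.39e-6,
                              mCHG_rate = 0.02, mCHH_rate = 0.01,
                              missing_rate = 0.05,
                              cg_sites_range = c(20L, 80L),
                              chg_sites_range = c(20L, 80L),
                              chh_sites_range = c(20L, 80L),
                              p_meth_gbM = 0.85, p_meth_UM = 0.05,
                              p_chg_bg = 0.03, p_chh_bg = 0.02,
                              p_meth_contaminated = 0.7,
                              coverage_mean = 20,
                              nonconversion_rate = 0.0041,
                              meth_read_rate = 0.95,
                              expr_log_mean = 4, expr_gene_sd = 1,
                              expr_state_shifts = c(mCHH = 0, mCHG = 0.2275,
                                                    UM = 0.3368,
                                                    gbM = 0.3931),
                              expr_noise = c("nbinom", "gaussian_log"),
                              nb_size = 10, gaussian_sd = 0.3,
                              expr_gbM_sd_factor = 1,
                              expr_cg_slope = -5.77e-3,
                              cg_base_mean = 100, cg_gbM_shift = 1.338,
                              cg_sd = 2,
                              outgroup_discordance = 0.02,
                              seed = 1L) {
  expr_noise <- match.arg(expr_noise)
  cfg <- as.list(environment())
  probs <- c(frac_ancestral_gbM, mCHG_rate, mCHH_rate, missing_rate,
             p_meth_gbM, p_meth_UM, p_chg_bg, p_chh_bg, p_meth_contaminated,
             nonconversion_rate, meth_read_rate, outgroup_discordance)
  stopifnot(all(probs >= 0 & probs <= 1), mu > 0, nu > 0, Ne > 0,
            coverage_mean > 0)
  structure(cfg, class = "simulation_config")
}

# class-level stationary parameters on the UM-count axis
class_params <- function(config, class) {
  if (class == "gbM")
    model_params(config$mu, config$nu, config$s_gbM_class, config$Ne,
                 "gbM_advantage")
  else
    model_params(config$mu, config$nu, config$s_UM_class, config$Ne,
                 "UM_advantage")
}

#' Simulate a gene x accession state matrix from the stationary model
#'
#' Each gene belongs to an ancestral class (gbM or UM) with its own
#' selection regime; its UM-epiallele count across accessions is drawn from
#' the stationary sampling distribution (the frequency-spectrum model used
#' for inference), the UM accessions are assigned at random, and mCHG/mCHH
#' contamination and missing cells are overlaid at the configured rates.
#' Outgroup calls (two species, two replicates each) are generated from the
#' ancestral truth with a small per-replicate discordance rate.
#'
#' @param config A [simulation_config()].
#' @return List with `states` (character matrix), `ancestral` (truth,
#'   `data.table` of `gene_id`, `state`), `outgroup_calls`, and
#'   `params` (per-class [model_params()]).
#' @export
simulate_state_matrix <- function(config = simulation_config()) {
  set.seed(config$seed)
  nA <- config$n_accessions; nG <- config$n_genes
  genes <- sprintf("g%05d", seq_len(nG))
  accs <- sprintf("acc%04d", seq_len(nA))
  n_gbm <- round(config$frac_ancestral_gbM * nG)
  anc <- c(rep("gbM", n_gbm), rep("UM", nG - n_gbm))
  params <- list(gbM = class_params(config, "gbM"),
                 UM = class_params(config, "UM"))
  mat <- matrix(NA_character_, nG, nA, dimnames = list(genes, accs))
  for (cls in c("gbM", "UM")) {
    idx <- which(anc == cls)
    if (!length(idx)) next
    pr <- params[[cls]]
    p <- exp(stationary_log_pmf(nA, pr$alpha, pr$beta, signed_gamma(pr)))
    kk <- sample.int(nA + 1L, length(idx), replace = TRUE, prob = p) - 1L
    for (i in seq_along(idx)) {
      st <- rep("gbM", nA)
      if (kk[i] > 0) st[sample.int(nA, kk[i])] <- "UM"
      mat[idx[i], ] <- st
    }
  }
  # overlay contamination and missingness
  u <- matrix(runif(nG * nA), nG, nA)
  mat[u < config$mCHG_rate] <- "mCHG"
  mat[u >= config$mCHG_rate &
        u < config$mCHG_rate + config$mCHH_rate] <- "mCHH"
  um <- matrix(runif(nG * nA), nG, nA)
  mat[um < config$missing_rate] <- NA_character_
  # outgroup calls from the ancestral truth
  og <- data.table::CJ(gene_id = genes, species = c("outgroup1", "outgroup2"),
                       replicate = 1:2)
  og <- og[data.table::data.table(gene_id = genes, truth = anc),
           on = "gene_id"]
  flip <- runif(nrow(og)) < config$outgroup_discordance
  og[, state := ifelse(flip, ifelse(truth == "gbM", "UM", "gbM"), truth)]
  og[, truth := NULL]
  list(states = mat,
       ancestral = data.table::data.table(gene_id = genes, state = anc),
       outgroup_calls = og[], params = params)
}

# deterministic gene/site layout shared by all accessions
simulate_gene_structures <- function(config) {
  set.seed(config$seed + 1L)
  nG <- config$n_genes
  genes <- sprintf("g%05d", seq_len(nG))
  rint <- function(rng, n) {
    if (rng[1] == rng[2]) rep(rng[1], n)
    else sample(seq(rng[1], rng[2]), n, replace = TRUE)
  }
  n_cg <- rint(config$cg_sites_range, nG)
  n_chg <- rint(config$chg_sites_range, nG)
  n_chh <- rint(config$chh_sites_range, nG)
  tot <- n_cg + n_chg + n_chh
  glen <- tot * 4L + 100L
  gstart <- cumsum(c(1L, head(glen + 200L, -1L)))
  site_list <- vector("list", nG)
  for (i in seq_len(nG)) {
    offs <- sort(sample.int(glen[i], tot[i]))
    ctx <- sample(rep(c("CG", "CHG", "CHH"), c(n_cg[i], n_chg[i], n_chh[i])))
    site_list[[i]] <- data.table::data.table(
      gene_id = genes[i], chrom = "Chr1", pos = gstart[i] + offs - 1L,
      strand = "+", context = ctx)
  }
  sites <- data.table::rbindlist(site_list)
  annotation <- data.table::data.table(
    gene_id = genes, chrom = "Chr1", start = gstart,
    end = gstart + glen - 1L, strand = "+")
  list(sites = sites, annotation = annotation)
}

# per-site truth methylation probability given the cell state
site_meth_prob <- function(state, context, config) {
  p <- numeric(length(state))
  cg <- context == "CG"; chg <- context == "CHG"; chh <- context == "CHH"
  p[cg] <- config$p_meth_UM
  p[chg] <- config$p_chg_bg
  p[chh] <- config$p_chh_bg
  p[cg & state == "gbM"] <- config$p_meth_gbM
  p[cg & state %in% c("mCHG", "mCHH")] <- config$p_meth_contaminated
  p[chg & state %in% c("mCHG", "mCHH")] <- config$p_meth_contaminated
  p[chh & state == "mCHH"] <- config$p_meth_contaminated
  p
}

#' Simulate per-accession bisulfite count tables
#'
#' Emits allc-style cytosine records for each requested accession, using a
#' gene/site layout that is deterministic given the configuration seed (so
#' accessions can be generated independently, in any order or chunking, with
#' identical results). Within a cell, each site is truly methylated with the
#' state- and context-dependent probability; truly methylated sites yield
#' `Binomial(coverage, meth_read_rate)` methylated reads and truly
#' unmethylated sites `Binomial(coverage, nonconversion_rate)` (no-conversion
#' noise). Coverage is Poisson so sites with <= 2 reads occur and exercise
#' the low-coverage calling rule. Cells with a missing state emit no reads
#' for that gene.
#'
#' @param states State matrix from [simulate_state_matrix()].
#' @param config The same [simulation_config()].
#' @param accessions Accessions to emit (default: all columns).
#' @param structures Optional precomputed layout (internal reuse).
#' @param dir If given, write one `<accession>.tsv` per accession plus
#'   `annotation.gff3` into `dir` and return file paths instead of tables.
#' @return List with `allc` (named list of `data.table`s, or paths),
#'   `annotation` (CDS intervals) and `sites` (the site layout).
#' @export
simulate_methylomes <- function(states, config, accessions = colnames(states),
                                structures = NULL, dir = NULL) {
  if (is.null(structures)) structures <- simulate_gene_structures(config)
  stopifnot(nrow(states) == config$n_genes)
  sites <- structures$sites
  out <- vector("list", length(accessions))
  names(out) <- accessions
  all_acc <- colnames(states)
  for (acc in accessions) {
    set.seed(config$seed + 1000L + match(acc, all_acc))
    st <- states[sites$gene_id, match(acc, all_acc)]
    tab <- sites[!is.na(st)]
    stv <- st[!is.na(st)]
    p <- site_meth_prob(stv, tab$context, config)
    truly <- runif(nrow(tab)) < p
    cov <- rpois(nrow(tab), config$coverage_mean)
    mc <- integer(nrow(tab))
    mc[truly] <- rbinom(sum(truly), cov[truly], config$meth_read_rate)
    mc[!truly] <- rbinom(sum(!truly), cov[!truly], config$nonconversion_rate)
    tab <- tab[, .(chrom, pos, strand, context)]
    tab[, `:=`(mc = mc, cov = cov)]
    out[[acc]] <- tab
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(length(accessions))
    names(paths) <- accessions
    for (acc in accessions) {
      paths[acc] <- file.path(dir, paste0(acc, ".tsv"))
      data.table::fwrite(out[[acc]], paths[acc], sep = "\t",
                         col.names = FALSE)
    }
    gff <- file.path(dir, "annotation.gff3")
    write_gff3(structures$annotation, gff)
    return(list(allc = paths, annotation = structures$annotation,
                sites = sites, gff = gff))
  }
  list(allc = out, annotation = structures$annotation, sites = sites)
}

# minimal single-CDS-per-gene GFF3 writer (gene -> mRNA -> CDS)
write_gff3 <- function(annotation, path) {
  a <- data.table::as.data.table(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(a))) {
    g <- a[i]
    writeLines(c(
      sprintf("%s\tepisfs\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tepisfs\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tepisfs\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id)), con)
  }
  invisible(path)
}

#' Simulate an accession x gene expression count table
#'
#' Counts follow a gene random intercept plus a state-dependent shift on the
#' log scale; by default noise is negative binomial on the count scale
#' (intentionally heavier-tailed than the Gaussian-on-log fit model), with a
#' `gaussian_log` option for exact-recovery tests. When a `cg` matrix is
#' supplied, `expr_cg_slope * (cg - mean(cg))` is added to the log mean so
#' sequence and epiallele effects can be disentangled by the joint model.
#'
#' @param states State matrix from [simulate_state_matrix()].
#' @param config A [simulation_config()].
#' @param cg Optional #CG matrix from [simulate_cg_counts()].
#' @return Integer matrix of raw read counts, genes x accessions.
#' @export
simulate_expression <- function(states, config, cg = NULL) {
  set.seed(config$seed + 2L)
  nG <- nrow(states); nA <- ncol(states)
  base <- rnorm(nG, config$expr_log_mean, config$expr_gene_sd)
  shift <- matrix(0, nG, nA)
  for (s in names(config$expr_state_shifts))
    shift[states == s] <- config$expr_state_shifts[[s]]
  lmu <- base + shift
  if (!is.null(cg)) lmu <- lmu + config$expr_cg_slope * (cg - mean(cg))
  sdfac <- matrix(1, nG, nA)
  sdfac[states == "gbM"] <- config$expr_gbM_sd_factor
  counts <- if (config$expr_noise == "nbinom") {
    # size scales inversely with the squared extra-Poisson CV factor
    matrix(rnbinom(nG * nA, mu = exp(lmu),
                   size = config$nb_size / as.vector(sdfac)^2), nG, nA)
  } else {
    y <- lmu + rnorm(nG * nA, 0, config$gaussian_sd * as.vector(sdfac))
    matrix(pmax(0L, as.integer(round(expm1(y)))), nG, nA)
  }
  dimnames(counts) <- dimnames(states)
  counts
}

#' Simulate per-cell CG dinucleotide counts
#'
#' Gene-level baseline (Poisson around `cg_base_mean`) plus a `cg_gbM_shift`
#' excess for gbM cells and Gaussian cell-level noise, rounded to
#' non-negative integers.
#'
#' @param states State matrix.
#' @param config A [simulation_config()].
#' @return Integer matrix, genes x accessions.
#' @export
simulate_cg_counts <- function(states, config) {
  set.seed(config$seed + 3L)
  nG <- nrow(states); nA <- ncol(states)
  base <- rpois(nG, config$cg_base_mean)
  shift <- matrix(0, nG, nA)
  shift[states == "gbM"] <- config$cg_gbM_shift
  cg <- base + shift + matrix(rnorm(nG * nA, 0, config$cg_sd), nG, nA)
  cg <- matrix(pmax(0L, as.integer(round(cg))), nG, nA)
  dimnames(cg) <- dimnames(states)
  cg
}
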