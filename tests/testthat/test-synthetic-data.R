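test_that("neutral state matrices follow the beta-binomial spectrum", {
  cfg <- simulation_config(n_accessions = 50, n_genes = 20000,
                           s_gbM_class = 0, s_UM_class = 0,
                           mCHG_rate = 0, mCHH_rate = 0, missing_rate = 0,
                           seed = 101)
  tr <- simulate_state_matrix(cfg)
  k <- rowSums(tr$states == "UM")
  d <- tabulate(k + 1L, nbins = 51L)
  pr <- model_params(cfg$mu, cfg$nu, 0, cfg$Ne)
  e <- exp(oracle_beta_binom(0:50, 50, pr$alpha, pr$beta)) * cfg$n_genes
  g <- gof_chisq(d, e)
  expect_gt(g$p_value, 0.01)
})

test_that("a symmetric neutral regime gives a symmetric spectrum", {
  cfg <- simulation_config(n_accessions = 40, n_genes = 8000,
                           mu = 1e-7, nu = 1e-7,
                           s_gbM_class = 0, s_UM_class = 0,
                           mCHG_rate = 0, mCHH_rate = 0, missing_rate = 0,
                           seed = 55)
  tr <- simulate_state_matrix(cfg)
  k <- rowSums(tr$states == "UM")
  # mean UM fraction should sit at 1/2 within sampling error
  se <- sd(k / 40) / sqrt(length(k))
  expect_lt(abs(mean(k / 40) - 0.5), 4 * se)
  # no contamination states were requested, none emitted
  expect_true(all(tr$states %in% c("UM", "gbM")))
})

test_that("contamination and missingness are overlaid at the set rates", {
  cfg <- simulation_config(n_accessions = 60, n_genes = 2000, seed = 77)
  tr <- simulate_state_matrix(cfg)
  n_cells <- length(tr$states)
  expect_lt(abs(mean(tr$states == "mCHG", na.rm = TRUE) /
                  mean(!is.na(tr$states)) - 0.02), 0.005)
  expect_lt(abs(mean(is.na(tr$states)) - 0.05), 0.01)
  # ancestral truth covers every gene and matches the class split
  expect_equal(nrow(tr$ancestral), 2000L)
  expect_equal(sum(tr$ancestral$state == "gbM"), 600L)
  # outgroup calls: two species, two replicates per gene
  expect_equal(nrow(tr$outgroup_calls), 2000L * 4L)
})

test_that("methylome generation is seed-stable and chunk-invariant", {
  cfg <- simulation_config(n_accessions = 6, n_genes = 40, seed = 12)
  tr <- simulate_state_matrix(cfg)
  m1 <- simulate_methylomes(tr$states, cfg)
  m2 <- simulate_methylomes(tr$states, cfg)
  expect_equal(m1$allc, m2$allc)
  # generating one accession alone reproduces its slice of the full run
  acc <- colnames(tr$states)[3]
  m3 <- simulate_methylomes(tr$states, cfg, accessions = acc)
  expect_equal(m3$allc[[acc]], m1$allc[[acc]])
  # written files are identical across runs
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  f1 <- simulate_methylomes(tr$states, cfg, accessions = acc, dir = d1)
  f2 <- simulate_methylomes(tr$states, cfg, accessions = acc, dir = d2)
  expect_equal(readLines(f1$allc[[acc]]), readLines(f2$allc[[acc]]))
})

test_that("simulated methylomes have the configured marginals", {
  cfg <- simulation_config(n_accessions = 4, n_genes = 150, seed = 9)
  tr <- simulate_state_matrix(cfg)
  m <- simulate_methylomes(tr$states, cfg)
  allc <- m$allc[[1]]
  # Poisson coverage around the configured mean
  se <- sqrt(cfg$coverage_mean / nrow(allc))
  expect_lt(abs(mean(allc$cov) - cfg$coverage_mean), 4 * se)
  # a thinner library produces sites at <= 2 reads, exercising the
  # low-coverage calling rule downstream
  cfg_thin <- simulation_config(n_accessions = 2, n_genes = 50,
                                coverage_mean = 4, seed = 10)
  tr_thin <- simulate_state_matrix(cfg_thin)
  m_thin <- simulate_methylomes(tr_thin$states, cfg_thin)
  expect_gt(sum(m_thin$allc[[1]]$cov <= 2), 0)
  # read-level methylation at CG sites of UM epialleles stays near the
  # no-conversion floor plus the 5% truly methylated fraction
  sites <- m$sites
  st <- tr$states[sites$gene_id, 1]
  um_cg <- which(st == "UM" & sites$context == "CG")
  obs <- allc[data.table::data.table(chrom = sites$chrom[um_cg],
                                     pos = sites$pos[um_cg]),
              on = c("chrom", "pos")]
  frac <- sum(obs$mc) / sum(obs$cov)
  p_exp <- cfg$p_meth_UM * cfg$meth_read_rate +
    (1 - cfg$p_meth_UM) * cfg$nonconversion_rate
  expect_lt(abs(frac - p_exp), 0.02)
})

test_that("the written GFF3 annotation is read back faithfully", {
  cfg <- simulation_config(n_accessions = 3, n_genes = 25, seed = 44)
  tr <- simulate_state_matrix(cfg)
  dir <- tempfile()
  m <- simulate_methylomes(tr$states, cfg, accessions = colnames(tr$states)[1],
                           dir = dir)
  ann <- read_gene_annotation(m$gff)
  expect_equal(nrow(ann), 25L)
  expect_equal(sort(ann$gene_id), sort(unique(m$sites$gene_id)))
  orig <- m$annotation[order(gene_id)]
  expect_equal(ann[order(gene_id), .(gene_id, start, end)],
               orig[, .(gene_id, start, end)])
  # and the reader keeps only the longest transcript when several exist
  extra <- c(readLines(m$gff),
             sprintf("Chr1\tepisfs\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.2;Parent=%s",
                     orig$start[1], orig$start[1] + 10L,
                     orig$gene_id[1], orig$gene_id[1]),
             sprintf("Chr1\tepisfs\tCDS\t%d\t%d\t.\t+\t0\tID=%s.2.c;Parent=%s.2",
                     orig$start[1], orig$start[1] + 10L,
                     orig$gene_id[1], orig$gene_id[1]))
  f2 <- tempfile(fileext = ".gff3")
  writeLines(extra, f2)
  ann2 <- read_gene_annotation(f2)
  expect_equal(ann2[gene_id == orig$gene_id[1], end], orig$end[1])
})

test_that("classification on simulated methylomes recovers the truth", {
  cfg <- simulation_config(n_accessions = 8, n_genes = 200, seed = 66)
  tr <- simulate_state_matrix(cfg)
  m <- simulate_methylomes(tr$states, cfg)
  acc_ok <- numeric(0)
  for (acc in colnames(tr$states)[1:4]) {
    calls <- call_sites(m$allc[[acc]])
    calls <- assign_sites_to_genes(calls, m$annotation)
    bg <- compute_background_rates(calls)
    cl <- classify_genes(count_gene_context_sites(calls), bg)
    truth <- tr$states[, acc]
    inferred <- cl$state[match(rownames(tr$states), cl$gene_id)]
    keep <- !is.na(truth)
    acc_ok <- c(acc_ok, mean(inferred[keep] == truth[keep], na.rm = TRUE))
  }
  expect_gte(mean(acc_ok), 0.98)
})
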