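make_calls <- function(context, n, n_meth, gene = NULL) {
  data.table::data.table(
    chrom = "Chr1", pos = seq_len(n), strand = "+", context = context,
    cov = 10L, status = rep(c("methylated", "unmethylated"),
                            c(n_meth, n - n_meth)),
    gene_id = gene)
}

test_that("background rates are per-context methylated fractions", {
  calls <- rbind(make_calls("CG", 100, 10), make_calls("CHG", 100, 5),
                 make_calls("CHH", 100, 1))
  expect_equal(compute_background_rates(calls),
               c(CG = 0.10, CHG = 0.05, CHH = 0.01))
  # context with no eligible site is undefined
  bg <- compute_background_rates(make_calls("CG", 1000, 50))
  expect_equal(bg[["CG"]], 0.05)
  expect_true(is.nan(bg[["CHG"]]) && is.nan(bg[["CHH"]]))
  # all unmethylated
  expect_equal(unname(compute_background_rates(
    rbind(make_calls("CG", 10, 0), make_calls("CHG", 10, 0),
          make_calls("CHH", 10, 0)))), c(0, 0, 0))
  # low-coverage sites are excluded from both numerator and denominator
  lc <- make_calls("CG", 100, 50)
  lc$cov[1:50] <- 2L
  expect_equal(compute_background_rates(lc)[["CG"]], 0)
})

test_that("gene classification follows the significance rules", {
  bg <- c(CG = 0.05, CHG = 0.05, CHH = 0.05)
  counts <- data.table::rbindlist(list(
    # 19 CG sites: below the site minimum in every context
    data.table::data.table(gene_id = "g_few", context = "CG",
                           total_sites = 19L, meth_sites = 19L),
    # fully methylated CG, other contexts at background
    data.table::data.table(gene_id = "g_gbm", context = c("CG", "CHG", "CHH"),
                           total_sites = c(20L, 20L, 20L),
                           meth_sites = c(20L, 1L, 1L)),
    # one of twenty methylated: P(X >= 1 | 20, .05) = 1 - .95^20 = 0.642
    data.table::data.table(gene_id = "g_um", context = c("CG", "CHG", "CHH"),
                           total_sites = c(20L, 20L, 20L),
                           meth_sites = c(1L, 1L, 1L)),
    # CHG enrichment without CG enrichment (CG not required for mCHG)
    data.table::data.table(gene_id = "g_chg", context = c("CG", "CHG", "CHH"),
                           total_sites = c(20L, 30L, 20L),
                           meth_sites = c(1L, 30L, 0L)),
    # CHH enrichment dominates
    data.table::data.table(gene_id = "g_chh", context = c("CG", "CHG", "CHH"),
                           total_sites = c(20L, 20L, 30L),
                           meth_sites = c(20L, 20L, 30L))))
  cl <- classify_genes(counts, bg)
  states <- setNames(cl$state, cl$gene_id)
  expect_equal(states[["g_few"]], "undetermined")
  expect_equal(states[["g_gbm"]], "gbM")
  expect_equal(states[["g_um"]], "UM")
  expect_equal(states[["g_chg"]], "mCHG")
  expect_equal(states[["g_chh"]], "mCHH")
  # every gene got exactly one state from the five-value set
  expect_true(all(cl$state %in% c("UM", "gbM", "mCHG", "mCHH",
                                  "undetermined")))
  # deterministic
  expect_identical(cl, classify_genes(counts, bg))
})

test_that("a raw CG p-value of 0.05^20 underlies the fully methylated gene", {
  # single-gene family: BH is the identity, so the corrected p is the raw
  counts <- data.table::data.table(gene_id = "g1", context = "CG",
                                   total_sites = 20L, meth_sites = 20L)
  cl <- classify_genes(counts, bg = c(CG = 0.05, CHG = 0.05, CHH = 0.05))
  expect_equal(cl$p_CG, 0.05^20)
  expect_equal(classify_genes(
    data.table::data.table(gene_id = "g1", context = "CG",
                           total_sites = 20L, meth_sites = 1L),
    bg = c(CG = 0.05, CHG = 0.05, CHH = 0.05))$p_CG,
    1 - 0.95^20)
})

test_that("an undefined background for a required context gives undetermined", {
  counts <- data.table::data.table(gene_id = "g1", context = "CG",
                                   total_sites = 30L, meth_sites = 30L)
  cl <- classify_genes(counts, bg = c(CG = 0.05, CHG = NaN, CHH = 0.05))
  expect_equal(cl$state, "undetermined")
})

test_that("strong gbM genes are recovered in nearly every accession", {
  # within-gene CG methylation 0.85 against background 0.05, >= 30 CG sites
  set.seed(7)
  n_rep <- 400L
  bg <- c(CG = 0.05, CHG = 0.03, CHH = 0.02)
  n_cg <- sample(30:60, n_rep, TRUE)
  counts <- data.table::rbindlist(lapply(seq_len(n_rep), function(i)
    data.table::data.table(
      gene_id = sprintf("g%04d", i), context = c("CG", "CHG", "CHH"),
      total_sites = c(n_cg[i], 30L, 30L),
      meth_sites = c(rbinom(1, n_cg[i], 0.85), rbinom(1, 30, 0.03),
                     rbinom(1, 30, 0.02)))))
  cl <- classify_genes(counts, bg)
  expect_gte(mean(cl$state == "gbM"), 0.99)
})

test_that("ancestral states follow two-outgroup parsimony", {
  og <- function(s1a, s1b, s2a, s2b)
    data.table::data.table(gene_id = "g", species = rep(c("sp1", "sp2"), each = 2),
                           replicate = c(1, 2, 1, 2),
                           state = c(s1a, s1b, s2a, s2b))
  expect_equal(infer_ancestral(og("gbM", "gbM", "gbM", "gbM"))$state, "gbM")
  expect_equal(infer_ancestral(og("UM", "UM", "UM", "UM"))$state, "UM")
  # replicate discordance within a species
  expect_equal(infer_ancestral(og("gbM", "UM", "gbM", "gbM"))$state,
               "ambiguous")
  # discordance between species
  expect_equal(infer_ancestral(og("UM", "UM", "gbM", "gbM"))$state,
               "ambiguous")
  # shared state outside gbM/UM does not polarize the spectrum
  expect_equal(infer_ancestral(og("mCHG", "mCHG", "mCHG", "mCHG"))$state,
               "ambiguous")
  # absent replicate call
  expect_equal(infer_ancestral(og("gbM", NA, "gbM", "gbM"))$state, "missing")
  # genes absent from the outgroup table (non-syntelogs) are missing
  res <- infer_ancestral(og("gbM", "gbM", "gbM", "gbM"),
                         genes = c("g", "not_a_syntelog"))
  expect_equal(res[gene_id == "not_a_syntelog", state], "missing")
})

test_that("state matrices tally to the accession count", {
  mat <- toy_state_matrix(list(
    g1 = c("UM", "UM", "gbM", NA),
    g2 = c("mCHG", "undetermined", "gbM", "UM")))
  tal <- state_tallies(mat)
  tots <- tal$n_UM + tal$n_gbM + tal$n_mCHG + tal$n_mCHH +
    tal$n_undetermined + tal$n_missing
  expect_equal(tots, c(4L, 4L))
  expect_equal(tal$n_UM, c(2L, 1L))
  expect_equal(tal$n_missing, c(1L, 0L))
})
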