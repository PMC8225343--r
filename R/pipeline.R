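#' Run the full gene-level analysis track on synthetic methylomes
#'
#' End-to-end orchestration of the gene-level pipeline on generated data:
#' simulate a state matrix and per-accession bisulfite counts, call cytosine
#' methylation per accession (BH within accession), classify gene states
#' against the genome-wide CDS background, infer ancestral states from the
#' outgroup calls, build projected SFS per ancestral subset, fit the
#' selection model by MCMC and test goodness of fit. Accessions are
#' processed one at a time so memory stays flat in the accession count.
#'
#' @param sim A [simulation_config()].
#' @param n_prime Projection sample size for the SFS.
#' @param conv A [conversion_config()].
#' @param mcmc An [mcmc_config()].
#' @param subsets Character subset labels to fit: any of `"all"`,
#'   `"ancestral_gbM"`, `"ancestral_UM"`.
#' @param both_orientations Fit both selection orientations and keep the
#'   stronger (default); otherwise each ancestral subset is fit with its
#'   natural orientation and `"all"` with UM advantage.
#' @param out_dir If given, write state matrix, ancestral calls, spectra,
#'   fit reports and a checksum manifest into this directory.
#' @return List with `truth`, `states` (inferred matrix), `accuracy`
#'   (cellwise agreement with truth where truth is non-missing),
#'   `background` (per-accession rates), `ancestral`, `sfs`, `fits`, `gof`,
#'   and `manifest` (when `out_dir` is used).
#' @export
run_pipeline <- function(sim = simulation_config(), n_prime,
                         conv = conversion_config(),
                         mcmc = mcmc_config(),
                         subsets = c("ancestral_gbM", "ancestral_UM"),
                         both_orientations = TRUE,
                         out_dir = NULL) {
  stopifnot(all(subsets %in% c("all", "ancestral_gbM", "ancestral_UM")))
  truth <- simulate_state_matrix(sim)
  structures <- simulate_gene_structures(sim)
  accs <- colnames(truth$states)
  per_acc <- vector("list", length(accs))
  names(per_acc) <- accs
  bg_all <- matrix(NA_real_, length(accs), 3,
                   dimnames = list(accs, c("CG", "CHG", "CHH")))
  # the cytosine layout is shared across accessions, so the CDS overlap is
  # resolved once and reused as a keyed join
  site_map <- assign_sites_to_genes(structures$sites[, .(chrom, pos)],
                                    structures$annotation)
  data.table::setkey(site_map, chrom, pos)
  for (acc in accs) {
    meth <- simulate_methylomes(truth$states, sim, accessions = acc,
                                structures = structures)
    calls <- call_sites(meth$allc[[acc]], conv)
    calls <- site_map[calls, on = c("chrom", "pos"), nomatch = NULL]
    bg <- compute_background_rates(calls, conv$min_coverage)
    bg_all[acc, ] <- bg
    counts <- count_gene_context_sites(calls, conv$min_coverage)
    per_acc[[acc]] <- classify_genes(counts, bg)
  }
  states <- build_state_matrix(per_acc, genes = rownames(truth$states))
  cmp <- !is.na(truth$states)
  accuracy <- sum(states[cmp] == truth$states[cmp], na.rm = TRUE) / sum(cmp)
  ancestral <- infer_ancestral(truth$outgroup_calls,
                               genes = rownames(states))
  gene_sets <- list(
    all = rownames(states),
    ancestral_gbM = ancestral[state == "gbM", gene_id],
    ancestral_UM = ancestral[state == "UM", gene_id])
  natural <- c(all = "UM_advantage", ancestral_gbM = "gbM_advantage",
               ancestral_UM = "UM_advantage")
  sfs <- fits <- gof <- list()
  for (sub in subsets) {
    sfs[[sub]] <- build_gene_sfs(states, n_prime, genes = gene_sets[[sub]],
                                 label = sub)
    fits[[sub]] <- if (both_orientations)
      fit_both_orientations(sfs[[sub]], sim$Ne, mcmc)
    else run_mcmc(sfs[[sub]], sim$Ne, natural[[sub]], mcmc)
    pm <- fits[[sub]]$summary
    pars <- model_params(mu = pm[parameter == "mu", mean],
                         nu = pm[parameter == "nu", mean],
                         s = pm[parameter == "s", mean], Ne = sim$Ne,
                         orientation = fits[[sub]]$orientation)
    gof[[sub]] <- gof_chisq(sfs[[sub]],
                            expected_sfs(pars, n_prime, sum(sfs[[sub]]$d)))
  }
  res <- list(truth = truth, states = states, accuracy = accuracy,
              background = bg_all, ancestral = ancestral,
              sfs = sfs, fits = fits, gof = gof)
  if (!is.null(out_dir)) res$manifest <- write_pipeline_outputs(res, out_dir)
  res
}

# TSV/JSON artifacts plus an md5 manifest
write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  wtsv <- function(x, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(x, p, sep = "\t")
    paths <<- c(paths, p)
  }
  sm <- data.table::as.data.table(res$states, keep.rownames = "gene_id")
  wtsv(sm, "state_matrix.tsv")
  wtsv(state_tallies(res$states), "state_tallies.tsv")
  wtsv(res$ancestral, "ancestral_states.tsv")
  for (sub in names(res$sfs)) {
    s <- res$sfs[[sub]]
    wtsv(data.table::data.table(k = 0:s$n_prime, d_k = s$d),
         paste0("sfs_", sub, ".tsv"))
    wtsv(res$fits[[sub]]$chains, paste0("chains_", sub, ".tsv"))
    rep <- list(summary = res$fits[[sub]]$summary,
                orientation = res$fits[[sub]]$orientation,
                acceptance = res$fits[[sub]]$acceptance,
                verdict = res$fits[[sub]]$verdict,
                seed = res$fits[[sub]]$seed,
                gof = res$gof[[sub]],
                attrition = s$attrition)
    p <- file.path(out_dir, paste0("fit_", sub, ".json"))
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, p)
  }
  manifest <- data.table::data.table(file = basename(paths),
                                     md5 = unname(tools::md5sum(paths)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, dataframe = "rows")
  manifest
}
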