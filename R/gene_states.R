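#' Genome-wide CDS background methylation rates
#'
#' Per-context fraction of called-methylated cytosines among all CDS
#' cytosines with sufficient coverage, for one accession. These rates are the
#' null of the gene-level enrichment tests.
#'
#' @param calls Site calls restricted to CDS (from [call_sites()] +
#'   [assign_sites_to_genes()]) for one accession.
#' @param min_coverage Coverage floor for a site to enter numerator and
#'   denominator (default 3, matching the cytosine-level analysis).
#' @return Named numeric `c(CG=, CHG=, CHH=)`; `NaN` marks a context with no
#'   eligible sites (its rate is undefined).
#' @export
compute_background_rates <- function(calls, min_coverage = 3L) {
  calls <- data.table::as.data.table(calls)
  elig <- calls[cov >= min_coverage]
  out <- c(CG = NaN, CHG = NaN, CHH = NaN)
  if (nrow(elig)) {
    r <- elig[, .(rate = mean(status == "methylated")), by = context]
    out[r$context] <- r$rate
  }
  out
}

#' Tally methylated / eligible CDS sites per gene and context
#'
#' @param calls Site calls with a `gene_id` column (one accession).
#' @param min_coverage Coverage floor for site eligibility.
#' @return `data.table` with `gene_id`, `context`, `total_sites`,
#'   `meth_sites`.
#' @export
count_gene_context_sites <- function(calls, min_coverage = 3L) {
  calls <- data.table::as.data.table(calls)
  calls[cov >= min_coverage,
        .(total_sites = .N, meth_sites = sum(status == "methylated")),
        by = .(gene_id, context)]
}

# states a gene x accession can take; "missing" is encoded as NA
.gene_states <- c("UM", "gbM", "mCHG", "mCHH", "undetermined")

#' Classify gene methylation states for one accession
#'
#' Per gene and context, a one-sided binomial test asks whether the fraction
#' of methylated CDS cytosines exceeds the genome-wide CDS background rate;
#' p-values are BH-corrected across all genes of the accession, separately
#' per context. A gene is:
#'
#' * **gbM** - >= `min_sites` CG sites, CG significant, CHG and CHH not;
#' * **mCHG** - >= `min_sites` CHG sites, CHG significant, CHH not
#'   (CG significance is not required);
#' * **mCHH** - >= `min_sites` CHH sites and CHH significant;
#' * **UM** - >= `min_sites` CG sites and no context significant;
#' * **undetermined** otherwise (including when a needed background rate is
#'   undefined).
#'
#' The five categories are mutually exclusive by construction. Contexts with
#' no eligible sites in a gene count as not significant (p = 1), so e.g. a
#' gene without CHH sites can still be gbM.
#'
#' @param counts Output of [count_gene_context_sites()].
#' @param bg Output of [compute_background_rates()] for the same accession.
#' @param min_sites Minimum eligible sites in the defining context
#'   (default 20).
#' @param p_threshold Significance cutoff (default 0.05, one-sided).
#' @param use_corrected Threshold the BH-corrected p-value (default) rather
#'   than the raw one.
#' @return `data.table` with `gene_id`, `state` and the per-context
#'   (corrected) p-values `p_CG`, `p_CHG`, `p_CHH`.
#' @export
classify_genes <- function(counts, bg, min_sites = 20L, p_threshold = 0.05,
                           use_corrected = TRUE) {
  counts <- data.table::as.data.table(counts)
  genes <- unique(counts$gene_id)
  p <- n <- matrix(NA_real_, length(genes), 3,
                   dimnames = list(genes, c("CG", "CHG", "CHH")))
  n[] <- 0
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- counts[context == ctx]
    if (nrow(sub) == 0L) next
    n[sub$gene_id, ctx] <- sub$total_sites
    if (is.nan(bg[[ctx]])) next      # undefined background: leave p = NA
    raw <- pbinom(sub$meth_sites - 1, sub$total_sites, bg[[ctx]],
                  lower.tail = FALSE)
    raw[sub$total_sites == 0] <- 1
    p[sub$gene_id, ctx] <- if (use_corrected) p.adjust(raw, "BH") else raw
  }
  # a context absent from a gene carries no evidence of enrichment
  absent <- n == 0
  for (ctx in c("CG", "CHG", "CHH"))
    if (!is.nan(bg[[ctx]])) p[absent[, ctx], ctx] <- 1
  sig <- p <= p_threshold            # NA propagates -> undetermined
  state <- rep("undetermined", length(genes))
  ok <- function(x) !is.na(x) & x
  enough <- n >= min_sites
  is_gbm  <- enough[, "CG"]  & ok(sig[, "CG"]) & ok(!sig[, "CHG"]) &
    ok(!sig[, "CHH"])
  is_chg  <- enough[, "CHG"] & ok(sig[, "CHG"]) & ok(!sig[, "CHH"])
  is_chh  <- enough[, "CHH"] & ok(sig[, "CHH"])
  is_um   <- enough[, "CG"]  & ok(!sig[, "CG"]) & ok(!sig[, "CHG"]) &
    ok(!sig[, "CHH"])
  state[is_um]  <- "UM"
  state[is_gbm] <- "gbM"
  state[is_chg] <- "mCHG"
  state[is_chh] <- "mCHH"
  data.table::data.table(gene_id = genes, state = state,
                         p_CG = p[, "CG"], p_CHG = p[, "CHG"],
                         p_CHH = p[, "CHH"])
}

#' Assemble a gene x accession state matrix
#'
#' @param per_accession Named list (by accession) of [classify_genes()]
#'   outputs.
#' @param genes Optional character vector fixing row order; genes missing
#'   from an accession are `NA` (no data).
#' @return Character matrix, rows = genes, columns = accessions, entries in
#'   `{UM, gbM, mCHG, mCHH, undetermined, NA}`.
#' @export
build_state_matrix <- function(per_accession, genes = NULL) {
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(per_accession, `[[`, "gene_id"))))
  mat <- matrix(NA_character_, length(genes), length(per_accession),
                dimnames = list(genes, names(per_accession)))
  for (acc in names(per_accession)) {
    cl <- per_accession[[acc]]
    mat[cl$gene_id, acc] <- cl$state
  }
  mat
}

#' Per-gene state tallies
#'
#' @param mat State matrix from [build_state_matrix()] or
#'   [simulate_state_matrix()].
#' @return `data.table` with per-gene counts of each state plus `n_missing`;
#'   tallies sum to the number of accessions.
#' @export
state_tallies <- function(mat) {
  tab <- vapply(.gene_states, function(s) rowSums(mat == s, na.rm = TRUE),
                numeric(nrow(mat)))
  if (nrow(mat) == 1L) tab <- matrix(tab, 1, dimnames = list(NULL, .gene_states))
  out <- data.table::data.table(gene_id = rownames(mat))
  for (s in .gene_states) out[[paste0("n_", s)]] <- as.integer(tab[, s])
  out$n_missing <- as.integer(rowSums(is.na(mat)))
  out
}

#' Infer ancestral gene methylation states from outgroup calls
#'
#' Parsimony over two outgroup species with two replicates each: the
#' ancestral state is the value shared by all four calls when that value is
#' gbM or UM. Replicate- or species-discordant genes, and genes whose shared
#' outgroup state is neither gbM nor UM, are `ambiguous`; genes with any
#' absent call (or absent from the table, e.g. non-syntelogs) are `missing`.
#'
#' @param outgroup_calls `data.frame` with columns `gene_id`, `species`,
#'   `replicate`, `state`.
#' @param genes Optional gene universe; genes absent from `outgroup_calls`
#'   are reported as `missing`.
#' @return `data.table` with `gene_id` and `state` in
#'   `{gbM, UM, ambiguous, missing}`.
#' @export
infer_ancestral <- function(outgroup_calls, genes = NULL) {
  oc <- data.table::as.data.table(outgroup_calls)
  stopifnot(all(c("gene_id", "species", "replicate", "state") %in% names(oc)))
  if (length(unique(oc$species)) != 2L)
    stop("exactly two outgroup species are required")
  res <- oc[, {
    st <- state[!is.na(state)]
    if (length(state) < 4L || length(st) < 4L) {
      "missing"
    } else if (length(unique(st)) > 1L) {
      "ambiguous"
    } else if (st[1] %in% c("gbM", "UM")) {
      st[1]
    } else "ambiguous"
  }, by = gene_id]
  data.table::setnames(res, "V1", "state")
  if (!is.null(genes)) {
    res <- res[data.table::data.table(gene_id = genes), on = "gene_id"]
    res[is.na(state), state := "missing"]
  }
  res[]
}
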