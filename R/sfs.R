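#' Hypergeometric projection of an allele count
#'
#' Probability that `i` copies (i = 0..n') of an allele observed `k` times in
#' a sample of `n` appear in a random subsample of size `n'`:
#' `C(k,i) C(n-k, n'-i) / C(n, n')`. Computed in log space so sample sizes in
#' the hundreds pose no problem. This is the standard device for
#' downsampling a frequency spectrum with missing data to a common sample
#' size.
#'
#' @param k Observed derived-allele count, `0 <= k <= n`.
#' @param n Original sample size.
#' @param n_prime Target sample size, `n_prime <= n`.
#' @return Numeric probability vector of length `n_prime + 1` summing to 1.
#' @export
project_counts <- function(k, n, n_prime) {
  stopifnot(length(k) == 1L, k >= 0, k <= n, n_prime >= 0)
  if (n_prime > n)
    stop("n_prime (", n_prime, ") exceeds sample size n (", n,
         "); such genes must be filtered out before projection")
  i <- 0:n_prime
  p <- exp(lchoose(k, i) + lchoose(n - k, n_prime - i) - lchoose(n, n_prime))
  p
}

new_projected_sfs <- function(d, n_prime, unit, label, attrition) {
  structure(list(d = d, n_prime = as.integer(n_prime), unit = unit,
                 label = label, attrition = attrition),
            class = "projected_sfs")
}

#' @export
print.projected_sfs <- function(x, ...) {
  cat("Projected unfolded SFS (", x$unit, " level): ", x$label, "\n",
      "  n' = ", x$n_prime, ", retained ", format(round(sum(x$d), 2)),
      " ", x$unit, "s\n", sep = "")
  a <- x$attrition
  if (length(a)) cat("  attrition:",
                     paste(names(a), unlist(a), sep = "=", collapse = ", "),
                     "\n")
  invisible(x)
}

#' Build the projected gene-level epiallele SFS
#'
#' For each gene, `n = n_UM + n_gbM` accessions carry an informative
#' epiallele (mCHG/mCHH/undetermined/missing never count toward `n`). Genes
#' with fewer than `n_prime` informative accessions are discarded, as are
#' genes where mCHG/mCHH states exceed `other_frac_max` of the accessions
#' with any determined state (possible pseudogenes or misannotated
#' transposons). Each retained gene adds its hypergeometric projection of
#' `k = n_UM` out of `n` to the expected spectrum, so entries are real
#' valued; the k axis counts unmethylated (UM) epialleles.
#'
#' @param mat Gene x accession state matrix.
#' @param n_prime Projection sample size (600 for the 876-accession leaf
#'   panel, 80 for the 120-accession panel).
#' @param other_frac_max Maximum tolerated mCHG+mCHH fraction (default 0.7).
#' @param genes Optional subset of genes (e.g. ancestrally gbM) to build on.
#' @param label Description stored with the spectrum.
#' @return A `projected_sfs` with `d[k+1]` = expected number of genes with
#'   `k` UM epialleles out of `n_prime`; `sum(d)` equals the retained gene
#'   count.
#' @export
build_gene_sfs <- function(mat, n_prime, other_frac_max = 0.7,
                           genes = NULL, label = "all genes") {
  if (!is.null(genes)) mat <- mat[rownames(mat) %in% genes, , drop = FALSE]
  tal <- state_tallies(mat)
  tal[, n_eff := n_UM + n_gbM]
  n_input <- nrow(tal)
  det <- tal$n_UM + tal$n_gbM + tal$n_mCHG + tal$n_mCHH
  other_frac <- ifelse(det > 0, (tal$n_mCHG + tal$n_mCHH) / det, 0)
  drop_other <- other_frac > other_frac_max
  drop_small <- tal$n_eff < n_prime & !drop_other
  keep <- !drop_other & !drop_small
  attrition <- list(input = n_input,
                    dropped_mCHG_mCHH = sum(drop_other),
                    dropped_below_n_prime = sum(drop_small),
                    retained = sum(keep))
  if (!any(keep))
    stop("no genes retained for the SFS (",
         paste(names(attrition), unlist(attrition), sep = "=",
               collapse = ", "), ")")
  kept <- tal[keep]
  d <- numeric(n_prime + 1)
  # aggregate identical (k, n) pairs so each projection is computed once
  agg <- kept[, .N, by = .(k = n_UM, n = n_eff)]
  for (r in seq_len(nrow(agg)))
    d <- d + agg$N[r] * project_counts(agg$k[r], agg$n[r], n_prime)
  new_projected_sfs(d, n_prime, "gene", label, attrition)
}

#' Build the projected SFS of individual CG cytosines
#'
#' Site-level analogue of [build_gene_sfs()]: for each CG cytosine within
#' the CDS of genes of a given ancestral class, `k` counts accessions where
#' the site is unmethylated among accessions with coverage >= `min_coverage`.
#' Accessions whose gene-level state is mCHG or mCHH are excluded for that
#' gene's cytosines, and cytosines observed in fewer than `n_prime` eligible
#' accessions are dropped.
#'
#' @param site_calls `data.table` with columns `accession`, `gene_id`,
#'   `chrom`, `pos`, `context`, `cov`, `status` pooled over accessions.
#' @param mat Gene x accession state matrix (for the mCHG/mCHH exclusion).
#' @param ancestral Output of [infer_ancestral()].
#' @param gene_class `"gbM"` or `"UM"`: the ancestral class of host genes.
#' @param n_prime Projection sample size.
#' @param min_coverage Per-accession coverage floor (default 3).
#' @return A `projected_sfs` at the cytosine level.
#' @export
build_cytosine_sfs <- function(site_calls, mat, ancestral, gene_class,
                               n_prime, min_coverage = 3L) {
  stopifnot(gene_class %in% c("gbM", "UM"))
  sc <- data.table::as.data.table(site_calls)
  anc_genes <- ancestral[state == gene_class, gene_id]
  sc <- sc[context == "CG" & cov >= min_coverage & gene_id %in% anc_genes]
  n_sites0 <- nrow(unique(sc[, .(gene_id, chrom, pos)]))
  if (nrow(sc)) {
    gs <- mat[cbind(match(sc$gene_id, rownames(mat)),
                    match(sc$accession, colnames(mat)))]
    sc <- sc[!gs %in% c("mCHG", "mCHH")]
  }
  per_site <- sc[, .(n = .N, k = sum(status == "unmethylated")),
                 by = .(gene_id, chrom, pos)]
  keep <- per_site[n >= n_prime]
  attrition <- list(input = n_sites0,
                    dropped_below_n_prime = n_sites0 - nrow(keep),
                    retained = nrow(keep))
  if (nrow(keep) == 0L)
    stop("no cytosines retained for the SFS (",
         paste(names(attrition), unlist(attrition), sep = "=",
               collapse = ", "), ")")
  d <- numeric(n_prime + 1)
  agg <- keep[, .N, by = .(k, n)]
  for (r in seq_len(nrow(agg)))
    d <- d + agg$N[r] * project_counts(agg$k[r], agg$n[r], n_prime)
  new_projected_sfs(d, n_prime, "cytosine",
                    paste("ancestrally", gene_class, "genes"), attrition)
}
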