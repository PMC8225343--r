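#' Configuration for cytosine methylation calling
#'
#' @param nonconversion_rate Bisulfite no-conversion rate, the probability
#'   that a read over a truly unmethylated cytosine still reports it as
#'   methylated. Default 0.0041, the study-wide average for leaf methylomes.
#' @param p_threshold BH-corrected p-value below which a site is called
#'   methylated (default 0.001).
#' @param min_coverage Minimum read coverage for a site to be tested; sites
#'   with fewer reads are declared unmethylated outright (default 3, i.e.
#'   sites with <= 2 reads are never called methylated).
#' @return A list of class `conversion_config`.
#' @export
conversion_config <- function(nonconversion_rate = 0.0041,
                              p_threshold = 0.001,
                              min_coverage = 3L) {
  stopifnot(nonconversion_rate > 0, nonconversion_rate < 1,
            p_threshold > 0, p_threshold < 1, min_coverage >= 1)
  structure(list(nonconversion_rate = nonconversion_rate,
                 p_threshold = p_threshold,
                 min_coverage = as.integer(min_coverage)),
            class = "conversion_config")
}

#' One-sided binomial p-value for a methylated read count
#'
#' Upper-tail probability `P(X >= methylated)` for
#' `X ~ Binomial(coverage, p0)`, where `p0` is the no-conversion rate.
#' Vectorized over all arguments; zero coverage returns 1 (no evidence).
#'
#' @param methylated Methylated read count(s).
#' @param coverage Total read count(s).
#' @param p0 Null methylation probability (no-conversion rate).
#' @return Numeric vector of p-values.
#' @export
binomial_site_pvalue <- function(methylated, coverage, p0) {
  stopifnot(all(p0 > 0), all(p0 < 1))
  if (any(methylated < 0 | methylated > coverage, na.rm = TRUE))
    stop("methylated count must lie in [0, coverage]")
  p <- pbinom(methylated - 1, coverage, p0, lower.tail = FALSE)
  p[coverage == 0] <- 1
  p
}

#' Call cytosine methylation for one accession
#'
#' Sites with coverage below `config$min_coverage` (<= 2 reads by default)
#' are declared unmethylated without testing and are excluded from the
#' multiple-testing family. Remaining sites receive a one-sided binomial
#' p-value against the no-conversion rate, Benjamini-Hochberg corrected
#' across all tested sites of the accession; a site is called methylated
#' when the corrected p-value is below `config$p_threshold`.
#'
#' When the table carries a pre-computed `call` column (as distributed
#' methylome files often do) and `use_existing_calls = TRUE`, those calls are
#' kept and no test is run.
#'
#' @param sites A `data.table` from [read_allc_table()] (one accession).
#' @param config A [conversion_config()].
#' @param use_existing_calls Honour an existing `call` column if present.
#' @return The input with `raw_p`, `corrected_p` and `status` columns added.
#'   `corrected_p` is `NA` for untested (low-coverage) sites.
#' @export
call_sites <- function(sites, config = conversion_config(),
                       use_existing_calls = TRUE) {
  stopifnot(inherits(config, "conversion_config"))
  out <- data.table::copy(data.table::as.data.table(sites))
  if (nrow(out) == 0L) {
    out[, `:=`(raw_p = numeric(), corrected_p = numeric(),
               status = character())]
    return(out[])
  }
  if (use_existing_calls && "call" %in% names(out)) {
    st <- out$call
    if (is.numeric(st)) st <- ifelse(st > 0, "methylated", "unmethylated")
    out[, `:=`(raw_p = NA_real_, corrected_p = NA_real_,
               status = as.character(st))]
    # the low-coverage rule still applies to pre-called data
    out[cov < config$min_coverage, status := "unmethylated"]
    return(out[])
  }
  out[, raw_p := binomial_site_pvalue(mc, cov, config$nonconversion_rate)]
  out[, corrected_p := NA_real_]
  tested <- out$cov >= config$min_coverage
  out[tested, corrected_p := p.adjust(raw_p, method = "BH")]
  out[, status := "unmethylated"]
  out[tested & corrected_p < config$p_threshold, status := "methylated"]
  out[]
}
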