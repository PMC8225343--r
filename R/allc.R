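#' Read an allc-style cytosine count table
#'
#' Reads a tab-separated per-cytosine table with columns chromosome, position,
#' strand, context, methylated read count and total read count, and an
#' optional seventh column carrying a pre-computed methylation call
#' (`"methylated"`/`"unmethylated"` or 1/0). Gzip-compressed files are
#' accepted. A header line is detected automatically (the position column of
#' a data line must be numeric).
#'
#' Each cytosine is one record; CG sites are *not* collapsed across strands.
#'
#' @param path Path to the table (plain or gzipped TSV).
#' @return A `data.table` with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `cov` and, when present in the file, `call`.
#' @export
read_allc_table <- function(path) {
  if (!file.exists(path)) stop("allc table not found: ", path)
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  mc = integer(), cov = integer()))
  }
  if (ncol(dt) < 6L)
    stop("allc table must have >= 6 tab-separated columns ",
         "(chrom, pos, strand, context, mc, cov); found ", ncol(dt))
  dt <- dt[, 1:min(ncol(dt), 7L)]
  nm <- c("chrom", "pos", "strand", "context", "mc", "cov", "call")
  data.table::setnames(dt, nm[seq_len(ncol(dt))])
  dt[, pos := as.integer(pos)]
  dt[, mc := as.integer(mc)]
  dt[, cov := as.integer(cov)]
  validate_allc(dt, path)
  dt[]
}

# invariant checks with 1-based data-line numbers in messages
validate_allc <- function(dt, path = "<allc>") {
  bad <- function(w) if (any(w)) which(w)[1] else 0L
  i <- bad(is.na(dt$pos) | dt$pos < 1L)
  if (i) stop(path, ": invalid position at data line ", i)
  i <- bad(!dt$context %in% c("CG", "CHG", "CHH"))
  if (i) stop(path, ": context must be CG/CHG/CHH at data line ", i,
              " (got '", dt$context[i], "')")
  i <- bad(!dt$strand %in% c("+", "-"))
  if (i) stop(path, ": strand must be +/- at data line ", i)
  i <- bad(is.na(dt$mc) | is.na(dt$cov) | dt$mc < 0L | dt$cov < 0L)
  if (i) stop(path, ": negative or missing read count at data line ", i)
  i <- bad(dt$mc > dt$cov)
  if (i) stop(path, ": methylated count exceeds total count at data line ", i,
              " (", dt$mc[i], " > ", dt$cov[i], ")")
  invisible(dt)
}

#' Write site calls back to an allc-style table
#'
#' Emits the input columns plus `raw_p`, `corrected_p` and `status`.
#'
#' @param calls A `data.table` as returned by [call_sites()].
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_site_calls <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}
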