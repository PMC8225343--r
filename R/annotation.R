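#' Read CDS intervals of the longest transcript per gene from a GFF3 file
#'
#' Imports a GFF3 annotation, resolves the CDS features of each transcript,
#' and keeps, for every gene, the transcript with the largest summed CDS
#' length (ties broken by transcript identifier for determinism). Coordinates
#' are the GFF3 1-based inclusive convention.
#'
#' @param path GFF3 file.
#' @return A `data.table` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; one row per CDS interval.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  tx <- gr[typ %in% c("mRNA", "transcript")]
  if (length(tx) == 0L) stop(path, ": no mRNA/transcript features")
  tx_parent <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) sub("^gene:", "", p[[1]]) else NA_character_, "")
  tx_map <- data.table::data.table(tx_id = sub("^transcript:", "", tx$ID),
                                   gene_id = tx_parent)
  cds <- gr[typ == "CDS"]
  if (length(cds) == 0L) stop(path, ": no CDS features")
  cds_parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) sub("^transcript:", "", p[[1]]) else NA_character_, "")
  cd <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    tx_id = cds_parent)
  cd <- tx_map[cd, on = "tx_id"]
  if (anyNA(cd$gene_id)) stop(path, ": CDS with unresolvable gene parent")
  # longest transcript per gene
  len <- cd[, .(len = sum(end - start + 1L)), by = .(gene_id, tx_id)]
  data.table::setorder(len, gene_id, -len, tx_id)
  keep <- len[, .SD[1L], by = gene_id]
  out <- cd[keep[, .(gene_id, tx_id)], on = c("gene_id", "tx_id")]
  stopifnot(all(out$start <= out$end))
  out[, tx_id := NULL]
  data.table::setcolorder(out, c("gene_id", "chrom", "start", "end", "strand"))
  out[]
}

#' Assign cytosine sites to gene CDS intervals
#'
#' Overlap join of per-cytosine records onto CDS intervals (both 1-based
#' inclusive). Sites outside any CDS are dropped; a site overlapping CDS of
#' several genes is assigned to each.
#'
#' @param sites `data.table` with `chrom` and `pos` columns.
#' @param annotation `data.table` from [read_gene_annotation()] (or the
#'   annotation component of [simulate_methylomes()]).
#' @return `sites` restricted to CDS, with a `gene_id` column added.
#' @export
assign_sites_to_genes <- function(sites, annotation) {
  s <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  a <- GenomicRanges::GRanges(annotation$chrom,
                              IRanges::IRanges(annotation$start,
                                               annotation$end))
  hits <- GenomicRanges::findOverlaps(s, a, ignore.strand = TRUE)
  out <- data.table::as.data.table(sites)[S4Vectors::queryHits(hits)]
  out[, gene_id := annotation$gene_id[S4Vectors::subjectHits(hits)]]
  out[]
}
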