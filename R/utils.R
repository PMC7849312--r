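#' @importFrom stats median p.adjust pnorm pt qnorm rbinom rlnorm rnbinom
#'   rnorm runif sd t.test wilcox.test dhyper fisher.test setNames quantile
#'   complete.cases aggregate
#' @importFrom utils write.table read.delim packageVersion
NULL

# Internal: 0-based half-open alignment intervals <-> 1-based closed GRanges.
aln_to_granges <- function(aln, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = aln$contig,
    ranges = IRanges::IRanges(start = aln$start + 1L, end = aln$end),
    strand = aln$strand
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# Internal: run expr with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# Internal: stable config hash for provenance headers (no timestamps).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  # md5 of the serialized config; file header bytes are constant across runs
  unname(tools::md5sum(f))
}

# Internal: write a data.frame as TSV with '#'-prefixed provenance header.
write_tsv_prov <- function(df, path, provenance = character()) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (line in provenance) {
    writeLines(paste0("# ", line), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: read a provenance-headed TSV back.
read_tsv_prov <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
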