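#' Read a FASTQ file into a raw-read table
#'
#' Loads a (Phred+33) FASTQ file into the plain data.frame representation the
#' processing stages operate on.
#'
#' @param path FASTQ file path.
#' @return Data frame with columns \code{id}, \code{seq}, \code{qual}
#'   (quality string, Phred+33).
#' @export
read_fastq <- function(path) {
  # the reader warns about dropping its own internal metadata columns
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  data.frame(
    id = names(qs),
    seq = as.character(qs),
    qual = as.character(Biostrings::quality(qs)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a raw-read table as FASTQ
#'
#' @param reads Data frame with \code{id}, \code{seq}, \code{qual}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

# Internal: earliest adapter occurrence (full internal match or 3' suffix
# overlap >= min_overlap) per read; NA_integer_ when none. Positions 1-based.
adapter_positions <- function(seqs, adapter, min_overlap) {
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  pos <- ifelse(pos > 0, as.integer(pos), NA_integer_)
  alen <- nchar(adapter)
  n <- nchar(seqs)
  # partial adapter running off the 3' end: read suffix == adapter prefix
  if (alen - 1L >= min_overlap) for (k in seq(alen - 1L, min_overlap)) {
    pref <- substr(adapter, 1L, k)
    hit <- endsWith(seqs, pref) & (n >= k)
    cand <- n - k + 1L
    pos <- ifelse(hit & (is.na(pos) | cand < pos), cand, pos)
  }
  pos
}

#' Trim 3' sequencing adapters
#'
#' Removes the earliest occurrence of any adapter (exact internal match, or a
#' read-terminal prefix of the adapter of length >= \code{min_overlap}) and
#' everything 3' of it, then applies the length window: reads whose trimmed
#' length falls outside \[\code{min_len}, \code{max_len}\] are discarded.
#' Matching is exact (0 mismatches); when several adapters match, the leftmost
#' occurrence across all adapters wins. Qualities are trimmed in register.
#'
#' @param reads Raw-read data frame (\code{id}, \code{seq}, \code{qual}).
#' @param adapters Character vector of 3' adapter sequences.
#' @param min_overlap Minimum terminal overlap to call a partial adapter
#'   (default 5).
#' @param min_len,max_len Retained trimmed-length window (defaults 26 and 38:
#'   a 15-30 nt insert plus two 4-nt UMIs).
#' @return List with \code{kept} (trimmed read table), and counts
#'   \code{n_in}, \code{n_kept}, \code{n_discarded}.
#' @export
trim_adapter <- function(reads, adapters, min_overlap = 5L,
                         min_len = 26L, max_len = 38L) {
  stopifnot(length(adapters) >= 1)
  pos <- rep(NA_integer_, nrow(reads))
  for (ad in adapters) {
    p <- adapter_positions(reads$seq, ad, min_overlap)
    pos <- ifelse(!is.na(p) & (is.na(pos) | p < pos), p, pos)
  }
  newlen <- ifelse(is.na(pos), nchar(reads$seq), pos - 1L)
  out <- reads
  out$seq <- substr(out$seq, 1L, newlen)
  out$qual <- substr(out$qual, 1L, newlen)
  keep <- newlen >= min_len & newlen <= max_len
  list(kept = out[keep, , drop = FALSE],
       n_in = nrow(reads), n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Filter reads on base-call quality
#'
#' Keeps a read iff at least \code{pct} percent of its bases have Phred
#' quality >= \code{q}. With the default \code{pct = 100} a single base below
#' \code{q} discards the read. Empty reads are discarded.
#'
#' @param reads Read table with Phred+33 \code{qual} strings.
#' @param q Phred threshold (default 20).
#' @param pct Minimum percent of bases meeting the threshold (default 100).
#' @return List with \code{kept} and stage counts as in [trim_adapter()].
#' @export
quality_filter <- function(reads, q = 20L, pct = 100) {
  if (nrow(reads) == 0) {
    return(list(kept = reads, n_in = 0L, n_kept = 0L, n_discarded = 0L))
  }
  qint <- as(Biostrings::PhredQuality(reads$qual), "IntegerList")
  n_ok <- sum(qint >= q)
  len <- S4Vectors::elementNROWS(qint)
  keep <- len > 0 & (100 * n_ok / pmax(len, 1L)) >= pct
  list(kept = reads[keep, , drop = FALSE],
       n_in = nrow(reads), n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Collapse PCR duplicates using attached UMIs
#'
#' PCR duplicates are byte-identical copies of the full read — at this stage
#' the two 4-nt UMIs are still attached, so identical inserts from distinct
#' molecules carry different UMIs and are kept apart, while true PCR copies
#' share the entire sequence. Reads with identical full sequence are collapsed
#' to the first occurrence, which carries \code{copies} = multiplicity;
#' first-occurrence order is preserved.
#'
#' @param reads Read table (UMIs still attached; collapse precedes UMI
#'   trimming).
#' @return List with \code{kept} (collapsed table with a \code{copies}
#'   column) and stage counts.
#' @export
collapse_umi_duplicates <- function(reads) {
  if (nrow(reads) == 0) {
    out <- reads
    out$copies <- integer(0)
    return(list(kept = out, n_in = 0L, n_kept = 0L, n_discarded = 0L))
  }
  first <- !duplicated(reads$seq)
  idx <- match(reads$seq, reads$seq[first])
  out <- reads[first, , drop = FALSE]
  out$copies <- as.integer(tabulate(idx, nbins = sum(first)))
  list(kept = out, n_in = nrow(reads), n_kept = nrow(out),
       n_discarded = nrow(reads) - nrow(out))
}

#' Trim UMIs and extract the insert
#'
#' Stores the first and last \code{umi_len} bases as the 5' and 3' UMIs and
#' keeps the interior as the insert; inserts shorter than \code{min_len} (and
#' reads too short to carry both UMIs) are discarded.
#'
#' @param reads Read table (optionally with \code{copies} from collapsing).
#' @param umi_len UMI length at each end (default 4).
#' @param min_len Minimum insert length (default 15).
#' @return List with \code{kept}: data frame \code{id}, \code{insert},
#'   \code{umi5}, \code{umi3}, \code{copies}; and stage counts.
#' @export
extract_insert <- function(reads, umi_len = 4L, min_len = 15L) {
  n <- nchar(reads$seq)
  long_enough <- n >= 2L * umi_len
  insert <- substr(reads$seq, umi_len + 1L, n - umi_len)
  keep <- long_enough & nchar(insert) >= min_len
  out <- data.frame(
    id = reads$id,
    insert = insert,
    umi5 = substr(reads$seq, 1L, umi_len),
    umi3 = substr(reads$seq, n - umi_len + 1L, n),
    copies = if ("copies" %in% names(reads)) reads$copies else 1L,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  list(kept = out, n_in = nrow(reads), n_kept = sum(keep),
       n_discarded = sum(!keep))
}

#' Run the five-stage small-RNA read-processing pipeline
#'
#' Applies, in fixed order: (i) adapter trimming, (ii) quality filtering,
#' (iii) UMI-aware PCR-duplicate collapsing, (iv) UMI trimming, (v)
#' minimum-insert-length filtering (steps iv and v are one call to
#' [extract_insert()]). The order matters: collapsing must precede UMI
#' trimming, otherwise distinct molecules sharing an insert would be merged.
#'
#' @param reads Raw-read table or a FASTQ path.
#' @param adapters 3' adapter sequences.
#' @param min_overlap,min_len_trim,max_len_trim Adapter-stage parameters
#'   (see [trim_adapter()]).
#' @param q,pct Quality-stage parameters (see [quality_filter()]).
#' @param umi_len,min_insert Insert-stage parameters (see [extract_insert()]).
#' @return List with \code{processed} (insert table) and \code{report}, a
#'   per-stage conservation ledger (\code{stage}, \code{n_in}, \code{n_kept},
#'   \code{n_discarded}).
#' @export
process_reads <- function(reads, adapters,
                          min_overlap = 5L, min_len_trim = 26L,
                          max_len_trim = 38L, q = 20L, pct = 100,
                          umi_len = 4L, min_insert = 15L) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  s1 <- trim_adapter(reads, adapters, min_overlap, min_len_trim, max_len_trim)
  s2 <- quality_filter(s1$kept, q, pct)
  s3 <- collapse_umi_duplicates(s2$kept)
  s4 <- extract_insert(s3$kept, umi_len, min_insert)
  report <- data.frame(
    stage = c("adapter_trim", "quality_filter", "umi_collapse",
              "insert_extract"),
    n_in = c(s1$n_in, s2$n_in, s3$n_in, s4$n_in),
    n_kept = c(s1$n_kept, s2$n_kept, s3$n_kept, s4$n_kept),
    n_discarded = c(s1$n_discarded, s2$n_discarded, s3$n_discarded,
                    s4$n_discarded),
    stringsAsFactors = FALSE
  )
  list(processed = s4$kept, report = report)
}
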