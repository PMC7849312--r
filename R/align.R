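#' Build an exact-match genome index
#'
#' Wraps a reference genome for exhaustive exact-occurrence search on both
#' strands. The search compiles the query inserts into a trusted-band
#' dictionary ([Biostrings::PDict()], band = shortest insert, tails verified
#' exactly) matched against each contig and its reverse complement, so the
#' contract — every exact occurrence of the insert or its reverse complement
#' is found — holds by construction.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return A \code{genome_index} object (list with the genome, its reverse
#'   complement and contig lengths).
#' @export
build_genome_index <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  structure(
    list(genome = genome,
         rc = Biostrings::reverseComplement(genome),
         contig_lengths = setNames(Biostrings::width(genome), names(genome))),
    class = "genome_index"
  )
}

# Internal: all exact occurrences of the given unique inserts. One trusted-
# band dictionary (band = shortest insert) over all patterns; the tail
# beyond the band is verified exactly (max.mismatch = 0). Returns
# data.frame(query = index into `inserts`, contig, start, end, strand) with
# 0-based half-open coordinates.
all_exact_hits <- function(inserts, index) {
  lens <- nchar(inserts)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(inserts),
                          tb.start = 1L, tb.end = min(lens))
  out <- vector("list", 2L * length(index$genome))
  k <- 0L
  for (ci in seq_along(index$genome)) {
    contig <- names(index$genome)[ci]
    clen <- index$contig_lengths[[ci]]
    fwd <- Biostrings::matchPDict(pd, index$genome[[ci]])
    st <- Biostrings::startIndex(fwd)
    nh <- lengths(st)
    if (sum(nh) > 0) {
      k <- k + 1L
      q <- rep(which(nh > 0), nh[nh > 0])
      s1 <- unlist(st[nh > 0], use.names = FALSE)
      out[[k]] <- data.frame(
        query = q, contig = contig, start = s1 - 1L,
        end = s1 - 1L + lens[q], strand = "+", stringsAsFactors = FALSE
      )
    }
    rev <- Biostrings::matchPDict(pd, index$rc[[ci]])
    st <- Biostrings::startIndex(rev)
    nh <- lengths(st)
    if (sum(nh) > 0) {
      k <- k + 1L
      q <- rep(which(nh > 0), nh[nh > 0])
      s1 <- unlist(st[nh > 0], use.names = FALSE)
      # position s1 (1-based) on the reverse complement maps back to the
      # genomic interval [clen - s1 + 1 - L, clen - s1 + 1) in 0-based terms
      out[[k]] <- data.frame(
        query = q, contig = contig, start = clen - s1 + 1L - lens[q],
        end = clen - s1 + 1L, strand = "-", stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0) {
    return(data.frame(query = integer(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(k)])
}

#' Map inserts to the reference by exact matching
#'
#' Finds every exact occurrence of each insert (forward) and of its reverse
#' complement (reported on the minus strand with genomic coordinates) across
#' all contigs. When an insert has several equally good placements, exactly
#' one is reported, chosen uniformly at random from a seeded RNG —
#' the single-report multimapper policy of short-read aligners run with
#' "report one of the best alignments at random", made reproducible.
#' \code{n_hits} records the total number of placements. Inserts containing
#' non-ACGT characters are unmapped and counted separately.
#'
#' @param inserts Character vector of insert sequences (one per read).
#' @param index A [build_genome_index()] object.
#' @param seed Integer seed for multimapper tie-breaking.
#' @param read_ids Optional read identifiers (default
#'   \code{seq_along(inserts)}).
#' @return List with \code{alignments} — data.frame \code{read_id},
#'   \code{contig}, \code{start} (0-based), \code{end} (exclusive),
#'   \code{strand}, \code{n_hits} — and a \code{report} list
#'   (\code{n_in}, \code{n_mapped}, \code{n_unmapped}, \code{n_invalid},
#'   \code{seed}).
#' @export
map_reads <- function(inserts, index, seed = 1L, read_ids = NULL) {
  stopifnot(inherits(index, "genome_index"))
  if (is.null(read_ids)) read_ids <- as.character(seq_along(inserts))
  valid <- grepl("^[ACGT]+$", inserts)
  uq <- unique(inserts[valid])
  hits <- if (length(uq) > 0) all_exact_hits(uq, index) else
    data.frame(query = integer(0), contig = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  # canonical hit order (contig, start, strand) so the seeded draw is
  # independent of dictionary batch order
  hits <- hits[order(hits$query, hits$contig, hits$start, hits$strand), ,
               drop = FALSE]
  hpq <- tabulate(hits$query, nbins = length(uq))   # hits per unique insert
  offset <- c(0L, cumsum(hpq))
  qidx <- match(inserts, uq)                        # NA for invalid
  nh_read <- ifelse(is.na(qidx), 0L, hpq[ifelse(is.na(qidx), 1L, qidx)])
  mapped <- !is.na(qidx) & nh_read > 0
  pick <- with_seed(seed, {
    ifelse(nh_read > 1,
           floor(runif(length(inserts)) * nh_read) + 1L,
           1L)
  })
  row_of <- offset[qidx[mapped]] + pmin(pick[mapped], nh_read[mapped])
  sel <- hits[row_of, , drop = FALSE]
  alignments <- data.frame(
    read_id = read_ids[mapped],
    contig = sel$contig, start = sel$start, end = sel$end,
    strand = sel$strand, n_hits = nh_read[mapped],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(
    alignments = alignments,
    report = list(n_in = length(inserts), n_mapped = sum(mapped),
                  n_unmapped = sum(valid & !mapped),
                  n_invalid = sum(!valid), seed = seed)
  )
}

#' Map a single insert
#'
#' Convenience wrapper over [map_reads()] for one insert.
#'
#' @inheritParams map_reads
#' @param insert A single insert sequence.
#' @return One-row alignment data.frame, or \code{NULL} when unmapped.
#' @export
map_read <- function(insert, index, seed = 1L) {
  res <- map_reads(insert, index, seed = seed)
  if (nrow(res$alignments) == 0) NULL else res$alignments
}

#' Remove alignments overlapping structural RNAs
#'
#' Drops an alignment iff some structural-RNA feature (rRNA/tRNA/snoRNA/
#' snRNA) on the same strand covers at least \code{min_frac} of the
#' alignment's length — the strand-aware fractional-overlap removal of
#' \code{bedtools intersect -v -s -f 0.9}, with the fraction computed with
#' respect to the read interval.
#'
#' @param alignments Alignment data.frame (0-based half-open).
#' @param structural [GenomicRanges::GRanges] of structural features
#'   (stranded).
#' @param min_frac Minimum covered fraction of the read (default 0.9).
#' @return List with \code{kept} and \code{removed} alignment data.frames.
#' @export
filter_structural <- function(alignments, structural, min_frac = 0.9) {
  if (nrow(alignments) == 0) {
    return(list(kept = alignments, removed = alignments))
  }
  gr <- GenomicRanges::GRanges(
    alignments$contig,
    IRanges::IRanges(alignments$start + 1L, alignments$end),
    strand = alignments$strand
  )
  ov <- GenomicRanges::findOverlaps(gr, structural, ignore.strand = FALSE)
  w <- IRanges::width(IRanges::pintersect(
    gr[S4Vectors::queryHits(ov)], structural[S4Vectors::subjectHits(ov)]
  ))
  frac <- w / IRanges::width(gr[S4Vectors::queryHits(ov)])
  bad <- unique(S4Vectors::queryHits(ov)[frac >= min_frac])
  keep <- !(seq_len(nrow(alignments)) %in% bad)
  list(kept = alignments[keep, , drop = FALSE],
       removed = alignments[!keep, , drop = FALSE])
}

#' Per-sample RPM normalization factor
#'
#' @param sample_id Sample identifier.
#' @param non_structural_mapped Number of mapped non-structural reads.
#' @return List with \code{sample_id}, \code{non_structural_mapped} and
#'   \code{scale} = 1e6 / \code{non_structural_mapped}.
#' @export
norm_factor <- function(sample_id, non_structural_mapped) {
  if (non_structural_mapped <= 0) {
    stop("RPM normalization undefined with 0 non-structural mapped reads")
  }
  list(sample_id = sample_id,
       non_structural_mapped = non_structural_mapped,
       scale = 1e6 / non_structural_mapped)
}

#' Convert a read count to reads-per-million
#'
#' RPM = count x 1e6 / (mapped non-structural reads of the sample).
#'
#' @param count Read count (vectorized).
#' @param norm A [norm_factor()] object.
#' @return RPM value(s).
#' @export
normalize_rpm <- function(count, norm) {
  count * norm$scale
}
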