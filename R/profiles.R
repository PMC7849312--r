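#' Per-base coverage track for one contig
#'
#' Depth per position (each read covers its full interval), scaled to RPM.
#'
#' @param alignments Alignment data.frame restricted to the reads of interest
#'   (e.g. classified 22G reads antisense to the sensor).
#' @param contig_id Contig to profile.
#' @param contig_length Contig length (bp).
#' @param norm A [norm_factor()] for the sample.
#' @return Numeric vector of length \code{contig_length}: RPM depth at each
#'   position (index i = 0-based position i-1).
#' @export
coverage_track <- function(alignments, contig_id, contig_length, norm) {
  a <- alignments[alignments$contig == contig_id, , drop = FALSE]
  if (nrow(a) == 0) return(numeric(contig_length))
  cov <- IRanges::coverage(
    IRanges::IRanges(a$start + 1L, a$end), width = contig_length
  )
  as.numeric(cov) * norm$scale
}

#' Sensor coverage with replicate mean and SD
#'
#' Computes per-replicate RPM coverage tracks over the sensor contig and
#' their positionwise mean and standard deviation — the "read density over
#' the transgene, average of biological replicates" display.
#'
#' @param aln_list List of alignment data.frames, one per replicate.
#' @param contig_id,contig_length Sensor contig id and length.
#' @param norms List of [norm_factor()]s, parallel to \code{aln_list}.
#' @return List with \code{tracks} (matrix position x replicate),
#'   \code{mean}, \code{sd}.
#' @export
sensor_coverage <- function(aln_list, contig_id, contig_length, norms) {
  if (length(aln_list) == 0) stop("at least one replicate required")
  stopifnot(length(aln_list) == length(norms))
  tracks <- vapply(
    seq_along(aln_list),
    function(i) coverage_track(aln_list[[i]], contig_id, contig_length,
                               norms[[i]]),
    numeric(contig_length)
  )
  list(tracks = tracks,
       mean = rowMeans(tracks),
       sd = apply(tracks, 1, sd))
}

#' Quantify secondary and tertiary 22G RNAs on the sensor
#'
#' Secondary 22Gs are those triggered directly at the 21U recognition site:
#' reads whose interval intersects the site padded by \code{pad} on each
#' side. Tertiary 22Gs spread along the mCherry coding region: reads
#' intersecting the CDS but not the secondary window. Reported per replicate
#' in RPM, with the median across replicates.
#'
#' @param aln_list Per-replicate alignment data.frames of sensor-antisense
#'   22G reads (0-based half-open).
#' @param layout A [sensor_layout()].
#' @param norms Per-replicate [norm_factor()]s.
#' @param pad Padding (bp) around the 21-bp recognition site (default 50).
#' @return List with \code{per_replicate} (data.frame replicate,
#'   secondary_rpm, tertiary_rpm), \code{median_secondary},
#'   \code{median_tertiary}, \code{windows}.
#' @export
window_quantify <- function(aln_list, layout, norms, pad = 50L) {
  sec_win <- c(layout$u21_site[1] - pad, layout$u21_site[2] + pad)
  ter_win <- layout$mcherry_cds
  if (sec_win[1] < ter_win[2] && ter_win[1] < sec_win[2]) {
    stop("secondary window overlaps the mCherry CDS after padding; reduce pad")
  }
  quant <- function(a, norm) {
    a <- a[a$contig == layout$contig_id, , drop = FALSE]
    in_sec <- a$start < sec_win[2] & a$end > sec_win[1]
    in_ter <- a$start < ter_win[2] & a$end > ter_win[1] & !in_sec
    c(secondary = sum(in_sec) * norm$scale,
      tertiary = sum(in_ter) * norm$scale)
  }
  per_rep <- t(vapply(seq_along(aln_list),
                      function(i) quant(aln_list[[i]], norms[[i]]),
                      numeric(2)))
  df <- data.frame(replicate = seq_along(aln_list),
                   secondary_rpm = per_rep[, "secondary"],
                   tertiary_rpm = per_rep[, "tertiary"])
  list(per_replicate = df,
       median_secondary = median(df$secondary_rpm),
       median_tertiary = median(df$tertiary_rpm),
       windows = list(secondary = sec_win, tertiary = ter_win))
}

# Internal: normalized cumulative coverage of one gene on `n_bins` relative-
# position bins in transcript orientation. `cov` is the per-base coverage of
# the gene interval in genomic orientation; reversed for minus-strand genes.
# Fractional assignment: the continuous cumulative coverage F(x), x in [0, L],
# is evaluated at x = L*j/n_bins by linear interpolation within a base.
gene_cumcurve <- function(cov, strand, n_bins = 100L) {
  if (strand == "-") cov <- rev(cov)
  total <- sum(cov)
  if (total <= 0) return(rep(NA_real_, n_bins))
  L <- length(cov)
  cum <- c(0, cumsum(cov))
  x <- L * seq_len(n_bins) / n_bins
  i <- pmin(floor(x), L - 1)          # completed whole bases
  (cum[i + 1] + (x - i) * cov[i + 1]) / total
}

#' Metagene cumulative 22G coverage curve for a gene set
#'
#' For each gene in the set, the antisense 22G coverage is resampled onto
#' 100 equal relative-position bins (5' to 3' in transcript orientation),
#' cumulated, and normalized to the gene's total coverage, so every per-gene
#' curve rises from 0 to exactly 1. The set curve is the mean over genes,
#' computed per replicate; the replicate SD is returned for shading.
#' Zero-coverage genes are excluded and counted.
#'
#' @param aln_list Per-replicate alignment data.frames of classified 22G
#'   reads (0-based half-open).
#' @param annotation Annotation GRanges (features with \code{type == "gene"}).
#' @param gene_set Character vector of gene IDs to profile.
#' @param n_bins Number of relative-position bins (default 100).
#' @return List with \code{per_gene} (array bin x gene x replicate),
#'   \code{mean} (length \code{n_bins}), \code{sd} (across replicates),
#'   \code{n_genes_used}, \code{n_zero_excluded}.
#' @export
metagene_curve <- function(aln_list, annotation, gene_set, n_bins = 100L) {
  genes <- annotation[annotation$type == "gene" & annotation$ID %in% gene_set]
  if (length(genes) == 0) stop("no annotated genes in the requested set")
  nrep <- length(aln_list)
  curves <- array(NA_real_, dim = c(n_bins, length(genes), nrep),
                  dimnames = list(NULL, genes$ID, NULL))
  for (r in seq_len(nrep)) {
    a <- aln_list[[r]]
    gr <- aln_to_granges(a)
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      # antisense reads: opposite strand to the gene
      sel <- a$contig == as.character(GenomeInfoDb::seqnames(g)) &
        a$strand != as.character(BiocGenerics::strand(g)) &
        a$start < BiocGenerics::end(g) & a$end > BiocGenerics::start(g) - 1L
      sub <- a[sel, , drop = FALSE]
      cov <- numeric(BiocGenerics::width(g))
      if (nrow(sub) > 0) {
        s0 <- pmax(sub$start - (BiocGenerics::start(g) - 1L), 0L)
        e0 <- pmin(sub$end - (BiocGenerics::start(g) - 1L),
                   BiocGenerics::width(g))
        cov <- as.numeric(IRanges::coverage(
          IRanges::IRanges(s0 + 1L, e0), width = BiocGenerics::width(g)))
      }
      curves[, gi, r] <- gene_cumcurve(
        cov, as.character(BiocGenerics::strand(g)), n_bins)
    }
  }
  used <- apply(curves, 2, function(m) !all(is.na(m)))
  per_rep_mean <- apply(curves, c(1, 3), function(v) mean(v, na.rm = TRUE))
  list(per_gene = curves,
       mean = rowMeans(per_rep_mean),
       sd = apply(per_rep_mean, 1, sd),
       n_genes_used = sum(used),
       n_zero_excluded = sum(!used))
}

# Internal: per-gene normalized coverage summed within `n_bins` equal
# gene-length bins (partition of 1 for covered genes).
gene_bin_fractions <- function(curve_bins100, n_bins = 10L) {
  idx <- seq(100 / n_bins, 100, by = 100 / n_bins)
  cum <- curve_bins100[idx]
  diff(c(0, cum))
}

#' Per-bin genotype comparison of metagene distributions
#'
#' Sums each gene's normalized 22G coverage within 10 equal gene-length bins
#' and compares genotypes bin by bin with a two-tailed unpaired t-test across
#' genes, Bonferroni-corrected for the 10 bins (p_adj = min(1, 10p)).
#' Replicates are pooled per genotype before binning.
#'
#' @param mg_a,mg_b [metagene_curve()] outputs for the two genotypes (same
#'   gene set).
#' @param n_bins Number of gene-length bins (default 10; also the
#'   Bonferroni factor).
#' @return Data frame \code{bin} (1-10), \code{mean_a}, \code{mean_b},
#'   \code{t}, \code{p}, \code{p_adj} (\code{NA} when a bin has fewer than 2
#'   usable genes in either genotype).
#' @export
binned_metagene_test <- function(mg_a, mg_b, n_bins = 10L) {
  pooled_bins <- function(mg) {
    # average the per-gene cumulative curves over replicates, then bin
    curves <- apply(mg$per_gene, c(1, 2), function(v) mean(v, na.rm = TRUE))
    apply(curves, 2, gene_bin_fractions, n_bins = n_bins)  # n_bins x genes
  }
  A <- pooled_bins(mg_a)
  B <- pooled_bins(mg_b)
  out <- data.frame(bin = seq_len(n_bins), mean_a = NA_real_,
                    mean_b = NA_real_, t = NA_real_, p = NA_real_)
  for (b in seq_len(n_bins)) {
    x <- A[b, ]; y <- B[b, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    out$mean_a[b] <- mean(x); out$mean_b[b] <- mean(y)
    if (length(x) >= 2 && length(y) >= 2 && (sd(x) > 0 || sd(y) > 0)) {
      ht <- t_test2(x, y)
      out$t[b] <- ht$t; out$p[b] <- ht$p
    } else if (length(x) >= 2 && length(y) >= 2) {
      out$t[b] <- 0; out$p[b] <- 1
    }
  }
  out$p_adj <- pmin(1, n_bins * out$p)
  out
}

#' 22G profile centered on 21U target sites
#'
#' Accumulates antisense-22G 5'-end positions in a window of
#' \code{-flank..+flank} around the anchor of each 21-nt 21U target site.
#' The anchor is the genomic base pairing with position 10 of the 21U RNA
#' (1-based along the 21U, i.e. the 10th base of the site in target-
#' transcript orientation — the Argonaute cleavage-site convention).
#' Offsets are signed so that positive = 3' of the anchor on the target
#' transcript. Counts are RPM-scaled and summarized as replicate mean ± SD.
#'
#' @param aln_list Per-replicate alignment data.frames of classified 22G
#'   reads.
#' @param sites GRanges of 21-nt target sites, stranded by target-transcript
#'   strand.
#' @param norms Per-replicate [norm_factor()]s.
#' @param flank Window half-width in bp (default 50).
#' @return List with \code{offsets} (-flank..flank), \code{per_replicate}
#'   (matrix offset x replicate, RPM), \code{mean}, \code{sd}.
#' @export
site_profile <- function(aln_list, sites, norms, flank = 50L) {
  if (any(BiocGenerics::width(sites) < 21)) {
    stop("every 21U target site must be at least 21 nt")
  }
  offsets <- seq(-flank, flank)
  prof <- matrix(0, nrow = length(offsets), ncol = length(aln_list))
  site_start0 <- BiocGenerics::start(sites) - 1L
  site_end0 <- BiocGenerics::end(sites)
  site_strand <- as.character(BiocGenerics::strand(sites))
  anchor <- ifelse(site_strand == "+", site_start0 + 9L, site_end0 - 10L)
  for (r in seq_along(aln_list)) {
    a <- aln_list[[r]]
    if (nrow(a) == 0) next
    # 5' end of the read in genomic coordinates (0-based)
    pos5 <- ifelse(a$strand == "+", a$start, a$end - 1L)
    for (si in seq_along(sites)) {
      on_contig <- a$contig == as.character(GenomeInfoDb::seqnames(sites[si]))
      antisense <- a$strand != site_strand[si]
      off <- if (site_strand[si] == "+") pos5 - anchor[si] else
        anchor[si] - pos5
      sel <- on_contig & antisense & off >= -flank & off <= flank
      if (any(sel)) {
        tab <- table(factor(off[sel], levels = offsets))
        prof[, r] <- prof[, r] + as.numeric(tab) * norms[[r]]$scale
      }
    }
  }
  list(offsets = offsets, per_replicate = prof,
       mean = rowMeans(prof), sd = apply(prof, 1, sd))
}
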