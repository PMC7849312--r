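#' Small-RNA class decision table
#'
#' The class definitions are C. elegans field convention rather than anything
#' printed alongside the figures, so they are explicit and configurable here:
#' 21U = 21-nt, 5' U (T in DNA space), sense overlap with a piRNA locus;
#' 22G / 26G = 22- / 26-nt, 5' G, antisense to an annotated gene (the 21U
#' sensor transcript counts as a gene); miRNA = sense overlap with a miRNA
#' locus at any length in \code{mirna_len}. The first matching rule in
#' \code{precedence} wins, so no read is double counted.
#'
#' @param precedence Rule order (default miRNA, 21U, 22G, 26G).
#' @param len_21u,len_22g,len_26g Read lengths for the respective classes.
#' @param base_21u,base_22g 5' base requirements (DNA alphabet).
#' @param mirna_len Length range admitted for miRNA reads.
#' @return A \code{class_rules} list.
#' @export
class_rules <- function(precedence = c("miRNA", "21U", "22G", "26G"),
                        len_21u = 21L, len_22g = 22L, len_26g = 26L,
                        base_21u = "T", base_22g = "G",
                        mirna_len = c(18L, 26L)) {
  structure(list(precedence = precedence, len_21u = len_21u,
                 len_22g = len_22g, len_26g = len_26g, base_21u = base_21u,
                 base_22g = base_22g, mirna_len = mirna_len),
            class = "class_rules")
}

# Internal: logical vector — query alignments having an overlap with `features`
# in the given orientation ("sense": same strand; "antisense": opposite).
overlaps_oriented <- function(gr, features, orientation) {
  if (length(features) == 0) return(rep(FALSE, length(gr)))
  q <- gr
  if (orientation == "antisense") {
    BiocGenerics::strand(q) <- ifelse(
      as.character(BiocGenerics::strand(gr)) == "+", "-", "+")
  }
  h <- S4Vectors::queryHits(GenomicRanges::findOverlaps(q, features))
  seq_along(gr) %in% h
}

#' Classify mapped reads into small-RNA classes
#'
#' Applies the [class_rules()] decision table to each alignment: class is a
#' function of insert length, 5' base and annotation context only, and every
#' read gets exactly one class (\code{"other"} when no rule matches).
#'
#' @param alignments Alignment data.frame (0-based half-open), one row per
#'   mapped, non-structural read.
#' @param inserts Character vector of insert sequences, parallel to
#'   \code{alignments}.
#' @param annotation [GenomicRanges::GRanges] with a \code{type} column
#'   containing at least \code{gene}, \code{piRNA}, \code{miRNA} features
#'   (stranded).
#' @param rules A [class_rules()] object.
#' @return The alignment data.frame with \code{length}, \code{base5} and
#'   \code{class} columns appended.
#' @export
classify_reads <- function(alignments, inserts, annotation,
                           rules = class_rules()) {
  stopifnot(nrow(alignments) == length(inserts))
  len <- nchar(inserts)
  base5 <- substr(inserts, 1L, 1L)
  gr <- aln_to_granges(alignments)
  genes <- annotation[annotation$type == "gene"]
  pirna <- annotation[annotation$type == "piRNA"]
  mirna <- annotation[annotation$type == "miRNA"]
  crit <- list(
    "miRNA" = len >= rules$mirna_len[1] & len <= rules$mirna_len[2] &
      overlaps_oriented(gr, mirna, "sense"),
    "21U" = len == rules$len_21u & base5 == rules$base_21u &
      overlaps_oriented(gr, pirna, "sense"),
    "22G" = len == rules$len_22g & base5 == rules$base_22g &
      overlaps_oriented(gr, genes, "antisense"),
    "26G" = len == rules$len_26g & base5 == rules$base_22g &
      overlaps_oriented(gr, genes, "antisense")
  )
  cls <- rep("other", nrow(alignments))
  for (rule in rev(rules$precedence)) {
    cls[crit[[rule]]] <- rule
  }
  out <- alignments
  out$length <- len
  out$base5 <- base5
  out$class <- cls
  out
}

#' Per-class totals in RPM
#'
#' @param classified Output of [classify_reads()].
#' @param norm A [norm_factor()] for the sample.
#' @return Data frame \code{class}, \code{n_reads}, \code{rpm}, one row per
#'   class in \{21U, 22G, 26G, miRNA, other\} (zero rows retained).
#' @export
class_totals <- function(classified, norm) {
  levels <- c("21U", "22G", "26G", "miRNA", "other")
  n <- table(factor(classified$class, levels = levels))
  data.frame(class = levels, n_reads = as.integer(n),
             rpm = normalize_rpm(as.integer(n), norm),
             stringsAsFactors = FALSE)
}

#' Per-gene antisense 22G count matrix
#'
#' Counts, per sample, the classified 22G reads antisense to each annotated
#' gene. A read antisense to two or more overlapping genes increments none
#' (counted as ambiguous); all annotated genes keep a row even at zero.
#'
#' @param classified_list Named list (sample_id -> [classify_reads()]
#'   output).
#' @param annotation Annotation GRanges; rows = features with
#'   \code{type == "gene"}, identified by their \code{ID}.
#' @return List with \code{counts} (integer matrix genes x samples),
#'   \code{ambiguous} (per-sample ambiguous-read counts).
#' @export
count_per_gene <- function(classified_list, annotation) {
  genes <- annotation[annotation$type == "gene"]
  gene_ids <- genes$ID
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(classified_list),
                   dimnames = list(gene_ids, names(classified_list)))
  ambiguous <- setNames(integer(length(classified_list)),
                        names(classified_list))
  for (s in names(classified_list)) {
    cl <- classified_list[[s]]
    cl <- cl[cl$class == "22G", , drop = FALSE]
    if (nrow(cl) == 0) next
    gr <- aln_to_granges(cl)
    BiocGenerics::strand(gr) <- ifelse(
      as.character(BiocGenerics::strand(gr)) == "+", "-", "+")
    ov <- GenomicRanges::findOverlaps(gr, genes)
    nper <- tabulate(S4Vectors::queryHits(ov), nbins = length(gr))
    ambiguous[[s]] <- sum(nper > 1)
    keep <- nper[S4Vectors::queryHits(ov)] == 1
    tab <- table(factor(S4Vectors::subjectHits(ov)[keep],
                        levels = seq_along(genes)))
    counts[, s] <- as.integer(tab)
  }
  list(counts = counts, ambiguous = ambiguous)
}

#' Read gene-set lists from TSV
#'
#' Expects columns \code{set_name}, \code{gene_id}; sets may overlap (a gene
#' can belong to several Argonaute target lists).
#'
#' @param path TSV path.
#' @return Named list: set_name -> character vector of gene ids.
#' @export
read_gene_sets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set_name", "gene_id") %in% names(df)))
  split(df$gene_id, df$set_name)
}
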