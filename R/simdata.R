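#' Sensor transgene layout
#'
#' Geometry of the 21U sensor contig: an mCherry coding region and a perfect
#' 21-bp 21U recognition site downstream of it, both inside the sensor
#' transcript. Coordinates are 0-based half-open on the sensor contig.
#'
#' @param contig_id Sensor contig name.
#' @param length Contig length (bp).
#' @param mcherry_cds 0-based half-open interval of the mCherry CDS.
#' @param u21_site 0-based half-open interval of the 21U recognition site
#'   (must be exactly 21 bp and disjoint from the CDS).
#' @param transcript 0-based half-open interval of the sensor transcript
#'   (annotated as a gene so antisense 22Gs classify).
#' @param transcript_strand Strand of the sensor transcript.
#' @return A \code{sensor_layout} list.
#' @export
sensor_layout <- function(contig_id = "sensor", length = 5000L,
                          mcherry_cds = c(1000L, 2000L),
                          u21_site = c(2100L, 2121L),
                          transcript = c(1000L, 2200L),
                          transcript_strand = "+") {
  if (diff(u21_site) != 21L) stop("u21_site must be exactly 21 bp")
  if (u21_site[1] < mcherry_cds[2] && mcherry_cds[1] < u21_site[2]) {
    stop("u21_site and mcherry_cds must be disjoint")
  }
  if (u21_site[2] > length || mcherry_cds[2] > length ||
      min(u21_site[1], mcherry_cds[1]) < 0) {
    stop("sensor features exceed contig bounds")
  }
  structure(list(contig_id = contig_id, length = as.integer(length),
                 mcherry_cds = as.integer(mcherry_cds),
                 u21_site = as.integer(u21_site),
                 transcript = as.integer(transcript),
                 transcript_strand = transcript_strand),
            class = "sensor_layout")
}

#' Simulation configuration
#'
#' All tunables for the synthetic study: toy genome scale, read architecture
#' (4-nt UMIs at both insert ends followed by the 3' adapter and a random
#' tail), small-RNA class mix, sample design, planted per-gene fold changes,
#' PCR-duplication and low-quality rates. Identical configurations (including
#' \code{seed}) produce byte-identical outputs.
#'
#' @param seed Master seed; every random draw derives from it.
#' @param n_genes Number of protein-coding genes on the autosome-like contig.
#' @param gene_length_bp Gene length.
#' @param n_structural,n_mirna_loci,n_pirna_loci Numbers of structural-RNA,
#'   miRNA and piRNA (21U) loci.
#' @param n_target_sites Number of endogenous 21U target sites, planted
#'   inside WAGO-1 target genes.
#' @param contig_length Autosome-like contig length (bp).
#' @param sensor A [sensor_layout()].
#' @param class_mix Named fractions for classes 21U/22G/26G/miRNA; must sum
#'   to 1.
#' @param structural_frac Fraction of reads drawn from structural loci (taken
#'   off the top before the class mix applies).
#' @param sensor_frac Fraction of 22G reads directed at the sensor.
#' @param sensor_ratio Secondary:tertiary count ratio planted on the sensor.
#' @param sensor_tertiary Plant tertiary (mCherry-body) 22Gs? Setting FALSE
#'   emulates a genotype that has lost the amplified response.
#' @param reads_per_sample Reads per sample before processing.
#' @param samples Data frame \code{sample_id}, \code{genotype},
#'   \code{replicate}.
#' @param reference_genotype Genotype treated as control.
#' @param planted_fold_changes Named numeric, gene id -> log2 fold change of
#'   22G production in non-reference samples. \code{NULL} plants +2 on the
#'   first three and -2 on the next three genes.
#' @param adapter 3' adapter sequence, written without errors.
#' @param umi_len UMI length at each end.
#' @param read_length Raw read length (insert + UMIs + adapter are truncated
#'   or tail-padded to this).
#' @param duplication_rate Fraction of reads that are exact PCR copies of
#'   another read.
#' @param low_quality_frac Fraction of reads given one base below Q20.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, gene_length_bp = 1000L,
                       n_structural = 8L, n_mirna_loci = 10L,
                       n_pirna_loci = 20L, n_target_sites = 10L,
                       contig_length = 200000L, sensor = sensor_layout(),
                       class_mix = c("21U" = 0.15, "22G" = 0.55,
                                     "26G" = 0.10, "miRNA" = 0.20),
                       structural_frac = 0.02, sensor_frac = 0.05,
                       sensor_ratio = 10, sensor_tertiary = TRUE,
                       reads_per_sample = 50000L,
                       samples = default_samples(),
                       reference_genotype = "WT",
                       planted_fold_changes = NULL,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       umi_len = 4L, read_length = 55L,
                       duplication_rate = 0.2, low_quality_frac = 0.05) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (umi_len < 0) stop("umi_len must be >= 0")
  if (reads_per_sample <= 0) stop("reads_per_sample must be > 0")
  stopifnot(all(c("sample_id", "genotype", "replicate") %in% names(samples)))
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    n_structural = as.integer(n_structural),
    n_mirna_loci = as.integer(n_mirna_loci),
    n_pirna_loci = as.integer(n_pirna_loci),
    n_target_sites = as.integer(n_target_sites),
    contig_length = as.integer(contig_length), sensor = sensor,
    class_mix = class_mix, structural_frac = structural_frac,
    sensor_frac = sensor_frac, sensor_ratio = sensor_ratio,
    sensor_tertiary = sensor_tertiary,
    reads_per_sample = as.integer(reads_per_sample), samples = samples,
    reference_genotype = reference_genotype,
    planted_fold_changes = planted_fold_changes, adapter = adapter,
    umi_len = as.integer(umi_len), read_length = as.integer(read_length),
    duplication_rate = duplication_rate,
    low_quality_frac = low_quality_frac
  ), class = "sim_config")
}

#' Default sample sheet: 3 wild-type and 3 mutant replicates
#' @return Data frame \code{sample_id}, \code{genotype}, \code{replicate}.
#' @export
default_samples <- function() {
  data.frame(
    sample_id = c("WT_1", "WT_2", "WT_3", "mut_1", "mut_2", "mut_3"),
    genotype = rep(c("WT", "mutant"), each = 3),
    replicate = rep(1:3, 2),
    stringsAsFactors = FALSE
  )
}

BASES <- c("A", "C", "G", "T")

# Internal: n random fixed-width nucleotide strings (fast columnwise paste).
random_strings <- function(n, width) {
  if (n == 0) return(character(0))
  cols <- replicate(width, sample(BASES, n, replace = TRUE),
                    simplify = FALSE)
  do.call(paste0, cols)
}

#' Build the toy reference: genome, annotation and gene sets
#'
#' Generates a two-contig genome (one autosome-like contig plus the 21U
#' sensor contig), a feature annotation (genes, structural RNAs, miRNA loci,
#' piRNA loci, 21U target sites, sensor features) with no overlapping genes,
#' and overlapping Argonaute-pathway gene-set lists. piRNA loci are built
#' with a 5' T so that sense 21-mers read from them are bona fide 21U RNAs.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory; created if missing. \code{NULL} skips file
#'   output.
#' @return List with \code{genome} ([Biostrings::DNAStringSet]),
#'   \code{annotation} (GRanges with \code{type}, \code{ID}),
#'   \code{gene_sets} (named list), \code{cfg}, and (when written)
#'   \code{paths}.
#' @export
make_reference <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    gap <- 200L
    slot <- cfg$gene_length_bp + gap
    n_slots <- cfg$n_genes
    struct_len <- 150L
    # genes first, then structural / miRNA / piRNA loci in the tail space
    gene_start <- (seq_len(cfg$n_genes) - 1L) * slot   # 0-based
    tail0 <- cfg$n_genes * slot
    struct_start <- tail0 + (seq_len(cfg$n_structural) - 1L) *
      (struct_len + gap)
    mirna0 <- tail0 + cfg$n_structural * (struct_len + gap)
    mirna_start <- mirna0 + (seq_len(cfg$n_mirna_loci) - 1L) * (22L + gap)
    pirna0 <- mirna0 + cfg$n_mirna_loci * (22L + gap)
    pirna_start <- pirna0 + (seq_len(cfg$n_pirna_loci) - 1L) * (21L + gap)
    needed <- pirna0 + cfg$n_pirna_loci * (21L + gap)
    if (needed > cfg$contig_length) {
      stop("contig too short to place requested features (need ", needed,
           " bp, have ", cfg$contig_length, ")")
    }
    chr <- sample(BASES, cfg$contig_length, replace = TRUE)
    # piRNA loci: force a 5' T on the locus strand
    pirna_strand <- rep(c("+", "-"), length.out = cfg$n_pirna_loci)
    for (i in seq_len(cfg$n_pirna_loci)) {
      if (pirna_strand[i] == "+") {
        chr[pirna_start[i] + 1L] <- "T"
      } else {
        chr[pirna_start[i] + 21L] <- "A"
      }
    }
    sensor_seq <- sample(BASES, cfg$sensor$length, replace = TRUE)
    genome <- Biostrings::DNAStringSet(c(
      chrI = paste(chr, collapse = ""),
      paste(sensor_seq, collapse = "")
    ))
    names(genome)[2] <- cfg$sensor$contig_id

    gene_strand <- rep(c("+", "-"), length.out = cfg$n_genes)
    gene_ids <- sprintf("gene_%03d", seq_len(cfg$n_genes))
    ann <- list(
      GenomicRanges::GRanges("chrI",
        IRanges::IRanges(gene_start + 1L,
                         gene_start + cfg$gene_length_bp),
        strand = gene_strand, type = "gene", ID = gene_ids),
      GenomicRanges::GRanges("chrI",
        IRanges::IRanges(struct_start + 1L, struct_start + struct_len),
        strand = rep(c("+", "-"), length.out = cfg$n_structural),
        type = rep(c("rRNA", "tRNA", "snoRNA", "snRNA"),
                   length.out = cfg$n_structural),
        ID = sprintf("struct_%02d", seq_len(cfg$n_structural))),
      GenomicRanges::GRanges("chrI",
        IRanges::IRanges(mirna_start + 1L, mirna_start + 22L),
        strand = rep(c("+", "-"), length.out = cfg$n_mirna_loci),
        type = "miRNA", ID = sprintf("mir_%02d", seq_len(cfg$n_mirna_loci))),
      GenomicRanges::GRanges("chrI",
        IRanges::IRanges(pirna_start + 1L, pirna_start + 21L),
        strand = pirna_strand, type = "piRNA",
        ID = sprintf("21ur_%02d", seq_len(cfg$n_pirna_loci)))
    )
    # gene sets: independent draws so sets overlap, as published lists do
    frac <- c(Mutator = 0.25, `CSR-1` = 0.25, `WAGO-1` = 0.20,
              `ERGO-1` = 0.10, `ALG-3/4` = 0.10,
              replicative_histones = 0.05)
    gene_sets <- lapply(frac, function(f) {
      sort(sample(gene_ids, max(2L, round(f * cfg$n_genes))))
    })
    # 21U target sites sit inside WAGO-1 target genes, on the gene strand
    wago <- gene_sets[["WAGO-1"]]
    site_genes <- wago[seq_len(min(cfg$n_target_sites, length(wago)))]
    gi <- match(site_genes, gene_ids)
    site_start <- gene_start[gi] + 300L
    ann <- c(ann, list(
      GenomicRanges::GRanges("chrI",
        IRanges::IRanges(site_start + 1L, site_start + 21L),
        strand = gene_strand[gi], type = "u21_site",
        ID = sprintf("site_%02d", seq_along(site_genes))),
      GenomicRanges::GRanges(cfg$sensor$contig_id,
        IRanges::IRanges(cfg$sensor$transcript[1] + 1L,
                         cfg$sensor$transcript[2]),
        strand = cfg$sensor$transcript_strand, type = "gene",
        ID = "sensor"),
      GenomicRanges::GRanges(cfg$sensor$contig_id,
        IRanges::IRanges(cfg$sensor$mcherry_cds[1] + 1L,
                         cfg$sensor$mcherry_cds[2]),
        strand = cfg$sensor$transcript_strand, type = "mCherry_CDS",
        ID = "mcherry"),
      GenomicRanges::GRanges(cfg$sensor$contig_id,
        IRanges::IRanges(cfg$sensor$u21_site[1] + 1L,
                         cfg$sensor$u21_site[2]),
        strand = cfg$sensor$transcript_strand, type = "u21_site",
        ID = "sensor_site")
    ))
    annotation <- suppressWarnings(do.call(c, ann))
    GenomeInfoDb::seqlevels(annotation) <- names(genome)
    GenomeInfoDb::seqlengths(annotation) <-
      setNames(Biostrings::width(genome), names(genome))

    out <- list(genome = genome, annotation = annotation,
                gene_sets = gene_sets, cfg = cfg)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        annotation = file.path(dir, "annotation.gff3"),
        gene_sets = file.path(dir, "gene_sets.tsv")
      )
      Biostrings::writeXStringSet(genome, paths$genome)
      rtracklayer::export(annotation, paths$annotation, format = "gff3")
      # drop the export date pragma so identical runs are byte-identical
      gff <- readLines(paths$annotation)
      writeLines(gff[!startsWith(gff, "##date")], paths$annotation)
      gs_df <- data.frame(
        set_name = rep(names(gene_sets), lengths(gene_sets)),
        gene_id = unlist(gene_sets, use.names = FALSE),
        stringsAsFactors = FALSE
      )
      write.table(gs_df, paths$gene_sets, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

# Internal: candidate antisense read-start positions (0-based, relative to
# contig) inside a feature interval such that the read's 5' base is G.
# chars: contig as character vector; interval 0-based half-open; strand of
# the targeted transcript; read_len of the antisense read.
antisense_starts <- function(chars, interval, strand, read_len) {
  lo <- interval[1]; hi <- interval[2]
  if (hi - lo < read_len) return(integer(0))
  p <- lo:(hi - read_len)
  if (strand == "+") {
    # antisense read on '-' strand; its 5' base is complement of base p+L-1
    p[chars[p + read_len] == "C"]
  } else {
    p[chars[p + 1L] == "G"]
  }
}

#' Simulate class-structured small-RNA reads with ground truth
#'
#' Draws reads per sample under the configured class mix: 21-nt 5'-U sense
#' reads from piRNA loci, 22-nt 5'-G reads antisense to genes and to the
#' sensor (secondary/tertiary placement at the configured ratio), 26-nt 5'-G
#' reads antisense to ERGO-1/ALG-3/4 target genes, sense miRNA-locus reads
#' and structural-locus reads. Per-gene 22G abundance is scaled by
#' \code{2^log2FC} in non-reference genotypes. Every raw read is
#' UMI + insert + UMI + adapter (+ random tail), all bases Q40 except the
#' planted low-quality fraction; PCR duplicates are exact copies of existing
#' reads. Molecule full sequences are made unique by UMI re-draws, so with
#' \code{duplication_rate = 0} every read sequence is distinct.
#'
#' @param cfg A [sim_config()].
#' @param ref A [make_reference()] result for the same config.
#' @param dir Output directory for per-sample FASTQ and the truth table;
#'   \code{NULL} skips file output.
#' @return List with \code{truth} (one row per read: sample, read/molecule
#'   ids, class, origin, true placement, UMIs, flags), \code{reads} (named
#'   list of raw-read tables), \code{expected_gene_weights}, and (when
#'   written) \code{paths}.
#' @export
simulate_reads <- function(cfg, ref, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- ref$annotation
  genes <- ann[ann$type == "gene" & ann$ID != "sensor"]
  pirna <- ann[ann$type == "piRNA"]
  mirna <- ann[ann$type == "miRNA"]
  struct <- ann[ann$type == "rRNA" | ann$type == "tRNA" |
                  ann$type == "snoRNA" | ann$type == "snRNA"]
  chr_chars <- strsplit(as.character(ref$genome[["chrI"]]), "")[[1]]
  sen_chars <- strsplit(as.character(ref$genome[[cfg$sensor$contig_id]]),
                        "")[[1]]
  gene_start0 <- BiocGenerics::start(genes) - 1L
  gene_end0 <- BiocGenerics::end(genes)
  gene_strand <- as.character(BiocGenerics::strand(genes))
  gene_ids <- genes$ID

  lfc <- cfg$planted_fold_changes
  if (is.null(lfc)) {
    k <- min(6L, length(gene_ids))
    lfc <- setNames(rep(c(2, -2), each = 3)[seq_len(k)], gene_ids[seq_len(k)])
  }

  cand22 <- lapply(seq_along(genes), function(i) {
    antisense_starts(chr_chars, c(gene_start0[i], gene_end0[i]),
                     gene_strand[i], 22L)
  })
  cand26 <- lapply(seq_along(genes), function(i) {
    antisense_starts(chr_chars, c(gene_start0[i], gene_end0[i]),
                     gene_strand[i], 26L)
  })
  g26 <- which(gene_ids %in% union(ref$gene_sets[["ERGO-1"]],
                                   ref$gene_sets[["ALG-3/4"]]) &
                 lengths(cand26) > 0)
  g22 <- which(lengths(cand22) > 0)
  # sensor secondary/tertiary candidate starts (antisense to the transcript)
  pad <- 50L
  sec_iv <- c(cfg$sensor$u21_site[1] - pad, cfg$sensor$u21_site[2] + pad)
  sen_strand <- cfg$sensor$transcript_strand
  cand_sec <- antisense_starts(sen_chars, sec_iv, sen_strand, 22L)
  cand_ter <- antisense_starts(sen_chars, cfg$sensor$mcherry_cds,
                               sen_strand, 22L)

  base_w <- with_seed(cfg$seed + 17L, rlnorm(length(genes), 0, 0.5))
  base_w[lengths(cand22) == 0] <- 0

  revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  # length-safe uniform draw (avoids sample()'s scalar expansion)
  draw <- function(pool, k, prob = NULL) {
    pool[sample.int(length(pool), k, replace = TRUE, prob = prob)]
  }

  chrI_str <- as.character(ref$genome[["chrI"]])
  sensor_str <- as.character(ref$genome[[cfg$sensor$contig_id]])

  truth_list <- list()
  reads_list <- list()
  for (si in seq_len(nrow(cfg$samples))) {
    sample_id <- cfg$samples$sample_id[si]
    genotype <- cfg$samples$genotype[si]
    is_mut <- genotype != cfg$reference_genotype
    res <- with_seed(cfg$seed + 1000L * si, {
      n <- cfg$reads_per_sample
      n_mol <- n - round(n * cfg$duplication_rate)
      cls_probs <- c(cfg$class_mix * (1 - cfg$structural_frac),
                     structural = cfg$structural_frac)
      cls <- sample(names(cls_probs), n_mol, replace = TRUE,
                    prob = cls_probs)
      insert <- character(n_mol)
      origin <- character(n_mol)
      contig <- character(n_mol)
      start0 <- integer(n_mol)
      strand <- character(n_mol)

      i22 <- which(cls == "22G")
      # sensor reads come off the top of the 22G pool at exact counts so the
      # planted secondary:tertiary ratio is exact
      n_sen <- round(length(i22) * cfg$sensor_frac)
      if (cfg$sensor_tertiary) {
        n_ter <- max(1L, round(n_sen / (cfg$sensor_ratio + 1)))
        n_sec <- as.integer(cfg$sensor_ratio * n_ter)
      } else {
        n_ter <- 0L
        n_sec <- n_sen
      }
      sen_idx <- i22[seq_len(min(n_sec + n_ter, length(i22)))]
      sec_idx <- sen_idx[seq_len(min(n_sec, length(sen_idx)))]
      ter_idx <- setdiff(sen_idx, sec_idx)
      gene_idx22 <- setdiff(i22, sen_idx)

      if (length(sec_idx)) {
        p <- draw(cand_sec, length(sec_idx))
        contig[sec_idx] <- cfg$sensor$contig_id
        start0[sec_idx] <- p
        strand[sec_idx] <- if (sen_strand == "+") "-" else "+"
        insert[sec_idx] <- if (sen_strand == "+") {
          revcomp(substring(sensor_str, p + 1L, p + 22L))
        } else {
          substring(sensor_str, p + 1L, p + 22L)
        }
        origin[sec_idx] <- "sensor_secondary"
      }
      if (length(ter_idx)) {
        p <- draw(cand_ter, length(ter_idx))
        contig[ter_idx] <- cfg$sensor$contig_id
        start0[ter_idx] <- p
        strand[ter_idx] <- if (sen_strand == "+") "-" else "+"
        insert[ter_idx] <- if (sen_strand == "+") {
          revcomp(substring(sensor_str, p + 1L, p + 22L))
        } else {
          substring(sensor_str, p + 1L, p + 22L)
        }
        origin[ter_idx] <- "sensor_tertiary"
      }
      if (length(gene_idx22)) {
        w <- base_w
        if (is_mut && length(lfc)) {
          gi <- match(names(lfc), gene_ids)
          ok <- !is.na(gi)
          w[gi[ok]] <- w[gi[ok]] * 2^lfc[ok]
        }
        g <- draw(g22, length(gene_idx22), prob = w[g22])
        p <- vapply(g, function(gg) {
          cv <- cand22[[gg]]
          cv[sample.int(length(cv), 1L)]
        }, integer(1))
        contig[gene_idx22] <- "chrI"
        start0[gene_idx22] <- p
        strand[gene_idx22] <- ifelse(gene_strand[g] == "+", "-", "+")
        fwd <- substring(chrI_str, p + 1L, p + 22L)
        insert[gene_idx22] <- ifelse(gene_strand[g] == "+",
                                     revcomp(fwd), fwd)
        origin[gene_idx22] <- gene_ids[g]
      }
      i26 <- which(cls == "26G")
      if (length(i26)) {
        g <- draw(g26, length(i26))
        p <- vapply(g, function(gg) {
          cv <- cand26[[gg]]
          cv[sample.int(length(cv), 1L)]
        }, integer(1))
        contig[i26] <- "chrI"
        start0[i26] <- p
        strand[i26] <- ifelse(gene_strand[g] == "+", "-", "+")
        fwd <- substring(chrI_str, p + 1L, p + 26L)
        insert[i26] <- ifelse(gene_strand[g] == "+", revcomp(fwd), fwd)
        origin[i26] <- gene_ids[g]
      }
      i21 <- which(cls == "21U")
      if (length(i21)) {
        li <- sample(length(pirna), length(i21), replace = TRUE)
        p <- BiocGenerics::start(pirna)[li] - 1L
        st <- as.character(BiocGenerics::strand(pirna))[li]
        contig[i21] <- "chrI"
        start0[i21] <- p
        strand[i21] <- st
        fwd <- substring(chrI_str, p + 1L, p + 21L)
        insert[i21] <- ifelse(st == "+", fwd, revcomp(fwd))
        origin[i21] <- pirna$ID[li]
      }
      imir <- which(cls == "miRNA")
      if (length(imir)) {
        li <- sample(length(mirna), length(imir), replace = TRUE)
        p <- BiocGenerics::start(mirna)[li] - 1L
        st <- as.character(BiocGenerics::strand(mirna))[li]
        contig[imir] <- "chrI"
        start0[imir] <- p
        strand[imir] <- st
        fwd <- substring(chrI_str, p + 1L, p + 22L)
        insert[imir] <- ifelse(st == "+", fwd, revcomp(fwd))
        origin[imir] <- mirna$ID[li]
      }
      istr <- which(cls == "structural")
      if (length(istr)) {
        li <- sample(length(struct), length(istr), replace = TRUE)
        len <- sample(18:30, length(istr), replace = TRUE)
        smax <- BiocGenerics::width(struct)[li] - len
        off <- floor(runif(length(istr)) * (smax + 1))
        p <- BiocGenerics::start(struct)[li] - 1L + as.integer(off)
        st <- as.character(BiocGenerics::strand(struct))[li]
        contig[istr] <- "chrI"
        start0[istr] <- p
        strand[istr] <- st
        fwd <- substring(chrI_str, p + 1L, p + len)
        insert[istr] <- ifelse(st == "+", fwd, revcomp(fwd))
        origin[istr] <- struct$ID[li]
      }

      umi5 <- random_strings(n_mol, cfg$umi_len)
      umi3 <- random_strings(n_mol, cfg$umi_len)
      # enforce unique full molecule sequences (UMI collisions on shared
      # inserts would otherwise be indistinguishable from PCR duplicates)
      key <- paste0(umi5, insert, umi3)
      while (anyDuplicated(key)) {
        dup <- which(duplicated(key))
        umi5[dup] <- random_strings(length(dup), cfg$umi_len)
        umi3[dup] <- random_strings(length(dup), cfg$umi_len)
        key <- paste0(umi5, insert, umi3)
      }
      core <- paste0(umi5, insert, umi3, cfg$adapter)
      tail_needed <- pmax(cfg$read_length - nchar(core), 0L)
      tw <- max(tail_needed, 1L)
      tails <- substr(random_strings(n_mol, tw), 1L, tail_needed)
      raw <- substr(paste0(core, tails), 1L, cfg$read_length)

      # PCR duplicates: exact copies of existing reads
      n_dup <- n - n_mol
      dup_src <- if (n_dup > 0) sample.int(n_mol, n_dup, replace = TRUE)
        else integer(0)
      mol_of_read <- c(seq_len(n_mol), dup_src)
      ord <- sample.int(n)   # interleave duplicates
      mol_of_read <- mol_of_read[ord]
      raw_all <- raw[mol_of_read]
      qual_all <- strrep("I", nchar(raw_all))   # Q40
      # low-quality planting: only on reads whose molecule occurs once, so
      # the post-filter molecule multiset stays exactly computable
      n_lowq <- round(n * cfg$low_quality_frac)
      once <- which(mol_of_read %in%
                      which(tabulate(mol_of_read, n_mol) == 1L))
      lowq <- sort(sample(once, min(n_lowq, length(once))))
      if (length(lowq)) {
        # plant within UMI+insert+UMI so the low base survives adapter trim
        core_len <- 2L * cfg$umi_len +
          nchar(insert[mol_of_read[lowq]])
        pos <- ceiling(runif(length(lowq)) * core_len)
        substr(qual_all[lowq], pos, pos) <- "0"   # Q15 < 20
      }
      read_id <- sprintf("%s_r%06d", sample_id, seq_len(n))
      truth <- data.frame(
        sample_id = sample_id, read_id = read_id,
        molecule_id = sprintf("%s_m%06d", sample_id, mol_of_read),
        class = cls[mol_of_read], origin = origin[mol_of_read],
        contig = contig[mol_of_read], start = start0[mol_of_read],
        end = start0[mol_of_read] + nchar(insert[mol_of_read]),
        strand = strand[mol_of_read], insert = insert[mol_of_read],
        umi5 = umi5[mol_of_read], umi3 = umi3[mol_of_read],
        duplicate = duplicated(mol_of_read),
        low_quality = seq_len(n) %in% lowq,
        stringsAsFactors = FALSE
      )
      reads <- data.frame(id = read_id, seq = raw_all, qual = qual_all,
                          stringsAsFactors = FALSE)
      list(truth = truth, reads = reads)
    })
    truth_list[[sample_id]] <- res$truth
    reads_list[[sample_id]] <- res$reads
  }
  out <- list(truth = do.call(rbind, c(truth_list, make.row.names = FALSE)),
              reads = reads_list,
              expected_gene_weights = setNames(base_w, gene_ids),
              planted_fold_changes = lfc)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq <- vapply(names(reads_list), function(s) {
      p <- file.path(dir, paste0(s, ".fastq"))
      write_fastq(reads_list[[s]], p)
      p
    }, character(1))
    tp <- file.path(dir, "truth.tsv")
    write.table(out$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- list(fastq = fq, truth = tp)
  }
  out
}

#' Configuration for synthetic two-channel granule images
#'
#' @param dim Image dimensions c(rows, cols).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param objects Data frame \code{channel} (1 or 2), \code{x}, \code{y}
#'   (planted centers, 1-based pixel coordinates), \code{radius_px}.
#' @param background,peak Background and object intensities (0-1 scale).
#' @param noise_sd Gaussian noise SD added to every pixel (0 = noise-free).
#' @param seed Seed for the noise.
#' @return A \code{granule_image_config} list.
#' @export
granule_image_config <- function(dim = c(128L, 128L), pixel_size_um = 0.1,
                                 objects, background = 0.05, peak = 0.9,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(all(c("channel", "x", "y", "radius_px") %in% names(objects)))
  structure(list(dim = as.integer(dim), pixel_size_um = pixel_size_um,
                 objects = objects, background = background, peak = peak,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "granule_image_config")
}

#' Render synthetic two-channel granule images with ground truth
#'
#' Draws each planted object as an above-background disc at its centroid;
#' channels are co-registered by construction. Planted objects that overlap
#' within a channel are flagged in the truth (\code{overlap_warning}).
#'
#' @param icfg A [granule_image_config()].
#' @param path Optional TIFF output path (16-bit, one plane per channel).
#' @return List with \code{channels} (list of 2 matrices), \code{truth}
#'   (per-object planted centers/areas in px and µm, rendered pixel areas),
#'   and \code{path} when written.
#' @export
simulate_images <- function(icfg, path = NULL) {
  stopifnot(inherits(icfg, "granule_image_config"))
  nr <- icfg$dim[1]; nc <- icfg$dim[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  channels <- list(matrix(icfg$background, nr, nc),
                   matrix(icfg$background, nr, nc))
  obj <- icfg$objects
  obj$area_px_rendered <- NA_integer_
  obj$overlap_warning <- FALSE
  for (ch in 1:2) {
    idx <- which(obj$channel == ch)
    covered <- matrix(0L, nr, nc)
    for (i in idx) {
      disc <- (rows - obj$y[i])^2 + (cols - obj$x[i])^2 <=
        obj$radius_px[i]^2
      channels[[ch]][disc] <- icfg$peak
      obj$area_px_rendered[i] <- sum(disc)
      covered <- covered + disc
    }
    if (any(covered > 1L)) {
      obj$overlap_warning[idx] <- TRUE
    }
  }
  if (icfg$noise_sd > 0) {
    channels <- with_seed(icfg$seed, lapply(channels, function(m) {
      pmin(pmax(m + rnorm(length(m), 0, icfg$noise_sd), 0), 1)
    }))
  }
  truth <- data.frame(
    channel = obj$channel, x_px = obj$x, y_px = obj$y,
    x_um = obj$x * icfg$pixel_size_um, y_um = obj$y * icfg$pixel_size_um,
    radius_px = obj$radius_px, area_px = obj$area_px_rendered,
    area_um2 = obj$area_px_rendered * icfg$pixel_size_um^2,
    overlap_warning = obj$overlap_warning
  )
  out <- list(channels = channels, truth = truth)
  if (!is.null(path)) {
    tiff::writeTIFF(channels, path, bits.per.sample = 16)
    out$path <- path
  }
  out
}

#' Simulate a reversion plate assay
#'
#' Each plate independently shows at least one revertant with probability
#' \eqn{1 - e^{-N f}} (Poisson count of excision events among N animals), the
#' sampling model inverted by the zero-class estimator.
#'
#' @param f_true True per-animal excision frequency.
#' @param n_plates Number of plates scored (T).
#' @param worms_per_plate Animals per plate (N).
#' @return List with \code{T}, \code{R}, \code{N}.
#' @export
simulate_reversion_plates <- function(f_true, n_plates = 100L,
                                      worms_per_plate = 10000L) {
  p_rev <- 1 - exp(-worms_per_plate * f_true)
  R <- rbinom(1L, n_plates, p_rev)
  list(T = n_plates, R = R, N = worms_per_plate)
}
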