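#' Assemble and validate a pipeline run configuration
#'
#' Collects all stage inputs and parameters; every referenced path must
#' exist at validation time, before any compute starts.
#'
#' @param reference Genome FASTA path.
#' @param annotation GFF3 annotation path.
#' @param gene_sets Gene-set TSV path (columns \code{set_name},
#'   \code{gene_id}).
#' @param fastq Named character vector: sample_id -> FASTQ path.
#' @param samples Data frame \code{sample_id}, \code{genotype},
#'   \code{replicate} covering every FASTQ sample.
#' @param reference_genotype Control genotype for differential testing.
#' @param out_dir Output directory.
#' @param adapters 3' adapter sequences for trimming.
#' @param seed Seed for multimapper tie-breaking (recorded in every output
#'   header).
#' @param sensor_contig Sensor contig id (profiled when present).
#' @param pad Secondary-window padding (bp).
#' @param alpha,fc Differential-call thresholds.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(reference, annotation, gene_sets, fastq, samples,
                       reference_genotype = "WT", out_dir,
                       adapters = c("TGGAATTCTCGGGTGCCAAGG",
                                    "AGATCGGAAGAGCACACGTCT"),
                       seed = 1L, sensor_contig = "sensor", pad = 50L,
                       alpha = 0.05, fc = 2) {
  paths <- c(reference = reference, annotation = annotation,
             gene_sets = gene_sets, fastq)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(names(fastq)) || any(names(fastq) == "")) {
    stop("fastq must be a named vector (sample_id -> path)")
  }
  stopifnot(all(c("sample_id", "genotype", "replicate") %in% names(samples)))
  if (!all(names(fastq) %in% samples$sample_id)) {
    stop("every FASTQ sample must appear in the sample sheet")
  }
  structure(list(reference = reference, annotation = annotation,
                 gene_sets = gene_sets, fastq = fastq, samples = samples,
                 reference_genotype = reference_genotype, out_dir = out_dir,
                 adapters = adapters, seed = as.integer(seed),
                 sensor_contig = sensor_contig, pad = as.integer(pad),
                 alpha = alpha, fc = fc),
            class = "run_config")
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes read processing, exact-match mapping, structural filtering,
#' classification, per-gene 22G counting, sensor window quantification and
#' differential testing with gene-set overlap enrichment, writing
#' tab-separated outputs with provenance headers (package version, config
#' hash, seed — no timestamps, so identical configs give byte-identical
#' bundles). A machine-readable run report carries the per-stage read
#' conservation ledger and mapping rates.
#'
#' @param config A [run_config()].
#' @return List with \code{counts}, \code{class_totals},
#'   \code{differential}, \code{overlap}, \code{sensor_windows},
#'   \code{report}, \code{norms} and \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash analysis parameters only (not paths) so equivalent runs in
  # different directories produce identical provenance
  hashable <- unclass(config)
  for (p in c("reference", "annotation", "gene_sets", "fastq", "out_dir")) {
    hashable[[p]] <- basename(hashable[[p]])
  }
  prov <- c(paste0("wormsilence ", as.character(packageVersion("wormsilence"))),
            paste0("config_hash ", config_hash(hashable)),
            paste0("seed ", config$seed),
            paste0("pad ", config$pad))
  index <- build_genome_index(config$reference)
  annotation <- rtracklayer::import(config$annotation, format = "gff3")
  annotation$ID <- if (!is.null(annotation$ID)) annotation$ID else
    annotation$Name
  catalog <- read_gene_sets(config$gene_sets)
  structural <- annotation[annotation$type %in%
                             c("rRNA", "tRNA", "snoRNA", "snRNA")]
  samples <- names(config$fastq)
  classified <- list()
  norms <- list()
  ledger <- list()
  cls_tot <- list()
  for (i in seq_along(samples)) {
    s <- samples[i]
    proc <- process_reads(config$fastq[[s]], config$adapters)
    mapped <- map_reads(proc$processed$insert, index,
                        seed = config$seed + i,
                        read_ids = proc$processed$id)
    filt <- filter_structural(mapped$alignments, structural)
    if (nrow(filt$kept) == 0) {
      stop("pipeline failed at stage 'structural_filter' for sample ", s,
           ": no non-structural mapped reads")
    }
    norms[[s]] <- norm_factor(s, nrow(filt$kept))
    ins <- proc$processed$insert[match(filt$kept$read_id,
                                       proc$processed$id)]
    classified[[s]] <- classify_reads(filt$kept, ins, annotation)
    cls_tot[[s]] <- cbind(sample_id = s,
                          class_totals(classified[[s]], norms[[s]]))
    ledger[[s]] <- rbind(
      proc$report,
      data.frame(stage = c("mapping", "structural_filter"),
                 n_in = c(nrow(proc$processed), nrow(mapped$alignments)),
                 n_kept = c(nrow(mapped$alignments), nrow(filt$kept)),
                 n_discarded = c(nrow(proc$processed) -
                                   nrow(mapped$alignments),
                                 nrow(filt$removed)))
    )
    ledger[[s]]$sample_id <- s
  }
  cm <- count_per_gene(classified, annotation)
  genotype <- config$samples$genotype[match(samples,
                                            config$samples$sample_id)]
  norm <- normalize_counts(cm$counts)
  diff_res <- test_differential(norm$normalized, genotype,
                                config$reference_genotype,
                                alpha = config$alpha, fc = config$fc)
  universe <- annotation$ID[annotation$type == "gene"]
  overlap <- gene_set_overlap(diff_res, catalog, universe,
                              alpha = config$alpha)

  sensor_windows <- NULL
  if (config$sensor_contig %in% names(index$contig_lengths)) {
    sen_ann <- annotation[GenomeInfoDb::seqnames(annotation) ==
                            config$sensor_contig]
    site <- sen_ann[sen_ann$type == "u21_site"]
    cds <- sen_ann[sen_ann$type == "mCherry_CDS"]
    tx <- sen_ann[sen_ann$type == "gene"]
    if (length(site) == 1 && length(cds) == 1) {
      layout <- sensor_layout(
        contig_id = config$sensor_contig,
        length = index$contig_lengths[[config$sensor_contig]],
        mcherry_cds = c(BiocGenerics::start(cds) - 1L,
                        BiocGenerics::end(cds)),
        u21_site = c(BiocGenerics::start(site) - 1L,
                     BiocGenerics::end(site)),
        transcript = c(BiocGenerics::start(tx) - 1L,
                       BiocGenerics::end(tx)),
        transcript_strand = as.character(BiocGenerics::strand(tx))
      )
      aln22 <- lapply(classified, function(cl) {
        cl[cl$class == "22G", , drop = FALSE]
      })
      sensor_windows <- window_quantify(aln22, layout, norms,
                                        pad = config$pad)
    }
  }

  report <- do.call(rbind, c(ledger, make.row.names = FALSE))
  cls_df <- do.call(rbind, c(cls_tot, make.row.names = FALSE))
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, row.names = NULL)
  write_tsv_prov(report, file.path(config$out_dir, "read_report.tsv"), prov)
  write_tsv_prov(cls_df, file.path(config$out_dir, "class_totals.tsv"), prov)
  write_tsv_prov(counts_df, file.path(config$out_dir, "counts_22g.tsv"), prov)
  write_tsv_prov(diff_res, file.path(config$out_dir, "differential.tsv"),
                 prov)
  write_tsv_prov(overlap, file.path(config$out_dir, "overlap.tsv"), prov)
  if (!is.null(sensor_windows)) {
    write_tsv_prov(sensor_windows$per_replicate,
                   file.path(config$out_dir, "sensor_windows.tsv"), prov)
  }
  list(counts = cm$counts, ambiguous = cm$ambiguous, class_totals = cls_df,
       differential = diff_res, overlap = overlap,
       sensor_windows = sensor_windows, report = report, norms = norms,
       classified = classified, out_dir = config$out_dir)
}
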