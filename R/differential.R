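#' Median-of-ratios count normalization
#'
#' Per-sample size factor = median, over genes with nonzero counts in every
#' sample, of the ratio of the gene's count to its geometric mean across
#' samples; the normalized matrix is counts divided by the sample's factor.
#' When no gene is nonzero in all samples the function falls back to
#' total-count scaling (factors proportional to column sums, geometric mean
#' 1) and flags it.
#'
#' @param counts Integer matrix, genes x samples.
#' @return List with \code{normalized} (matrix), \code{size_factors},
#'   \code{method} ("median_of_ratios" or "total_count").
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    log_geo <- rowMeans(log(sub))
    sf <- apply(sub, 2, function(col) exp(median(log(col) - log_geo)))
    method <- "median_of_ratios"
  } else {
    cs <- colSums(counts)
    if (any(cs == 0)) stop("sample with zero total counts")
    sf <- cs / exp(mean(log(cs)))
    method <- "total_count"
  }
  list(normalized = sweep(counts, 2, sf, "/"),
       size_factors = sf, method = method)
}

#' Differential 22G targeting between two genotypes
#'
#' Per-gene comparison of normalized antisense-22G counts between a mutant
#' and a reference genotype: log2 fold change of genotype means with a
#' pseudocount, a two-tailed unpaired location test on \code{log2(normalized
#' + pseudocount)} across replicates, Benjamini-Hochberg adjustment over all
#' tested genes, and status calls at the conventional volcano thresholds —
#' \code{up} iff adjusted p < \code{alpha} and fold change > \code{fc},
#' \code{down} iff adjusted p < \code{alpha} and fold change < -\code{fc}
#' (i.e. |log2FC| > log2(fc)), otherwise \code{ns}. Genes with zero counts in
#' every sample are excluded from testing (status \code{excluded}).
#'
#' With the default \code{var_method = "common"} the test statistic uses a
#' single log-scale variance estimated by pooling the per-gene residual sums
#' of squares over all tested genes — the common-dispersion assumption of
#' count-based differential tools, appropriate at typical small-RNA replicate
#' numbers where a per-gene variance from 2 x 3 samples is too noisy to give
#' useful power. \code{var_method = "per_gene"} gives the classical
#' equal-variance t-test per gene instead.
#'
#' @param normalized Normalized count matrix (genes x samples), e.g.
#'   \code{normalize_counts(counts)$normalized}.
#' @param genotype Character/factor vector, one entry per column.
#' @param reference Reference genotype level (log2FC is other vs reference).
#' @param pseudocount Added before logs (default 0.5).
#' @param alpha Adjusted-p threshold for calling (default 0.05).
#' @param fc Fold-change threshold for calling (default 2).
#' @param var_method \code{"common"} (pooled log-scale variance across
#'   genes, default) or \code{"per_gene"} (classical t-test).
#' @return Data frame \code{gene_id}, \code{base_mean}, \code{log2fc},
#'   \code{p}, \code{p_adj}, \code{status}.
#' @export
test_differential <- function(normalized, genotype, reference,
                              pseudocount = 0.5, alpha = 0.05, fc = 2,
                              var_method = c("common", "per_gene")) {
  var_method <- match.arg(var_method)
  genotype <- as.character(genotype)
  stopifnot(ncol(normalized) == length(genotype))
  lv <- unique(genotype)
  if (!(reference %in% lv)) stop("reference genotype absent from design")
  other <- setdiff(lv, reference)
  if (length(other) != 1) stop("exactly two genotypes required")
  if (sum(genotype == reference) < 2 || sum(genotype == other) < 2) {
    stop("need >= 2 replicates per genotype")
  }
  ref_idx <- genotype == reference
  mut_idx <- genotype == other
  nonzero <- rowSums(normalized) > 0
  lmat <- log2(normalized + pseudocount)
  res <- data.frame(
    gene_id = rownames(normalized),
    base_mean = rowMeans(normalized),
    log2fc = log2(rowMeans(normalized[, mut_idx, drop = FALSE]) + pseudocount) -
      log2(rowMeans(normalized[, ref_idx, drop = FALSE]) + pseudocount),
    p = NA_real_, p_adj = NA_real_, status = "excluded",
    stringsAsFactors = FALSE, row.names = NULL
  )
  tested <- which(nonzero)
  if (var_method == "per_gene") {
    res$p[tested] <- vapply(tested, function(i) {
      t_test2(lmat[i, mut_idx], lmat[i, ref_idx])$p
    }, numeric(1))
  } else {
    n1 <- sum(mut_idx); n2 <- sum(ref_idx)
    m1 <- rowMeans(lmat[, mut_idx, drop = FALSE])
    m2 <- rowMeans(lmat[, ref_idx, drop = FALSE])
    ss <- rowSums((lmat[, mut_idx, drop = FALSE] - m1)^2) +
      rowSums((lmat[, ref_idx, drop = FALSE] - m2)^2)
    df_gene <- n1 + n2 - 2
    df_pool <- df_gene * length(tested)
    s2 <- sum(ss[tested]) / df_pool
    if (s2 == 0) {
      res$p[tested] <- ifelse(m1[tested] == m2[tested], 1, NA_real_)
    } else {
      tstat <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
      res$p[tested] <- 2 * pt(-abs(tstat[tested]), df = df_pool)
    }
  }
  res$p_adj[tested] <- adjust_pvalues(res$p[tested], "BH")
  lfc_thr <- log2(fc)
  sig <- !is.na(res$p_adj) & res$p_adj < alpha
  res$status[tested] <- "ns"
  res$status[sig & res$log2fc > lfc_thr] <- "up"
  res$status[sig & res$log2fc < -lfc_thr] <- "down"
  res
}

#' Gene-set overlap enrichment of differential calls
#'
#' For every gene set and each direction (up, down), builds the 2x2 table
#' over the annotated-gene universe — membership in the set vs membership in
#' the direction — and tests association with Fisher's exact test
#' ([fisher_exact()]); p-values are Benjamini-Hochberg-adjusted across all
#' (set, direction) cells, the reported strength of association is the odds
#' ratio ad/bc, and cells with adjusted p >= \code{alpha} are flagged not
#' significant.
#'
#' @param results [test_differential()] output.
#' @param catalog Named list: set_name -> gene ids (may overlap).
#' @param universe Character vector of gene ids (must contain all set members
#'   and all tested genes).
#' @param alpha Significance threshold for the NS flag (default 0.05).
#' @return Data frame \code{set_name}, \code{direction}, \code{a}, \code{b},
#'   \code{c}, \code{d}, \code{odds_ratio}, \code{p}, \code{p_adj},
#'   \code{ns}.
#' @export
gene_set_overlap <- function(results, catalog, universe, alpha = 0.05) {
  if (!all(unlist(catalog) %in% universe)) {
    stop("universe must contain every gene-set member")
  }
  if (!all(results$gene_id %in% universe)) {
    stop("universe must contain every tested gene")
  }
  grid <- expand.grid(set_name = names(catalog),
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    set <- unique(catalog[[grid$set_name[i]]])
    dir_genes <- results$gene_id[results$status == grid$direction[i]]
    a <- sum(dir_genes %in% set)
    b <- length(dir_genes) - a
    c <- length(set) - a
    d <- length(universe) - a - b - c
    if (length(dir_genes) == 0) {
      data.frame(grid[i, ], a = a, b = b, c = c, d = d,
                 odds_ratio = NA_real_, p = 1, stringsAsFactors = FALSE)
    } else {
      fe <- fisher_exact(a, b, c, d)
      data.frame(grid[i, ], a = a, b = b, c = c, d = d,
                 odds_ratio = fe$odds_ratio, p = fe$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, "BH")
  out$ns <- out$p_adj >= alpha
  rownames(out) <- NULL
  out
}
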