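one_aln <- function(start, len = 22L, contig = "sensor", strand = "-",
                    id = "r1") {
  data.frame(read_id = id, contig = contig, start = start,
             end = start + len, strand = strand, n_hits = 1L,
             stringsAsFactors = FALSE)
}

test_that("coverage tracks add each read over its full interval", {
  nf <- norm_factor("s", 1e6)  # scale 1
  tr <- coverage_track(one_aln(100), "sensor", 500, nf)
  expect_equal(sum(tr), 22)
  expect_true(all(tr[101:122] == 1))
  expect_true(all(tr[-(101:122)] == 0))
  # zero reads -> all-zero track
  expect_equal(sum(coverage_track(one_aln(100)[0, ], "sensor", 500, nf)), 0)
  # coverage conservation: sum = sum(read length x scale)
  alns <- rbind(one_aln(10), one_aln(50), one_aln(400, len = 15L))
  nf2 <- norm_factor("s", 2e6)
  expect_equal(sum(coverage_track(alns, "sensor", 500, nf2)),
               (22 + 22 + 15) * 0.5)
})

test_that("sensor replicate mean and SD match direct recomputation", {
  nf <- norm_factor("s", 1e6)
  reps <- list(one_aln(100), rbind(one_aln(100), one_aln(100, id = "r2")),
               one_aln(130))
  sc <- sensor_coverage(reps, "sensor", 300, list(nf, nf, nf))
  tracks <- sapply(reps, coverage_track, "sensor", 300, nf)
  expect_equal(sc$mean, rowMeans(tracks))
  expect_equal(sc$sd, apply(tracks, 1, sd))
  expect_error(sensor_coverage(list(), "sensor", 300, list()), "replicate")
})

test_that("window quantification separates secondary and tertiary reads", {
  layout <- sensor_layout()
  nf <- norm_factor("s", 1e6)
  sec_read <- one_aln(2100)                # exactly on the site, pad 0 ok
  ter_read <- one_aln(1500)                # inside mCherry
  wq <- window_quantify(list(rbind(sec_read, ter_read)), layout, list(nf))
  expect_equal(wq$per_replicate$secondary_rpm, 1)
  expect_equal(wq$per_replicate$tertiary_rpm, 1)
  # all reads in the secondary window -> tertiary = 0
  wq2 <- window_quantify(list(sec_read), layout, list(nf))
  expect_equal(wq2$per_replicate$tertiary_rpm, 0)
  # pad = 0, read exactly on the site is still secondary
  wq3 <- window_quantify(list(sec_read), layout, list(nf), pad = 0L)
  expect_equal(wq3$per_replicate$secondary_rpm, 1)
  # overlapping windows after padding is an error
  expect_error(window_quantify(list(sec_read), layout, list(nf), pad = 200L),
               "overlaps")
})

test_that("planted secondary:tertiary ratio is recovered exactly", {
  cfg <- tiny_cfg(duplication_rate = 0, low_quality_frac = 0,
                  reads_per_sample = 4000L,
                  samples = data.frame(sample_id = c("WT_1", "mut_1"),
                                       genotype = c("WT", "mutant"),
                                       replicate = c(1L, 1L)))
  ref <- tiny_ref()
  sim <- simulate_reads(cfg, ref)
  idx <- build_genome_index(ref$genome)
  st <- ref$annotation[ref$annotation$type %in%
                         c("rRNA", "tRNA", "snoRNA", "snRNA")]
  quant <- function(s) {
    proc <- process_reads(sim$reads[[s]], default_adapters())
    m <- map_reads(proc$processed$insert, idx, seed = 3,
                   read_ids = proc$processed$id)
    f <- filter_structural(m$alignments, st)
    ins <- proc$processed$insert[match(f$kept$read_id, proc$processed$id)]
    cl <- classify_reads(f$kept, ins, ref$annotation)
    window_quantify(list(cl[cl$class == "22G", ]), cfg$sensor,
                    list(norm_factor(s, nrow(f$kept))))
  }
  wq <- quant("WT_1")
  expect_equal(wq$per_replicate$secondary_rpm /
                 wq$per_replicate$tertiary_rpm, cfg$sensor_ratio)
  # a "mutant" simulated without tertiary production
  cfg2 <- tiny_cfg(duplication_rate = 0, low_quality_frac = 0,
                   sensor_tertiary = FALSE, reads_per_sample = 4000L,
                   samples = data.frame(sample_id = "mut_1",
                                        genotype = "mutant",
                                        replicate = 1L))
  sim2 <- simulate_reads(cfg2, ref)
  proc <- process_reads(sim2$reads[[1]], default_adapters())
  m <- map_reads(proc$processed$insert, idx, seed = 3,
                 read_ids = proc$processed$id)
  f <- filter_structural(m$alignments, st)
  ins <- proc$processed$insert[match(f$kept$read_id, proc$processed$id)]
  cl <- classify_reads(f$kept, ins, ref$annotation)
  wq2 <- window_quantify(list(cl[cl$class == "22G", ]), cfg$sensor,
                         list(norm_factor("mut_1", nrow(f$kept))))
  expect_equal(wq2$per_replicate$tertiary_rpm, 0)
  expect_gt(wq2$per_replicate$secondary_rpm, 0)
})

test_that("metagene curves satisfy their normalization identities", {
  # one + strand gene [1001, 1100] and its - strand mirror [2001, 2100]
  ann <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1001, 2001), c(1100, 2100)),
    strand = c("+", "-"), type = "gene", ID = c("gp", "gm"))
  nf <- norm_factor("s", 1e6)
  # uniform coverage: reads tiling the whole gene body
  tile <- do.call(rbind, lapply(seq(1000, 1090, by = 10), function(s) {
    one_aln(s, len = 10L, contig = "chrT", strand = "-",
            id = paste0("t", s))
  }))
  mg <- metagene_curve(list(tile), ann, "gp")
  expect_equal(mg$mean[100], 1.0)
  expect_equal(mg$mean[50], 0.5, tolerance = 1e-12)
  expect_true(all(diff(mg$per_gene[, 1, 1]) >= 0))
  # gene with all coverage in the first decile reaches 1 by bin 10
  early <- one_aln(1000, len = 10L, contig = "chrT", strand = "-")
  mg_early <- metagene_curve(list(early), ann, "gp")
  expect_equal(mg_early$mean[10], 1.0)
  expect_equal(mg_early$mean[100], 1.0)
  # strand invariance: mirrored coverage on the - strand gene gives the
  # same curve as its + strand counterpart
  tile_m <- do.call(rbind, lapply(seq(2000, 2090, by = 10), function(s) {
    one_aln(s, len = 10L, contig = "chrT", strand = "+",
            id = paste0("m", s))
  }))
  mg_m <- metagene_curve(list(tile_m), ann, "gm")
  expect_equal(mg_m$mean, mg$mean)
  # 5' half coverage on the - strand gene = high genomic coordinates
  half_m <- one_aln(2050, len = 50L, contig = "chrT", strand = "+")
  mg_half <- metagene_curve(list(half_m), ann, "gm")
  expect_equal(mg_half$mean[50], 1.0)
  # zero-coverage genes are excluded and counted
  mg_z <- metagene_curve(list(tile), ann, c("gp", "gm"))
  expect_equal(mg_z$n_genes_used, 1)
  expect_equal(mg_z$n_zero_excluded, 1)
  expect_error(metagene_curve(list(tile), ann, "nonexistent"), "no annotated")
})

test_that("binned metagene test behaves on identical and shifted input", {
  ann <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(seq(1, 9901, by = 500)[1:20] + 1000,
                             seq(1, 9901, by = 500)[1:20] + 1099),
    strand = "+", type = "gene", ID = sprintf("g%02d", 1:20))
  nf <- norm_factor("s", 1e6)
  set.seed(4)
  mk_alns <- function(bias_5prime = FALSE) {
    rows <- lapply(seq_along(ann), function(i) {
      gs <- BiocGenerics::start(ann)[i] - 1L
      n <- 30
      pos <- if (bias_5prime) {
        gs + sample(0:29, n, replace = TRUE)          # first 30% only
      } else {
        gs + sample(0:89, n, replace = TRUE)
      }
      data.frame(read_id = sprintf("g%d_r%d", i, seq_len(n)),
                 contig = "chrT", start = pos, end = pos + 10L,
                 strand = "-", n_hits = 1L, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  a <- mk_alns(); b <- mk_alns()
  mg_a <- metagene_curve(list(a), ann, ann$ID)
  mg_b <- metagene_curve(list(b), ann, ann$ID)
  # per-gene bin sums partition the normalized total
  bins <- apply(mg_a$per_gene[, , 1], 2, function(v) diff(c(0, v[seq(10, 100, 10)])))
  expect_equal(colSums(bins), rep(1, 20), ignore_attr = TRUE)
  res_same <- binned_metagene_test(mg_a, mg_a)
  expect_true(all(res_same$t == 0, na.rm = TRUE))
  expect_true(all(res_same$p_adj == 1, na.rm = TRUE))
  # Bonferroni multiplies by the bin count
  res_ab <- binned_metagene_test(mg_a, mg_b)
  ok <- !is.na(res_ab$p)
  expect_equal(res_ab$p_adj[ok], pmin(1, 10 * res_ab$p[ok]))
  # a genotype with all coverage 5' shifted is detected in early bins
  mg_shift <- metagene_curve(list(mk_alns(bias_5prime = TRUE)), ann, ann$ID)
  res <- binned_metagene_test(mg_a, mg_shift)
  expect_true(any(res$p_adj[1:3] < 0.05))
})

test_that("site profiles anchor at 21U position 10 with signed offsets", {
  # + strand target site [1001,1021] (1-based): anchor = 0-based 1009
  sites <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 1021),
                                  strand = "+", type = "u21_site",
                                  ID = "siteA")
  nf <- norm_factor("s", 1e6)
  # antisense read (- strand): 5' end at genomic end-1
  read_at <- function(p5, id = "r1") {
    # - strand read of length 22 whose 5' end (0-based) is p5
    one_aln(p5 - 21L, len = 22L, contig = "chrT", strand = "-", id = id)
  }
  sp <- site_profile(list(read_at(1009)), sites, list(nf))
  expect_equal(sp$mean[sp$offsets == 0], 1)
  expect_equal(sum(sp$mean), 1)
  # +50 boundary in, +51 out
  sp50 <- site_profile(list(read_at(1059)), sites, list(nf))
  expect_equal(sp50$mean[sp50$offsets == 50], 1)
  sp51 <- site_profile(list(read_at(1060)), sites, list(nf))
  expect_equal(sum(sp51$mean), 0)
  # additivity over identical sites
  sites2 <- c(sites, GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(5001, 5021), strand = "+",
    type = "u21_site", ID = "siteB"))
  two <- rbind(read_at(1009, "a"), read_at(5009, "b"))
  sp2 <- site_profile(list(two), sites2, list(nf))
  expect_equal(sp2$mean[sp2$offsets == 0], 2)
  # - strand site: anchor = end-10 in 0-based terms, offsets flipped
  site_m <- GenomicRanges::GRanges("chrT", IRanges::IRanges(3001, 3021),
                                   strand = "-", type = "u21_site",
                                   ID = "siteM")
  # anchor = 3021-1-9 = 3011 (0-based); antisense read is + strand with
  # 5' end at start; put its 5' end 3 bp 3' of the anchor in transcript
  # orientation (i.e. genomically anchor-3)
  rp <- one_aln(3011 - 3L, len = 22L, contig = "chrT", strand = "+")
  spm <- site_profile(list(rp), site_m, list(nf))
  expect_equal(spm$mean[spm$offsets == 3], 1)
  expect_error(site_profile(list(rp), GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(1, 15), strand = "+"), list(nf)), "21 nt")
})

test_that("profiles are additive under sample merging", {
  nf <- norm_factor("s", 1e6)
  a <- one_aln(2100); b <- one_aln(1500, id = "r2")
  merged <- window_quantify(list(rbind(a, b)), sensor_layout(), list(nf))
  separate_sec <- window_quantify(list(a), sensor_layout(), list(nf))
  separate_ter <- window_quantify(list(b), sensor_layout(), list(nf))
  expect_equal(merged$per_replicate$secondary_rpm,
               separate_sec$per_replicate$secondary_rpm)
  expect_equal(merged$per_replicate$tertiary_rpm,
               separate_ter$per_replicate$tertiary_rpm)
})
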