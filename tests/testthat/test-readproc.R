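mk_read <- function(seq, qual = strrep("I", nchar(seq)), id = "r1") {
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming obeys the length window and overlap rule", {
  insert30 <- strrep("AC", 15)
  r <- mk_read(paste0("AAAA", insert30, "CCCC", ADAPTER))
  out <- trim_adapter(r, ADAPTER)
  expect_equal(out$n_kept, 1)           # 4+30+4 = 38 = max_len
  expect_equal(nchar(out$kept$seq), 38)
  expect_equal(nchar(out$kept$qual), 38)

  # trimmed length 25 -> below -m 26 -> discarded
  r25 <- mk_read(paste0(strrep("A", 25), ADAPTER))
  expect_equal(trim_adapter(r25, ADAPTER)$n_discarded, 1)

  # no adapter, length 38 -> retained unchanged
  r38 <- mk_read(strrep("AC", 19))
  out38 <- trim_adapter(r38, ADAPTER)
  expect_equal(out38$kept$seq, r38$seq)

  # partial terminal adapter: only >= min_overlap prefixes count
  r_part <- mk_read(paste0(strrep("A", 30), substr(ADAPTER, 1, 5)))
  expect_equal(nchar(trim_adapter(r_part, ADAPTER)$kept$seq), 30)
  r_short_ovl <- mk_read(paste0(strrep("A", 30), substr(ADAPTER, 1, 4)))
  expect_equal(nchar(trim_adapter(r_short_ovl, ADAPTER)$kept$seq), 34)

  # leftmost match across multiple adapters wins
  a2 <- "AGATCGGAAGAGCACACGTCT"
  r2 <- mk_read(paste0(strrep("C", 26), a2, strrep("G", 3), ADAPTER))
  out2 <- trim_adapter(r2, c(ADAPTER, a2))
  expect_equal(nchar(out2$kept$seq), 26)
})

test_that("quality filter is strict at pct = 100", {
  good <- mk_read(strrep("A", 30))
  expect_equal(quality_filter(good)$n_kept, 1)
  oneback <- mk_read(strrep("A", 30),
                     qual = paste0(strrep("I", 29), "3"))  # Q18 < 20
  expect_equal(quality_filter(oneback)$n_discarded, 1)
  # Q19 char is '4'; boundary just below threshold
  q19 <- mk_read("ACGT", qual = "III4")
  expect_equal(quality_filter(q19)$n_kept, 0)
  q20 <- mk_read("ACGT", qual = "III5")
  expect_equal(quality_filter(q20)$n_kept, 1)
  empty <- mk_read("")
  expect_equal(quality_filter(empty)$n_discarded, 1)
  # relaxed pct keeps reads with a tolerated fraction below threshold
  expect_equal(quality_filter(oneback, pct = 90)$n_kept, 1)
})

test_that("UMI collapse keys on the full sequence and keeps first order", {
  r <- rbind(mk_read("AAAACCCCGGGG", id = "a"),
             mk_read("TTTTCCCCGGGG", id = "b"),
             mk_read("AAAACCCCGGGG", id = "c"),
             mk_read("AAAACCCCGGGG", id = "d"))
  out <- collapse_umi_duplicates(r)
  expect_equal(out$kept$id, c("a", "b"))
  expect_equal(out$kept$copies, c(3L, 1L))
  # same insert, different UMIs -> distinct molecules survive
  r2 <- rbind(mk_read("AAAACCCCGGGG", id = "a"),
              mk_read("TGCACCCCGGGG", id = "b"))
  expect_equal(collapse_umi_duplicates(r2)$n_kept, 2)
})

test_that("collapse equals a hash-count oracle on random input", {
  set.seed(9)
  seqs <- sample(random_inserts(40, 20, 24), 300, replace = TRUE)
  r <- data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
                  qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
  out <- collapse_umi_duplicates(r)$kept
  oracle <- table(seqs)
  expect_setequal(out$seq, names(oracle))
  expect_equal(out$copies[match(names(oracle), out$seq)],
               as.integer(oracle))
})

test_that("insert extraction trims UMIs and applies the length floor", {
  r26 <- mk_read(strrep("ACGT", 6), id = "x")  # 24 nt -> 16-nt insert
  out <- extract_insert(mk_read(paste0("AAAA", strrep("C", 18), "GGGG")))
  expect_equal(out$kept$insert, strrep("C", 18))
  expect_equal(out$kept$umi5, "AAAA")
  expect_equal(out$kept$umi3, "GGGG")
  # 22-nt read -> 14-nt insert -> discarded
  out14 <- extract_insert(mk_read(paste0("AAAA", strrep("C", 14), "GGGG")))
  expect_equal(out14$n_discarded, 1)
  # shorter than both UMIs -> discard, counted
  expect_equal(extract_insert(mk_read("ACGTAC"))$n_discarded, 1)
})

test_that("the five-stage pipeline conserves reads and keeps its order", {
  sim <- tiny_sim()
  r <- sim$reads[[1]]
  res <- process_reads(r, default_adapters())
  rep <- res$report
  expect_true(all(rep$n_in == rep$n_kept + rep$n_discarded))
  expect_equal(rep$n_in[1], nrow(r))
  expect_equal(rep$n_in[-1], rep$n_kept[-nrow(rep)])
  # permuting collapse and UMI-trim changes the result on shared inserts:
  # two molecules with the same insert but different UMIs must survive the
  # correct order, and would merge under the wrong one
  two_mol <- rbind(
    mk_read(paste0("AAAA", strrep("C", 20), "GGGG"), id = "m1"),
    mk_read(paste0("TTTT", strrep("C", 20), "CCCC"), id = "m2")
  )
  right <- extract_insert(collapse_umi_duplicates(two_mol)$kept)
  expect_equal(nrow(right$kept), 2)
  # collapsing after UMI removal would wrongly merge the two molecules
  ins <- extract_insert(two_mol)$kept$insert
  expect_equal(length(unique(ins)), 1)
})

test_that("processing is idempotent on clean processed-like reads", {
  r <- mk_read(strrep("AGCT", 8))   # 32 nt, no adapter, all Q40
  once <- trim_adapter(r, default_adapters())
  expect_equal(once$kept$seq, r$seq)
  twice <- trim_adapter(once$kept, default_adapters())
  expect_equal(twice$kept, once$kept)
  qf <- quality_filter(once$kept)
  expect_equal(qf$kept$seq, r$seq)
})

test_that("collapse recovers the pre-duplication molecule multiset", {
  sim <- tiny_sim()
  for (s in names(sim$reads)[1]) {
    res <- process_reads(sim$reads[[s]], default_adapters())
    truth <- sim$truth[sim$truth$sample_id == s, ]
    surviving <- truth[!truth$low_quality & !duplicated(truth$molecule_id), ]
    expect_equal(nrow(res$processed), nrow(surviving))
    expect_setequal(paste(res$processed$umi5, res$processed$insert,
                          res$processed$umi3),
                    paste(surviving$umi5, surviving$insert, surviving$umi3))
    # per-read UMIs equal the simulated UMIs
    m <- match(res$processed$id, truth$read_id)
    expect_equal(res$processed$umi5, truth$umi5[m])
    expect_equal(res$processed$umi3, truth$umi3[m])
    expect_equal(res$processed$insert, truth$insert[m])
  }
})

test_that("fastq round trip preserves sequence and quality", {
  r <- rbind(mk_read("ACGTACGTACGTACG", id = "q1"),
             mk_read("GGGGTTTTCCCCAAA", qual = strrep("5", 15), id = "q2"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(r, f)
  back <- read_fastq(f)
  expect_equal(back$seq, r$seq)
  expect_equal(back$qual, r$qual)
  expect_equal(back$id, r$id)
})
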