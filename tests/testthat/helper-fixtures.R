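# Shared small fixtures, built once per session and reused across files.
.fixture_env <- new.env(parent = emptyenv())

tiny_cfg <- function(...) {
  defaults <- list(seed = 42L, n_genes = 20L, gene_length_bp = 600L,
                   n_structural = 4L, n_mirna_loci = 6L, n_pirna_loci = 10L,
                   n_target_sites = 5L, contig_length = 40000L,
                   reads_per_sample = 3000L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

tiny_ref <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- make_reference(tiny_cfg())
  .fixture_env$ref
}

tiny_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_reads(tiny_cfg(), tiny_ref())
  }
  .fixture_env$sim
}

default_adapters <- function() {
  c("TGGAATTCTCGGGTGCCAAGG", "AGATCGGAAGAGCACACGTCT")
}

# Pure-R brute-force exact matcher: every occurrence of insert or its
# reverse complement over all contigs; independent of the package's mapper.
brute_force_hits <- function(insert, genome_strings) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(insert, "")[[1]]),
                                     collapse = ""))
  out <- list()
  for (contig in names(genome_strings)) {
    s <- genome_strings[[contig]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") insert else rc
      hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
      # gregexpr misses overlapping occurrences; rescan from each hit + 1
      pos <- integer(0)
      from <- 1L
      repeat {
        h <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
        if (h < 0) break
        pos <- c(pos, from + h - 1L)
        from <- from + h
      }
      if (length(pos)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = pos - 1L,
          end = pos - 1L + nchar(insert), strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

random_inserts <- function(n, min_len = 15, max_len = 30) {
  vapply(sample(min_len:max_len, n, replace = TRUE), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}
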