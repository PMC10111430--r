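test_that("minimal dialect parses count rows and validates them", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tstrand\tcontext\tmeth_reads\ttotal_reads",
               "4\t2524803\t+\tCHH\t4\t13",
               "4\t100\t-\tCG\t0\t0"), tf)
  rec <- read_count_table(tf, dialect = "minimal")
  expect_equal(nrow(rec), 2)
  target <- rec[rec$pos == 2524803, ]
  expect_equal(target$meth_reads, 4L)
  expect_equal(target$unmeth_reads, 9L)
  expect_equal(target$strand, "+")
  # zero-coverage rows are retained; the coverage rule filters later
  expect_equal(rec$meth_reads[rec$pos == 100], 0L)
  expect_equal(rec$unmeth_reads[rec$pos == 100], 0L)

  writeLines("chrom\tpos\tstrand\tcontext\tmeth_reads\ttotal_reads", tf)
  expect_equal(nrow(read_count_table(tf)), 0)

  writeLines(c("chrom\tpos\tstrand\tcontext\tmeth_reads\ttotal_reads",
               "1\t5\t+\tCG\t7\t3"), tf)
  expect_error(read_count_table(tf), "line 2.*total_reads < meth_reads")

  writeLines(c("chrom\tpos\tstrand\tcontext\tmeth_reads\ttotal_reads",
               "1\t5\t+\tCG\t1\t4",
               "1\t5\t+\tCG\t2\t4"), tf)
  expect_error(read_count_table(tf), "duplicate")

  writeLines(c("chrom\tpos\tstrand\tcontext\tmeth_reads\ttotal_reads",
               "1\t5\t+\tCG\t1\t4",
               "1\t6\t+\tCG\tx\t4"), tf)
  expect_error(read_count_table(tf), "line 3")
})

test_that("methratio dialect maps C/CT counts and honours eff_CT", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chr", "pos", "strand", "context", "ratio",
                     "eff_CT_count", "C_count", "CT_count", sep = "\t"),
               "chr1\t10\t+\tCHH\t0.25\t11.6\t3\t12",
               "chr1\t20\t-\tCG\t0.0\t8.0\t0\t8"), tf)
  rec <- read_count_table(tf, dialect = "methratio")
  expect_equal(rec$meth_reads, c(3L, 0L))
  expect_equal(rec$unmeth_reads, c(9L, 8L))
  rec2 <- read_count_table(tf, dialect = "methratio", use_eff_ct = TRUE)
  expect_equal(rec2$unmeth_reads, c(9L, 8L))  # round(11.6) = 12
})

test_that("count tables and call TSVs round-trip losslessly", {
  for (seed in 1:3) {
    rec <- unique(random_records(60, seed = seed))
    rec <- rec[!duplicated(rec[c("chrom", "pos", "strand")]), ]
    rec <- rec[order(rec$chrom, rec$pos, rec$strand), ]
    rownames(rec) <- NULL
    tf <- withr::local_tempfile(fileext = ".tsv")
    write_count_table(rec, tf)
    expect_equal(read_count_table(tf), rec)
  }
  # calls round-trip through write_calls/read_calls with annotations
  rec <- random_records(40, seed = 9)
  rec <- rec[!duplicated(rec[c("chrom", "pos", "strand")]), ]
  calls <- call_methylation(rec, list(failure_prob = 0.005))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, tf, format = "tsv")
  back <- read_calls(tf)
  expect_equal(back$meth_reads, calls$meth_reads)
  expect_equal(back$unmeth_reads, calls$unmeth_reads)
  expect_equal(back$significant, calls$significant)
  expect_equal(back$ci_lower, calls$ci_lower, tolerance = 1e-12)
})

test_that("context assignment matches a 3-mer extraction oracle", {
  sim <- simulate_genome(sim_config(n_chrom = 1, chrom_length = 4000,
                                    n_palindromes = 2, seed = 5))
  sites <- cytosine_sites(sim$genome)
  chars <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  oracle <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$pos[i]
    if (sites$strand[i] == "+") {
      if (p + 2 > length(chars)) return("unknown")
      tri <- chars[p:(p + 2)]
    } else {
      if (p - 2 < 1) return("unknown")
      tri <- unname(comp[chars[p:(p - 2)]])
    }
    if (tri[2] == "G") "CG" else if (tri[3] == "G") "CHG" else "CHH"
  }, character(1))
  expect_equal(sites$context, oracle)
  got <- assign_context(sim$genome, "chr1", sites$pos, sites$strand)
  expect_equal(got, oracle)
})

test_that("context handles strand reading and contract violations", {
  g <- Biostrings::DNAStringSet(c(chrA = "AACGTACAGATTGAA"))
  expect_equal(assign_context(g, "chrA", 3, "+"), "CG")    # C G T
  expect_equal(assign_context(g, "chrA", 7, "+"), "CHG")   # C A G
  # minus-strand cytosine under plus-strand TTG reads 5'-CAA-3'
  expect_equal(assign_context(g, "chrA", 13, "-"), "CHH")
  expect_error(assign_context(g, "chrA", 1, "+"), "not a cytosine")
  expect_error(assign_context(g, "chrA", 3, "-"), "not a cytosine")
  # within 2 bp of the contig end
  g2 <- Biostrings::DNAStringSet(c(chrB = "AGTTTTTTGCA"))
  expect_equal(assign_context(g2, "chrB", 2, "-"), "unknown")
  expect_equal(assign_context(g2, "chrB", 10, "+"), "unknown")
})

test_that("gc_window is site-inclusive, strand-agnostic and truncates", {
  at <- paste(rep("AT", 300), collapse = "")
  gcseq <- paste(rep("GC", 300), collapse = "")
  mixed <- strsplit(at, "")[[1]]
  mixed[101:134] <- "G"   # 34 G+C inside the 201-bp window around pos 150
  g <- Biostrings::DNAStringSet(c(
    at = at, gc = gcseq, mixed = paste(mixed, collapse = "")))
  expect_equal(gc_window(g, "at", 150), 0)
  expect_equal(gc_window(g, "gc", 150), 100)
  expect_equal(round(gc_window(g, "mixed", 150), 2), 16.92)  # 34/201
  # window has no strand: mirrored site on the reverse complement matches
  rc <- Biostrings::reverseComplement(g["mixed"])
  names(rc) <- "mixed_rc"
  expect_equal(gc_window(rc, "mixed_rc", 600 - 150 + 1),
               gc_window(g, "mixed", 150))
  expect_warning(v <- gc_window(g, "at", 30), "truncated")
  expect_equal(v, 0)
})

test_that("BED export converts to 0-based half-open coordinates", {
  calls <- data.frame(chrom = "chr4", pos = 2524803L, strand = "+",
                      context = "CHH", meth_reads = 4L, unmeth_reads = 9L,
                      ratio = 4 / 13)
  tf <- withr::local_tempfile(fileext = ".bed")
  write_calls(calls, tf, format = "bed")
  bed <- utils::read.delim(tf, header = FALSE)
  expect_equal(bed$V2, 2524802)
  expect_equal(bed$V3, 2524803)
  # empty call set -> header-only TSV that reads back empty
  empty <- calls[0, ]
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_calls(empty, tf2, format = "tsv")
  expect_equal(nrow(read_count_table(tf2)), 0)
})
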