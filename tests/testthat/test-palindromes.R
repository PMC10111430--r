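test_that("finder agrees with the interval-major oracle on random DNA", {
  set.seed(31)
  params <- list(c(19, 8, 10), c(10, 4, 3), c(16, 5, 6), c(30, 9, 0))
  for (i in 1:25) {
    seq <- random_dna(400, gc = 0.23)
    p <- params[[(i %% length(params)) + 1]]
    got <- find_palindromes(seq, min_length = p[1], min_arm = p[2],
                            max_loop = p[3])
    exp <- oracle_palindromes(seq, min_len = p[1], min_arm = p[2],
                              max_loop = p[3])
    expect_equal(got[c("start", "end", "arm_len", "loop_len")], exp,
                 ignore_attr = TRUE)
  }
})

test_that("toy sequences produce the expected structures", {
  one <- find_palindromes("AAAAAAAACGTTTTTTTTT")
  expect_equal(nrow(one), 1)
  expect_equal(one$total_len, 19L)
  expect_equal(2 * one$arm_len + one$loop_len, one$total_len)
  # a homopolymer has no reverse-complement match at all
  expect_equal(nrow(find_palindromes(strrep("A", 200))), 0)
  expect_equal(nrow(find_palindromes("ACGTACGTACGTACGTAC")), 0)  # < 19 bp
  expect_error(find_palindromes("ACGT", min_length = 10, min_arm = 8),
               "configuration error")
  expect_error(find_palindromes("ACGT", mismatches = 1), "exact-arm")
})

test_that("reported arms verify the reverse-complement identity", {
  sim <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 15000,
                                    n_palindromes = 4, seed = 33))
  pals <- find_palindromes(sim$genome)
  expect_gt(nrow(pals), 0)
  for (i in seq_len(nrow(pals))) {
    s <- Biostrings::subseq(sim$genome[[pals$chrom[i]]],
                            pals$start[i], pals$end[i])
    a <- pals$arm_len[i]
    left <- Biostrings::subseq(s, 1, a)
    right <- Biostrings::subseq(s, length(s) - a + 1, length(s))
    expect_equal(as.character(right),
                 as.character(Biostrings::reverseComplement(left)))
  }
  # every planted palindrome is recovered (possibly extended outward when
  # flanking background bases happen to pair)
  truth <- sim$truth$palindromes
  for (i in seq_len(nrow(truth))) {
    covering <- pals$chrom == truth$chrom[i] &
      pals$start <= truth$start[i] & pals$end >= truth$end[i]
    expect_true(any(covering))
  }
})

test_that("nested removal keeps only outermost structures", {
  pals <- data.frame(chrom = "c1", start = c(100L, 110L),
                     end = c(150L, 130L), arm_len = c(10L, 5L),
                     loop_len = c(31L, 11L), total_len = c(51L, 21L))
  expect_equal(remove_nested(pals)$start, 100L)
  pals2 <- data.frame(chrom = "c1", start = c(100L, 140L),
                      end = c(150L, 190L), arm_len = 10L, loop_len = 31L,
                      total_len = 51L)
  expect_equal(nrow(remove_nested(pals2)), 2)  # overlap without containment
  set.seed(34)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    start <- sample(500, n, replace = TRUE)
    len <- sample(10:100, n, replace = TRUE)
    rand <- data.frame(chrom = sample(c("a", "b"), n, replace = TRUE),
                       start = start, end = start + len,
                       arm_len = 2L, loop_len = 0L, total_len = len + 1L)
    got <- remove_nested(rand)
    exp <- nested_oracle(rand[order(rand$chrom, rand$start, -rand$end), ])
    sort_df <- function(d) {
      d <- d[order(d$chrom, d$start, d$end), c("chrom", "start", "end")]
      rownames(d) <- NULL
      d
    }
    expect_equal(sort_df(got), sort_df(exp), ignore_attr = TRUE)
  }
})

test_that("length quantiles summarise overall and per chromosome", {
  single <- data.frame(chrom = "c1", start = 1L, end = 19L, arm_len = 9L,
                       loop_len = 1L, total_len = 19L)
  q <- length_quantiles(single)
  expect_true(all(q$overall == 19))
  many <- data.frame(chrom = "c1", start = 1, end = 2, arm_len = 2,
                     loop_len = 0, total_len = 19:80)
  expect_equal(unname(length_quantiles(many)$overall["50%"]), 49.5)
  expect_equal(length(length_quantiles(many[0, ])$overall), 0)
})

test_that("sites are classified stem, loop or outside correctly", {
  # palindrome [101, 140]: arms 15 bp, loop 10 bp at [116, 125]
  pal <- data.frame(chrom = "c1", start = 101L, end = 140L, arm_len = 15L,
                    loop_len = 10L, total_len = 40L)
  sites <- data.frame(chrom = "c1",
                      pos = c(101L, 115L, 116L, 125L, 126L, 140L, 141L, 50L),
                      strand = "+")
  ann <- annotate_sites(sites, pal)
  expect_equal(ann$status, c("stem", "stem", "loop", "loop", "stem",
                             "stem", "outside", "outside"))
  expect_true(all(is.na(ann$palindrome[ann$status == "outside"])))
  # a site in two palindromes is assigned to the longer one
  pal2 <- rbind(pal, data.frame(chrom = "c1", start = 130L, end = 199L,
                                arm_len = 30L, loop_len = 10L,
                                total_len = 70L))
  ann2 <- annotate_sites(data.frame(chrom = "c1", pos = 135L, strand = "+"),
                         pal2)
  expect_equal(ann2$palindrome, 2L)
})

test_that("overlap table reports 0% and 100% extremes by stringency", {
  sites <- data.frame(chrom = "c1", pos = c(110L, 120L, 130L),
                      strand = "+")
  sets <- list(a = call_set_of(sites), b = call_set_of(sites))
  pal <- data.frame(chrom = "c1", start = 101L, end = 140L, arm_len = 15L,
                    loop_len = 10L, total_len = 40L)
  tab <- overlap_stringency_table(sets, pal)
  expect_equal(tab$percent, 100)
  none <- overlap_stringency_table(sets, pal[0, ])
  expect_equal(none$percent, 0)
  expect_equal(none$common_mC, 3)
})
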