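test_that("n50 agrees with a brute-force scan on random multisets", {
  n50_brute <- function(x) {
    cand <- sort(unique(x), decreasing = TRUE)
    for (L in cand) if (sum(x[x >= L]) >= sum(x) / 2) return(L)
  }
  expect_equal(n50(10), 10)
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(rep(7, 13)), 7)
  set.seed(123)
  for (i in 1:1000) {
    x <- sample.int(1e5, sample(1:40, 1), replace = TRUE)
    expect_identical(n50(x), n50_brute(x))
  }
  expect_error(n50(numeric(0)), "empty")
})

test_that("contiguity is the longest-contig percentage", {
  expect_equal(contiguity(123), 100)
  expect_equal(contiguity(c(600, 400)), 60)
  expect_equal(contiguity(c(5, 5)), 50)
  expect_error(contiguity(numeric(0)), "empty")
})

test_that("qscore follows the Phred convention with a zero-error cap", {
  expect_equal(qscore(1, 0, 0, 1e4), 40)           # 1e-4 error -> Q40
  expect_equal(qscore(0, 0, 0, 1e4), 90)           # cap
  expect_equal(qscore(133, 0, 0, 1000), -10 * log10(0.133))
  expect_equal(qscore(133, 0, 0, 1000), 8.76, tolerance = 0.01)
  # strictly decreasing in error count; exact powers of ten
  for (N in 1:6) expect_equal(qscore(10^(6 - N), 0, 0, 1e6), 10 * N)
  expect_error(qscore(1, 0, 0, 0), "positive")
})

test_that("alignment blocks: identity, full-length, and absence", {
  ref <- c(R = rand_dna(10000, 71))
  # exact copy -> one full-length block at identity 1
  b <- align_to_reference(c(m = ref[["R"]]), ref)
  expect_equal(nrow(b), 1L)
  expect_equal(b$qstart, 0)
  expect_equal(b$qend, 10000)
  expect_equal(b$identity, 1)
  # 1% substitutions -> one block, identity ~0.99 (known by construction)
  m <- mutated_copy(ref[["R"]], 0.01, seed = 72)
  b2 <- align_to_reference(c(m = as.character(m)), ref)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$identity, attr(m, "identity"), tolerance = 0.002)
  expect_gt(b2$qend - b2$qstart, 9900)
  # reverse-complement contig maps on the minus strand over the full length
  b3 <- align_to_reference(c(m = revcomp(ref[["R"]])), ref)
  expect_equal(b3$strand, -1)
  expect_equal(b3$qend - b3$qstart, 10000)
  # unrelated contig -> no blocks
  b4 <- align_to_reference(c(x = rand_dna(10000, 73)), ref)
  expect_equal(nrow(b4), 0L)
})

test_that("AGF and purity match exhaustive per-base truth labeling", {
  ref <- c(R = rand_dna(40000, 81))
  # contig built from two disjoint reference pieces + 3 kb foreign sequence
  p1 <- substr(ref[["R"]], 1, 15000)
  p2 <- substr(ref[["R"]], 22001, 34000)
  foreign <- rand_dna(3000, 82)
  mag <- contig_set(c("c1", "c2", "c3"), c(p1, p2, foreign))
  blocks <- align_to_reference(mag, ref)
  agf <- aligned_genome_fraction(blocks, nchar(ref[["R"]]))
  # truth labeling: covered reference bases = 15000 + 12000
  expect_equal(agf, 100 * 27000 / 40000, tolerance = 0.1)
  unaligned <- hcbha:::contig_unaligned(blocks,
                                        stats::setNames(nchar(mag$seq),
                                                        mag$id))
  expect_equal(unaligned, 3000, tolerance = 60)
  expect_equal(purity(unaligned, 40000), 1 - 3000 / 40000, tolerance = 0.01)
  # clamp and degenerate cases
  expect_equal(purity(50000, 40000), 0)
  expect_error(purity(0, 0), "positive")
  expect_equal(aligned_genome_fraction(blocks[0, ], 40000), 0)
  # union arithmetic on overlapping blocks
  fake <- data.frame(rstart = c(0, 3000), rend = c(5000, 8000))
  expect_equal(aligned_genome_fraction(fake, 10000), 80)
})

test_that("misassembly breakpoints: colinear clean, translocation caught", {
  ref_lens <- c(R = 100000)
  colinear <- data.frame(contig = "c", ref = "R", strand = c(1, 1),
                         qstart = c(0, 5100), qend = c(5000, 10000),
                         rstart = c(0, 5150), rend = c(5000, 10050))
  expect_equal(misassembly_count(colinear, ref_lens), 0L)
  # halves mapping 50 kb apart
  trans <- data.frame(contig = "c", ref = "R", strand = c(1, 1),
                      qstart = c(0, 5000), qend = c(5000, 10000),
                      rstart = c(0, 55000), rend = c(5000, 60000))
  expect_equal(misassembly_count(trans, ref_lens), 1L)
  # strand flip counts
  inv <- trans
  inv$strand <- c(1, -1)
  inv$rstart <- c(0, 5000); inv$rend <- c(5000, 10000)
  expect_equal(misassembly_count(inv, ref_lens), 1L)
  # a rotated circular assembly wrapping the origin is not a misassembly
  wrap <- data.frame(contig = "c", ref = "R", strand = c(1, 1),
                     qstart = c(0, 60000), qend = c(60000, 100000),
                     rstart = c(40000, 0), rend = c(100000, 40000))
  expect_equal(misassembly_count(wrap, c(R = 100000), c(R = TRUE)), 0L)
  expect_equal(misassembly_count(wrap, c(R = 100000), c(R = FALSE)), 1L)
})

test_that("evaluate_mags assigns best references and summarizes", {
  refs <- list(genomes = c(A = rand_dna(20000, 91), B = rand_dna(20000, 92)),
               circular = c(A = FALSE, B = FALSE))
  mags <- list(mA = contig_set("c1", refs$genomes[["A"]]),
               mB = contig_set(c("c1", "c2"),
                               c(substr(refs$genomes[["B"]], 1, 9000),
                                 substr(refs$genomes[["B"]], 9501, 20000))))
  rep <- evaluate_mags(mags, refs)
  expect_equal(rep$ref, c("A", "B"))
  expect_equal(rep$agf[1], 100)
  expect_equal(rep$purity, c(1, 1))
  expect_equal(rep$qscore[1], 90)                  # exact copy hits the cap
  expect_equal(rep$n_contigs, c(1, 2))
  s <- attr(rep, "summary")
  expect_equal(s$mean_purity, 1)
  expect_equal(s$mean_agf, mean(rep$agf))
  expect_equal(nrow(evaluate_mags(list(), refs)), 0L)
})
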