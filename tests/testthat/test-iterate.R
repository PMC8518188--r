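qr <- function(compl, contam, n = 1, ...) {
  quality_record(compl, contam, n, ...)
}

test_that("qualified gate uses strict >90 / <10 / <30 bounds", {
  expect_true(is_qualified(qr(91, 9, 29)))
  expect_false(is_qualified(qr(90, 5, 10)))    # completeness must exceed 90
  expect_false(is_qualified(qr(95, 10, 10)))   # contamination must be < 10
  expect_false(is_qualified(qr(95, 5, 30)))    # contig count must be < 30
  expect_true(is_qualified(qr(90.01, 9.99, 29)))
})

test_that("retention gate uses strict >50 / <10 bounds", {
  expect_true(retain_filter(qr(51, 9.9)))
  expect_false(retain_filter(qr(50, 5)))
  expect_false(retain_filter(qr(99, 10)))
})

test_that("tier classification follows the MIMAG-style rules", {
  expect_equal(classify_tier(qr(85, 0, 1, circular_all = TRUE)), "complete")
  expect_equal(classify_tier(qr(92, 4, 3, rrna_full = TRUE)), "HQ")
  expect_equal(classify_tier(qr(92, 4, 3, rrna_full = FALSE)), "MQ")
  expect_equal(classify_tier(qr(90, 5, 3, rrna_full = TRUE)), "HQ")
  expect_equal(classify_tier(qr(50, 10, 3)), "MQ")
  expect_equal(classify_tier(qr(49.9, 2, 3)), "failed")
  expect_equal(classify_tier(qr(60, 10.1, 3)), "failed")
})

test_that("stop rule fires below 2% qualified abundance or at max_iter", {
  st <- list(qualified_abundance = 0.019, iteration = 3)
  expect_true(should_stop(st))
  st$qualified_abundance <- 0.020
  expect_false(should_stop(st))                 # strict <
  st$iteration <- 11
  expect_true(should_stop(st))                  # iteration cap
})

test_that("relative abundance is consumed bases over total bases", {
  rb <- stats::setNames(rep(100, 10), sprintf("r%d", 1:10))
  mags <- list(list(consumed_read_ids = sprintf("r%d", 1:3)),
               list(consumed_read_ids = sprintf("r%d", 4:5)),
               list(consumed_read_ids = character()))
  ab <- relative_abundance(mags, 1000, rb)
  expect_equal(ab, c(0.3, 0.2, 0))
  all_cons <- list(list(consumed_read_ids = names(rb)))
  expect_equal(relative_abundance(all_cons, 1000, rb), 1)
})

test_that("sketch ANI matches the construction identity of mutated pairs", {
  g <- rand_dna(20000, 31)
  expect_equal(estimate_ani(g, g)$ani, 1)
  expect_equal(estimate_ani(g, g)$coverage, 1)
  for (rate in c(0.01, 0.05)) {
    m <- mutated_copy(g, rate, seed = 100 + rate * 1000)
    id_true <- attr(m, "identity")
    est <- estimate_ani(g, m)
    expect_lt(abs(est$ani - id_true), 0.01)
  }
  # unrelated genomes
  g2 <- rand_dna(20000, 32)
  expect_lte(estimate_ani(g, g2)$ani, 0.8)
  expect_lt(estimate_ani(g, g2)$coverage, 0.05)
})

fake_mag <- function(id, seqs, compl = 95, contam = 1, n50v = 1e5) {
  list(id = id,
       contigs = contig_set(paste0(id, "_c", seq_along(seqs)), seqs),
       quality = quality_record(compl, contam, length(seqs), n50 = n50v),
       tier = "HQ", iteration = 1L, consumed_read_ids = character(),
       relative_abundance = 0)
}

test_that("dereplication collapses duplicates, keeps 0.95-ANI pair, idempotent", {
  g <- rand_dna(25000, 41)
  g95 <- mutated_copy(g, 0.05, seed = 42)       # same primary, new secondary
  gu <- rand_dna(25000, 43)                     # unrelated
  mags <- list(a = fake_mag("a", g, compl = 96),
               b = fake_mag("b", g, compl = 90),  # duplicate of a
               c = fake_mag("c", g95),
               d = fake_mag("d", gu))
  out <- dereplicate(unname(mags))
  ids <- vapply(out, `[[`, character(1), "id")
  expect_true("a" %in% ids)                     # higher score than b
  expect_false("b" %in% ids)                    # duplicate collapsed
  expect_true("c" %in% ids)                     # distinct secondary cluster
  expect_true("d" %in% ids)                     # unrelated retained
  out2 <- dereplicate(out)
  expect_equal(vapply(out2, `[[`, character(1), "id"), ids)  # idempotent
})

test_that("reference-mode quality assessment does base-count arithmetic", {
  fx <- list(genomes = c(A = rand_dna(30000, 51), B = rand_dna(30000, 52)),
             circular = c(A = FALSE, B = FALSE))
  # exact copy
  mag <- contig_set("m1", fx$genomes[["A"]])
  q <- assess_quality(mag, fx)
  expect_equal(q$completeness, 100)
  expect_equal(q$contamination, 0)
  expect_equal(attr(q, "ref"), "A")
  # 90% of A plus a 5% contig of B
  mag2 <- contig_set(c("m1", "m2"),
                     c(substr(fx$genomes[["A"]], 1, 27000),
                       substr(fx$genomes[["B"]], 1, 1500)))
  q2 <- assess_quality(mag2, fx)
  expect_equal(q2$completeness, 90, tolerance = 0.01)
  expect_equal(q2$contamination, 100 * 1500 / 28500, tolerance = 0.05)
  expect_error(assess_quality(contig_set(), fx), "empty")
})

test_that("planted marker locus drives the rRNA flag", {
  cm <- generate_community(community_spec(1, c(20000, 20000), seed = 61))
  g <- cm$truth$genomes[[1]]
  q_full <- assess_quality(contig_set("m", g), cm$truth)
  expect_true(q_full$rrna_full)
  # remove the marker region: flag must drop
  mk <- cm$truth$marker[[1]]
  at <- regexpr(mk, g, fixed = TRUE)
  no_mk <- paste0(substr(g, 1, at - 1),
                  substr(g, at + nchar(mk), nchar(g)))
  q_cut <- assess_quality(contig_set("m", no_mk), cm$truth)
  expect_false(q_cut$rrna_full)
})

test_that("subtract_reads is exact set arithmetic and order-preserving", {
  rs <- read_set(sprintf("r%04d", 1:1000),
                 rep(strrep("ACGT", 100), 1000), platform = "long")
  consumed <- sprintf("r%04d", sample(1:1000, 400))
  out <- subtract_reads(rs, consumed)
  expect_equal(length(out), 600L)
  expect_false(any(out$id %in% consumed))
  expect_identical(out$id, setdiff(rs$id, consumed))  # order preserved
  expect_identical(subtract_reads(rs, character())$id, rs$id)
  expect_equal(length(subtract_reads(rs, rs$id)), 0L)
  # disjoint subtractions commute
  s1 <- sprintf("r%04d", 1:100); s2 <- sprintf("r%04d", 500:600)
  expect_identical(subtract_reads(subtract_reads(rs, s1), s2)$id,
                   subtract_reads(subtract_reads(rs, s2), s1)$id)
})
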