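test_that("single read assembles to itself", {
  r <- read_set("r1", rand_dna(5000, 1), platform = "long")
  out <- mini_olc_assemble(r)
  expect_equal(nrow(out), 1L)
  expect_equal(out$seq, r$seq)
  expect_error(mini_olc_assemble(read_set(platform = "long")), "no long reads")
})

test_that("error-free tiling reads reconstruct a linear genome", {
  g <- rand_dna(20000, 2)
  rs <- tiling_reads(g, 5000, 250)           # 20x depth
  out <- mini_olc_assemble(rs)
  expect_equal(nrow(out), 1L)
  # exact reconstruction up to the genome sequence
  expect_equal(out$seq, g)
  expect_false(out$circular)
})

test_that("circular genome yields one circular contig, exact up to rotation", {
  g <- rand_dna(20000, 3)
  rs <- tiling_reads(g, 5000, 250, circular = TRUE)
  out <- mini_olc_assemble(rs)
  expect_equal(nrow(out), 1L)
  expect_true(out$circular)
  expect_equal(nchar(out$seq), nchar(g), tolerance = 0.01)
  # containment in the doubled genome checks rotation-exactness
  expect_true(grepl(out$seq, paste0(g, g), fixed = TRUE) ||
                grepl(revcomp(out$seq), paste0(g, g), fixed = TRUE))
})

test_that("assembly of error-prone reads reaches high identity vs truth", {
  fx <- sim_fixture(1, c(20000, 20000), ani = NULL, long_depth = 30,
                    short_depth = 0.1, seed = 400)
  out <- mini_olc_assemble(fx$long)
  expect_lte(nrow(out), 2L)
  ev <- evaluate_mags(list(m = out), fx$truth)
  expect_gte(ev$agf[1], 99)
  expect_gte(ev$qscore[1], 13)   # long-read-only consensus accuracy
})

test_that("short-read polishing corrects planted errors and is idempotent", {
  g <- rand_dna(10000, 5)
  draft <- as.character(mutated_copy(g, 0.05, seed = 6))
  set.seed(7)
  starts <- sample(nchar(g) - 250, 2000, replace = TRUE)    # 50x
  short <- read_set(sprintf("s%04d", seq_along(starts)),
                    substring(g, starts, starts + 249), platform = "short")
  pol <- polish_with_short_reads(draft, short, rounds = 2)
  loc <- hcbha:::cpp_locate_prefix(pol, g)
  expect_gte(1 - loc$edits / nchar(g), 0.999)
  # idempotence on clean input
  pol2 <- polish_with_short_reads(g, short, rounds = 1)
  expect_identical(pol2, g)
  # no coverage -> unchanged with a warning
  far <- read_set("f", rand_dna(250, 8), platform = "short")
  expect_warning(out <- polish_with_short_reads(draft, far, rounds = 1),
                 "anchored")
  expect_identical(out, draft)
})

test_that("polishing is non-decreasing in identity on mutated drafts", {
  g <- rand_dna(8000, 9)
  set.seed(10)
  starts <- sample(nchar(g) - 250, 1000, replace = TRUE)
  short <- read_set(sprintf("s%04d", seq_along(starts)),
                    substring(g, starts, starts + 249), platform = "short")
  for (seed in 11:13) {
    draft <- as.character(mutated_copy(g, 0.03, seed = seed))
    id0 <- 1 - hcbha:::cpp_locate_prefix(draft, g)$edits / nchar(g)
    pol <- polish_with_short_reads(draft, short, rounds = 1)
    id1 <- 1 - hcbha:::cpp_locate_prefix(pol, g)$edits / nchar(g)
    expect_gte(id1, id0)
  }
})

test_that("contig-end bridging merges a split genome and never lowers N50", {
  g <- rand_dna(30000, 14)
  # two polished halves with a 150 bp gap between them
  contigs <- contig_set(c("left", "right"),
                        c(substr(g, 1, 14000), substr(g, 14151, 30000)))
  # error-free bridging reads spanning the junction
  set.seed(15)
  starts <- seq(11000, 13800, by = 400)
  bridge <- read_set(sprintf("b%02d", seq_along(starts)),
                     substring(g, starts, starts + 5999), platform = "long")
  out <- improve_contiguity(contigs, bridge, min_bridges = 3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$seq, g)
  expect_gte(n50(nchar(out$seq)), n50(nchar(contigs$seq)))
  # without bridging reads the input is unchanged
  none <- read_set("x", rand_dna(6000, 16), platform = "long")
  expect_equal(improve_contiguity(contigs, none)$seq, contigs$seq)
})

test_that("bin promotion drops coverage and composition outliers", {
  g <- rand_dna(40000, 17)
  main <- contig_set(c("a", "b"),
                     c(substr(g, 1, 20000), substr(g, 20001, 40000)))
  # contaminant: distinct composition, low coverage
  contam <- contig_set("z", paste(rep(strrep("ACC", 1), 4000), collapse = ""))
  cs <- rbind(main, contam)
  class(cs) <- c("ContigSet", "data.frame")
  reads <- tiling_reads(g, 4000, 130)          # ~30x on the real genome only
  pr <- promote_bin(cs, reads)
  expect_setequal(pr$contigs$id, c("a", "b"))
  expect_equal(pr$dropped$id, "z")             # conserved in the dropped pool
  # homogeneous bin unchanged
  pr2 <- promote_bin(main, reads)
  expect_equal(nrow(pr2$dropped), 0L)
  expect_error(promote_bin(contig_set(), reads), "empty")
})

test_that("assemble_bin orchestrates and fails soft on empty bins", {
  fx <- sim_fixture(1, c(20000, 20000), ani = NULL, long_depth = 30,
                    short_depth = 50, seed = 500)
  res <- assemble_bin(fx$long, fx$short)
  expect_equal(res$status, "ok")
  ev <- evaluate_mags(list(m = res$contigs), fx$truth)
  expect_lte(nrow(res$contigs), 2L)
  expect_gte(ev$agf[1], 95)
  # empty bin: failed status, no crash
  empty <- assemble_bin(read_set(platform = "long"),
                        read_set(platform = "short"))
  expect_equal(empty$status, "failed")
  # determinism of the built-in backend
  res2 <- assemble_bin(fx$long, fx$short)
  expect_identical(res$contigs$seq, res2$contigs$seq)
})
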