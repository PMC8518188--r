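test_that("community generation: determinism, sizes, abundances, ANI", {
  spec <- community_spec(4, c(20000, 26000), target_ani = 0.95, seed = 7)
  cm1 <- generate_community(spec)
  cm2 <- generate_community(spec)
  expect_identical(cm1$truth$genomes, cm2$truth$genomes)  # determinism
  expect_equal(sum(cm1$truth$abundance), 1)
  expect_true(all(nchar(cm1$truth$genomes) >= 20000))
  # pairwise identity near the target (substitution-only derivation from a
  # common ancestor; identity ~ (1 - r)^2 with r = (1 - ANI)/2)
  a <- estimate_ani(cm1$truth$genomes[[1]], cm1$truth$genomes[[2]])
  expect_lt(abs(a$ani - 0.95), 0.01)
  # single genome, even abundance
  one <- generate_community(community_spec(1, c(20000, 20000), seed = 1))
  expect_equal(unname(one$truth$abundance), 1)
  expect_error(community_spec(2, c(20000, 25000), target_ani = 0.4),
               "target_ani")
  expect_error(community_spec(1, c(1000, 2000)))
})

test_that("repeats and markers are planted as specified", {
  spec <- community_spec(1, c(20000, 20000), n_repeats = 2, repeat_len = 900,
                         seed = 9)
  cm <- generate_community(spec)
  g <- cm$truth$genomes[[1]]
  expect_equal(nchar(g), 20000 + 2 * 900 + 1500)
  mk <- cm$truth$marker[[1]]
  expect_equal(nchar(mk), 1500)
  expect_true(grepl(mk, g, fixed = TRUE))
  expect_true(cm$truth$rrna_flag[[1]])
})

test_that("long-read simulator: exactness at accuracy 1, floors, truth", {
  cm <- generate_community(community_spec(2, c(20000, 22000), seed = 21))
  lr <- simulate_long_reads(cm$truth, mean_accuracy = 1, depth = 5, seed = 22)
  expect_true(all(nchar(lr$reads$seq) >= 1000))
  g2 <- vapply(cm$truth$genomes, function(g) paste0(g, g), character(1))
  tr <- lr$truth$reads
  for (i in seq_len(min(25, length(lr$reads)))) {
    row <- tr[tr$read_id == lr$reads$id[i], ]
    piece <- substr(g2[[row$genome]], row$start + 1, row$end)
    if (row$strand == "-") piece <- revcomp(piece)
    expect_identical(lr$reads$seq[i], piece)   # truth coordinates are exact
  }
  # determinism
  lr2 <- simulate_long_reads(cm$truth, mean_accuracy = 1, depth = 5, seed = 22)
  expect_identical(lr$reads$seq, lr2$reads$seq)
  expect_error(simulate_long_reads(cm$truth, depth = 0), "depth")
})

test_that("long-read error model hits the planted event rate", {
  cm <- generate_community(community_spec(1, c(30000, 30000), seed = 31))
  lr <- simulate_long_reads(cm$truth, mean_accuracy = 0.867, depth = 70,
                            seed = 32)
  expect_gt(total_bases(lr$reads), 2e6)
  # realign a sample of reads to their true intervals
  g2 <- paste0(cm$truth$genomes[[1]], cm$truth$genomes[[1]])
  tr <- lr$truth$reads
  idx <- seq(1, length(lr$reads), by = 2)
  stats <- vapply(idx, function(i) {
    row <- tr[tr$read_id == lr$reads$id[i], ]
    piece <- substr(g2, row$start + 1, row$end)
    if (row$strand == "-") piece <- revcomp(piece)
    loc <- hcbha:::cpp_locate_prefix(lr$reads$seq[i], piece)
    c(loc$edits, row$end - row$start)
  }, numeric(2))
  acc <- 1 - sum(stats[1, ]) / sum(stats[2, ])
  expect_lt(abs(acc - 0.867), 0.005)
  # abundance-proportional sampling: 0.9/0.1 with equal lengths
  cm2 <- generate_community(community_spec(2, c(20000, 20000), seed = 33))
  cm2$truth$abundance <- c(genome_01 = 0.9, genome_02 = 0.1)
  lr2 <- simulate_long_reads(cm2$truth, depth = 20, seed = 34)
  counts <- table(lr2$truth$reads$genome)
  p <- unname(counts["genome_01"] / sum(counts))
  ci <- qbinom(c(0.005, 0.995), sum(counts), 0.9) / sum(counts)
  expect_gte(p, ci[1])
  expect_lte(p, ci[2])
})

test_that("short-read simulator: pairs, inserts, errors, qualities", {
  cm <- generate_community(community_spec(1, c(20000, 20000), seed = 41))
  sr <- simulate_short_reads(cm$truth, depth = 100, error_rate = 0,
                             seed = 42)
  # depth calibration: total bases within 5% of 2 Mb at 100x on ~21.5 kb
  glen <- nchar(cm$truth$genomes[[1]])
  expect_lt(abs(total_bases(sr$reads) - 100 * glen) / (100 * glen), 0.05)
  expect_true(all(nchar(sr$reads$seq) == 150))
  expect_true(all(sr$reads$mate %in% c("R1", "R2")))
  # error-free reads are exact substrings; FR orientation with the recorded
  # fragment interval
  g2 <- paste0(cm$truth$genomes[[1]], cm$truth$genomes[[1]])
  tr <- sr$truth$reads
  for (i in seq_len(50)) {
    row <- tr[tr$read_id == sr$reads$id[i], ]
    frag <- substr(g2, row$start + 1, row$end)
    if (row$strand == "-") frag <- revcomp(frag)
    exp_seq <- if (sr$reads$mate[i] == "R1") substr(frag, 1, 150)
               else revcomp(substr(frag, nchar(frag) - 149, nchar(frag)))
    expect_identical(sr$reads$seq[i], exp_seq)
  }
  # insert sizes within Normal(350, 50) 99.7% bounds (truncated at 150)
  ins <- tr$end - tr$start
  expect_true(all(ins >= 150))
  expect_gt(mean(ins), 330)
  expect_lt(mean(ins), 370)
  # realized error rate matches the requested rate; mean quality passes the
  # >= Q30 preprocessing filter
  sre <- simulate_short_reads(cm$truth, depth = 50, error_rate = 0.003,
                              seed = 43)
  nsub <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                          strsplit(b, "")[[1]]),
                     sre$reads$seq[1:2000],
                     vapply(1:2000, function(i) {
                       row <- sre$truth$reads[
                         sre$truth$reads$read_id == sre$reads$id[i], ]
                       frag <- substr(g2, row$start + 1, row$end)
                       if (row$strand == "-") frag <- revcomp(frag)
                       if (sre$reads$mate[i] == "R1") substr(frag, 1, 150)
                       else revcomp(substr(frag, nchar(frag) - 149,
                                           nchar(frag)))
                     }, character(1))))
  rate <- nsub / (2000 * 150)
  expect_lt(abs(rate - 0.003), 0.001)
  expect_gt(mean(mean_phred(sre$reads)), 30)
})

test_that("simulated coverage tracks abundance across genomes", {
  spec <- community_spec(3, c(20000, 20000), abundance = "lognormal",
                         ab_sigma = 1, seed = 51)
  cm <- generate_community(spec)
  lr <- simulate_long_reads(cm$truth, depth = 25, seed = 52)
  bases <- tapply(lr$truth$reads$end - lr$truth$reads$start,
                  lr$truth$reads$genome, sum)
  glens <- nchar(cm$truth$genomes)[names(bases)]
  w <- cm$truth$abundance[names(bases)] * glens
  expect_gt(cor(as.numeric(bases), as.numeric(w)), 0.98)
})

test_that("simulated datasets round-trip through the on-disk layout", {
  cm <- generate_community(community_spec(2, c(20000, 21000), seed = 61))
  lr <- simulate_long_reads(cm$truth, depth = 2, seed = 62)
  sr <- simulate_short_reads(lr$truth, depth = 2, seed = 63)
  dir <- withr::local_tempdir()
  write_simulated(sr$truth, lr$reads, sr$reads, dir)
  expect_equal(parse_fasta(file.path(dir, "genomes.fasta")),
               sr$truth$genomes)
  back <- parse_fastq(file.path(dir, "long.fastq.gz"), "long")
  expect_equal(back$seq, lr$reads$seq)
  r1 <- parse_fastq(file.path(dir, "short_R1.fastq.gz"), "short")
  expect_true(all(r1$mate == "R1"))
  tt <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_setequal(tt$read_id, c(lr$reads$id, sr$reads$id))
  ab <- read.table(file.path(dir, "abundances.tsv"), header = TRUE,
                   sep = "\t")
  expect_equal(sum(ab$abundance), 1)
  # the bundled command-line front end parses cleanly
  cli <- system.file("cli", "hcbha", package = "hcbha")
  expect_true(nzchar(cli))
  expect_no_error(parse(cli))
})
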