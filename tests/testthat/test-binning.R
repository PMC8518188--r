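test_that("tnf_profile matches hand-enumerated cases and symmetry", {
  v <- tnf_profile("AAAA")
  expect_equal(sum(v), 1)
  expect_equal(unname(v[["AAAA"]]), 1)
  # reverse-complement symmetry on random sequence
  s <- rand_dna(5000, 10)
  expect_equal(tnf_profile(s), tnf_profile(revcomp(s)))
  # periodic sequence: windows cycle over ACGT, CGTA, GTAC, TACG, which
  # collapse to 3 canonical keys (TACG is the reverse complement of CGTA)
  p <- strrep("ACGT", 10)
  vp <- tnf_profile(p)
  expect_equal(sum(vp > 0), 3)
  expect_equal(unname(vp[["ACGT"]] + vp[["CGTA"]] + vp[["GTAC"]]), 1)
  expect_error(tnf_profile("ACG"), "shorter")
  # N windows are skipped
  vn <- tnf_profile("AANAA")
  expect_equal(sum(vn), 0)
})

test_that("feature matrix z-scores columns and weights coverage", {
  cs <- contig_set(c("a", "b"), c(rand_dna(5000, 1), rand_dna(5000, 1)),
                   coverage = c(10, 1000))
  prof <- composition_profiles(cs)
  f0 <- build_feature_matrix(prof, cov_weight = 0)
  expect_equal(unname(f0[, "cov"]), c(0, 0))
  # identical TNF -> all TNF features zero after z-scoring, distance driven
  # by the coverage term only
  f3 <- build_feature_matrix(prof, cov_weight = 3)
  d <- dist(f3)
  expect_equal(as.numeric(d), sqrt(sum((f3[1, ] - f3[2, ])^2)))
  expect_gt(as.numeric(d), 3)  # dominated by the weighted coverage column
  # singleton profile gives an all-zero row
  f1 <- build_feature_matrix(composition_profiles(cs[1, ]))
  expect_true(all(f1 == 0))
})

test_that("dendrogram cut separates well-separated clouds; permutation-stable", {
  set.seed(3)
  f <- rbind(matrix(rnorm(50, 0, .1), 10), matrix(rnorm(50, 8, .1), 10))
  rownames(f) <- sprintf("c%02d", 1:20)
  hc <- hierarchical_cluster(f)
  expect_gt(max(hc$height), 10 * sort(hc$height, decreasing = TRUE)[2])
  cl <- cutree(hc, k = 2)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  # permuting rows changes labels but not the induced partition
  p <- sample(20)
  hcp <- hierarchical_cluster(f[p, ])
  clp <- cutree(hcp, k = 2)[rownames(f)]
  expect_equal(length(unique(paste(cl, clp))), 2L)
  expect_error(hierarchical_cluster(matrix(c(1, NA), 1)), "non-finite")
})

test_that("cut_to_bins partitions contigs and pools small clusters", {
  cs <- contig_set(sprintf("c%d", 1:4),
                   c(rand_dna(30000, 1), rand_dna(30000, 2),
                     rand_dna(30000, 3), rand_dna(800, 4)),
                   coverage = c(30, 30, 500, 30))
  prof <- composition_profiles(cs)
  f <- build_feature_matrix(prof)
  hc <- hierarchical_cluster(f)
  bins <- cut_to_bins(hc, cs, f, k = 4, min_bin_bases = 10000)
  ids <- sort(unlist(lapply(bins, `[[`, "contig_ids")))
  expect_equal(ids, sort(cs$id))                      # partition property
  lo <- bins[[length(bins)]]
  expect_true(is_leftover(lo))
  expect_equal(lo$contig_ids, "c4")                   # small cluster pooled
  expect_error(cut_to_bins(hc, cs, f, k = 9), "exceeds")
  # height cut above the root keeps one bin
  b1 <- cut_to_bins(hc, cs, f, h = max(hc$height) + 1, min_bin_bases = 1000)
  expect_equal(length(b1), 1L)
})

test_that("amend_bins returns a planted-wrong contig and conserves the set", {
  # two genomes with distinct composition, several contigs each; plant one
  # contig in the wrong bin
  set.seed(21)
  g1 <- hcbha:::random_dna(60000, gc = 0.35)
  g2 <- hcbha:::random_dna(60000, gc = 0.62)
  cut_up <- function(g, pre) {
    starts <- seq(1, 50001, by = 10000)
    contig_set(sprintf("%s_%d", pre, seq_along(starts)),
               substring(g, starts, starts + 9999), coverage = 30)
  }
  cs <- rbind(cut_up(g1, "a"), cut_up(g2, "b"))
  class(cs) <- c("ContigSet", "data.frame")
  prof <- composition_profiles(cs)
  f <- build_feature_matrix(prof, cov_weight = 0)
  truth_bin <- substr(cs$id, 1, 1)
  wrong <- list(
    list(bin_id = "bin_01", contig_ids = c(cs$id[truth_bin == "a"], "b_1"),
         centroid = NULL, long_read_ids = character(),
         short_read_ids = character()),
    list(bin_id = "bin_02",
         contig_ids = setdiff(cs$id[truth_bin == "b"], "b_1"),
         centroid = NULL, long_read_ids = character(),
         short_read_ids = character()))
  for (i in 1:2) {
    wrong[[i]]$centroid <- colMeans(f[wrong[[i]]$contig_ids, , drop = FALSE])
  }
  fixed <- amend_bins(wrong, f)
  got <- vapply(fixed, function(b) "b_1" %in% b$contig_ids, logical(1))
  expect_true(got[2] && !got[1])                      # returned to its bin
  expect_setequal(unlist(lapply(fixed, `[[`, "contig_ids")), cs$id)
  # a clean clustering is a fixpoint
  clean <- amend_bins(fixed, f)
  expect_identical(lapply(clean, `[[`, "contig_ids"),
                   lapply(fixed, `[[`, "contig_ids"))
})

test_that("binning recovers simulated genomes (adjusted Rand index)", {
  skip_if_not_installed("mclust")
  # contigs cut from 3 unrelated genomes at distinct coverages
  set.seed(77)
  aris <- vapply(1:5, function(s) {
    cm <- generate_community(community_spec(3, c(60000, 60000),
                                            marker_len = 100,
                                            seed = 700 + s))
    gs <- as.list(unname(cm$truth$genomes))
    covs <- c(20, 60, 200)
    cs <- do.call(rbind, lapply(1:3, function(i) {
      starts <- seq(1, 50001, by = 12000)
      contig_set(sprintf("g%d_%d", i, seq_along(starts)),
                 substring(gs[[i]], starts, starts + 11999),
                 coverage = covs[i] * exp(rnorm(length(starts), 0, 0.1)))
    }))
    class(cs) <- c("ContigSet", "data.frame")
    bn <- bin_contigs(cs, min_bin_bases = 10000)
    lab <- rep(NA_integer_, nrow(cs))
    for (bi in seq_along(bn$bins)) {
      lab[match(bn$bins[[bi]]$contig_ids, cs$id)] <- bi
    }
    truth_lab <- as.integer(substr(cs$id, 2, 2))
    mclust::adjustedRandIndex(lab, truth_lab)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})
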