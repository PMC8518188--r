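# Composition/coverage binning of draft contigs into candidate haplotype
# bins: canonical tetranucleotide frequencies plus weighted log-coverage,
# average-linkage hierarchical clustering, a merge-height-gap cut, and a
# centroid-reassignment amendment pass.

#' Canonical tetranucleotide frequency profile of a contig
#'
#' Counts every 4-mer together with its reverse complement as one canonical
#' key (136 keys); windows containing N are skipped; counts are normalized to
#' frequencies.
#'
#' @param seq a contig sequence (length >= 4).
#' @return named numeric vector of length 136 summing to 1 (all zero when the
#'   contig has no valid 4-mer window).
#' @export
tnf_profile <- function(seq) {
  if (nchar(seq) < 4) stop("contig shorter than 4 bp has no tetranucleotides")
  v <- cpp_tnf(seq)
  names(v) <- cpp_tnf_labels()
  s <- sum(v)
  if (s > 0) v <- v / s
  v
}

#' Composition profiles for a contig table
#' @param contigs a ContigSet.
#' @return list with `tnf` (n x 136 matrix) and `log_cov` (log(coverage + 1)).
#' @export
composition_profiles <- function(contigs) {
  tnf <- t(vapply(contigs$seq, tnf_profile, numeric(136), USE.NAMES = FALSE))
  rownames(tnf) <- contigs$id
  list(tnf = tnf, log_cov = stats::setNames(log(contigs$coverage + 1),
                                            contigs$id))
}

#' Build the clustering feature matrix
#'
#' TNF columns are z-scored across contigs; log-coverage is z-scored and
#' multiplied by `cov_weight`. Zero-variance columns stay at 0.
#'
#' @param profiles output of [composition_profiles()].
#' @param cov_weight weight of the coverage feature (default 3).
#' @return numeric feature matrix (rows = contigs, input order).
#' @export
build_feature_matrix <- function(profiles, cov_weight = 3) {
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  tnf <- apply(profiles$tnf, 2, zscore)
  if (is.null(dim(tnf))) tnf <- matrix(tnf, nrow = 1)
  cov <- zscore(profiles$log_cov) * cov_weight
  f <- cbind(tnf, cov = cov)
  rownames(f) <- rownames(profiles$tnf)
  f
}

#' Agglomerative clustering of contig features
#'
#' @param features feature matrix from [build_feature_matrix()].
#' @param linkage hclust method (default `"average"`).
#' @param metric distance metric (default `"euclidean"`).
#' @return an `hclust` dendrogram (`NULL` for a single row).
#' @export
hierarchical_cluster <- function(features, linkage = "average",
                                 metric = "euclidean") {
  if (any(!is.finite(features))) stop("non-finite values in feature matrix")
  if (nrow(features) < 2) return(NULL)
  hclust(dist(features, method = metric), method = linkage)
}

# choose k by the largest gap between consecutive merge heights
gap_cut_k <- function(hc) {
  h <- hc$height
  n <- length(h) + 1
  if (n <= 2) return(if (max(h) > 0) 2 else 1)
  gaps <- diff(h)
  if (!length(gaps) || max(gaps) <= 0) return(1)
  i <- which.max(gaps)
  n - i
}

#' Cut a dendrogram into candidate bins
#'
#' Default mode cuts at the largest merge-height gap; `h` or `k` override.
#' Clusters whose total contig length is below `min_bin_bases` are pooled
#' into a reserved `"leftover"` bin that is excluded from assembly but kept
#' for later iterations.
#'
#' @param hc dendrogram from [hierarchical_cluster()] (or NULL for 1 contig).
#' @param contigs the ContigSet that was clustered (same order as features).
#' @param features feature matrix (for bin centroids).
#' @param h,k optional cut height / cluster count (k overrides h overrides
#'   the gap heuristic).
#' @param min_bin_bases minimum bin size in bp (default 50000).
#' @return list of `CandidateBin`s: `bin_id`, `contig_ids`, `centroid`,
#'   `long_read_ids`, `short_read_ids`; the leftover bin (if any) is last.
#' @export
cut_to_bins <- function(hc, contigs, features, h = NULL, k = NULL,
                        min_bin_bases = 50000) {
  n <- nrow(contigs)
  if (!is.null(k) && k > n) stop("k exceeds the number of contigs")
  if (is.null(hc)) {
    cl <- rep(1L, n)
  } else if (!is.null(k)) {
    cl <- cutree(hc, k = k)
  } else if (!is.null(h)) {
    cl <- cutree(hc, h = h)
  } else {
    cl <- cutree(hc, k = gap_cut_k(hc))
  }
  make_bins(cl, contigs, features, min_bin_bases)
}

make_bins <- function(cl, contigs, features, min_bin_bases) {
  bins <- list()
  leftover <- character()
  for (g in sort(unique(cl))) {
    ids <- contigs$id[cl == g]
    tot <- sum(nchar(contigs$seq[cl == g]))
    if (tot < min_bin_bases) {
      leftover <- c(leftover, ids)
    } else {
      rows <- match(ids, rownames(features))
      centroid <- colMeans(features[rows, , drop = FALSE])
      bins[[length(bins) + 1]] <- list(
        bin_id = sprintf("bin_%02d", length(bins) + 1),
        contig_ids = ids, centroid = centroid,
        long_read_ids = character(), short_read_ids = character())
    }
  }
  if (length(leftover)) {
    bins[[length(bins) + 1]] <- list(bin_id = "leftover",
                                     contig_ids = leftover, centroid = NULL,
                                     long_read_ids = character(),
                                     short_read_ids = character())
  }
  bins
}

is_leftover <- function(b) identical(b$bin_id, "leftover")

#' Amend bins by centroid reassignment
#'
#' Each contig moves to the bin with the nearest centroid when that distance
#' is below `(1 - margin)` times the distance to its current centroid;
#' repeated to a fixpoint or 10 rounds. The leftover bin does not take part.
#' The contig set is conserved.
#'
#' @param bins bins from [cut_to_bins()].
#' @param features feature matrix with rownames = contig ids.
#' @param margin reassignment hysteresis (default 0.1).
#' @return amended bins (empty real bins dropped).
#' @export
amend_bins <- function(bins, features, margin = 0.1) {
  real <- !vapply(bins, is_leftover, logical(1))
  if (sum(real) < 2) return(bins)
  for (round in 1:10) {
    centroids <- t(vapply(bins[real], function(b) b$centroid,
                          numeric(ncol(features))))
    moved <- FALSE
    assign <- lapply(bins, function(b) character())
    ridx <- which(real)
    for (bi in ridx) {
      for (cid in bins[[bi]]$contig_ids) {
        f <- features[cid, ]
        d <- sqrt(colSums((t(centroids) - f)^2))
        cur <- match(bi, ridx)
        best <- which.min(d)
        to <- bi
        if (best != cur && d[best] < (1 - margin) * d[cur]) {
          to <- ridx[best]
          moved <- TRUE
        }
        assign[[to]] <- c(assign[[to]], cid)
      }
    }
    for (bi in ridx) bins[[bi]]$contig_ids <- assign[[bi]]
    # refresh centroids of non-empty bins
    for (bi in ridx) {
      ids <- bins[[bi]]$contig_ids
      if (length(ids)) {
        bins[[bi]]$centroid <- colMeans(features[ids, , drop = FALSE])
      }
    }
    if (!moved) break
  }
  keep <- vapply(bins, function(b) is_leftover(b) || length(b$contig_ids) > 0,
                 logical(1))
  bins[keep]
}

#' Bin a contig table end to end
#'
#' Convenience wrapper: profiles, features, clustering, gap cut, amendment.
#'
#' @param contigs a ContigSet.
#' @param cov_weight coverage feature weight.
#' @param min_bin_bases minimum bin size (bp).
#' @param linkage,metric clustering parameters.
#' @param k optional fixed number of clusters.
#' @return list with `bins` and `features`.
#' @export
bin_contigs <- function(contigs, cov_weight = 3, min_bin_bases = 50000,
                        linkage = "average", metric = "euclidean", k = NULL) {
  prof <- composition_profiles(contigs)
  feats <- build_feature_matrix(prof, cov_weight)
  hc <- hierarchical_cluster(feats, linkage, metric)
  bins <- cut_to_bins(hc, contigs, feats, k = k,
                      min_bin_bases = min_bin_bases)
  bins <- amend_bins(bins, feats)
  list(bins = bins, features = feats)
}
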