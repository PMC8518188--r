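# Read phasing: assign long reads and short-read pairs to candidate bins by
# shared canonical minimizers, and subtract consumed reads between iterations.

#' Build a minimizer index over candidate bins
#'
#' Canonical (strand-symmetric) `(k, w)` minimizers of every contig are
#' indexed with their bin (and contig) of origin.
#'
#' @param bins list of CandidateBins (the leftover bin is skipped).
#' @param contigs ContigSet holding the bins' contig sequences.
#' @param k k-mer size (odd, default 15).
#' @param w window size (default 10).
#' @return a `MinimizerIndex`: sorted hash/bin/contig/pos columns plus bin ids.
#' @export
build_minimizer_index <- function(bins, contigs, k = 15, w = 10) {
  if (k %% 2 == 0) stop("k must be odd")
  real <- bins[!vapply(bins, is_leftover, logical(1))]
  if (!length(real)) stop("no non-leftover bins to index")
  hash <- numeric(); bin <- integer(); contig <- character(); pos <- integer()
  for (bi in seq_along(real)) {
    for (cid in real[[bi]]$contig_ids) {
      s <- contigs$seq[match(cid, contigs$id)]
      if (nchar(s) < k) next
      m <- cpp_minimizers(s, k, w)
      hash <- c(hash, m$hash)
      bin <- c(bin, rep(bi, nrow(m)))
      contig <- c(contig, rep(cid, nrow(m)))
      pos <- c(pos, m$pos)
    }
  }
  if (!length(hash)) stop("contigs shorter than k; nothing to index")
  # one entry per (hash, bin) for scoring; contig/pos kept for provenance
  o <- order(hash, bin, pos)
  hash <- hash[o]; bin <- bin[o]; contig <- contig[o]; pos <- pos[o]
  keep <- !duplicated(paste(hash, bin))
  structure(list(k = k, w = w,
                 hash = hash[keep], bin = bin[keep],
                 contig = contig[keep], pos = pos[keep],
                 bin_ids = vapply(real, function(b) b$bin_id, character(1))),
            class = "MinimizerIndex")
}

pair_stem <- function(id) sub("/[12]$", "", id)

#' Phase reads to candidate bins
#'
#' Each read (short-read mates jointly: scores are summed over the pair)
#' counts its distinct canonical minimizers shared with every bin and is
#' assigned to the top bin iff `score >= min_score` and
#' `runner_up <= tie_ratio * score`; otherwise it stays unassigned (exact
#' ties are never assigned).
#'
#' @param rs a ReadSet.
#' @param idx a [build_minimizer_index()] index.
#' @param min_score minimum shared-minimizer count (default 3).
#' @param tie_ratio maximum runner-up/best ratio (default 0.8).
#' @param min_score_frac additionally require `score` to reach this fraction
#'   of the read's (pair's) own minimizer count; an identity proxy that keeps
#'   reads of genomes without a bin from being absorbed by a related bin
#'   (default 0: off).
#' @return data.frame `read_id`, `bin_id` (NA when unassigned), `score`,
#'   `runner_up`.
#' @export
assign_reads <- function(rs, idx, min_score = 3, tie_ratio = 0.8,
                         min_score_frac = 0) {
  if (!length(rs)) {
    return(data.frame(read_id = character(), bin_id = character(),
                      score = integer(), runner_up = integer(),
                      stringsAsFactors = FALSE))
  }
  grp_key <- if (rs$platform == "short") pair_stem(rs$id) else rs$id
  grp <- as.integer(factor(grp_key, levels = unique(grp_key)))
  res <- cpp_assign_minimizers(rs$seq, grp, idx$hash, idx$bin, idx$k, idx$w,
                               length(idx$bin_ids))
  assigned <- res$bin > 0 & res$score >= min_score &
    res$score >= min_score_frac * res$n_min &
    res$runner_up <= tie_ratio * res$score
  bin_id <- ifelse(assigned, idx$bin_ids[pmax(res$bin, 1)], NA_character_)
  data.frame(read_id = rs$id, bin_id = bin_id[grp],
             score = res$score[grp], runner_up = res$runner_up[grp],
             stringsAsFactors = FALSE)
}

#' Remove consumed reads from a ReadSet
#'
#' Ids not present in `rs` are ignored. Order is preserved.
#'
#' @param rs a ReadSet.
#' @param consumed_ids character vector of read ids to remove.
#' @return a ReadSet with `length(rs) - |consumed in rs|` reads.
#' @export
subtract_reads <- function(rs, consumed_ids) {
  if (!length(consumed_ids) || !length(rs)) return(rs)
  rs_subset(rs, !(rs$id %in% consumed_ids))
}
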