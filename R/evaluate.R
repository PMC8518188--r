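# Reference-based appraisal: contig-to-reference alignment blocks and the
# derived metrics (aligned genome fraction, purity, misassembly and indel
# rates, assembly Q-scores, N50, contiguity).

# split colinear anchor hits into chains; breaks at large gaps or diagonal
# jumps. hits: data.frame(qpos, rpos) sorted by qpos, single strand.
chain_hits <- function(qpos, rpos, gap_threshold = 1000) {
  n <- length(qpos)
  if (!n) return(list())
  chains <- list()
  cq <- qpos[1]; cr <- rpos[1]
  qs <- c(cq); rs <- c(cr)
  for (i in seq_len(n)[-1]) {
    dq <- qpos[i] - cq; dr <- rpos[i] - cr
    if (dq > 0 && dr > 0 &&
        dq <= gap_threshold && dr <= gap_threshold &&
        abs(dq - dr) <= 0.3 * max(dq, dr) + 100) {
      qs <- c(qs, qpos[i]); rs <- c(rs, rpos[i])
      cq <- qpos[i]; cr <- rpos[i]
    } else if (qpos[i] > cq) {
      chains[[length(chains) + 1]] <- list(qpos = qs, rpos = rs)
      qs <- c(qpos[i]); rs <- c(rpos[i])
      cq <- qpos[i]; cr <- rpos[i]
    }
  }
  chains[[length(chains) + 1]] <- list(qpos = qs, rpos = rs)
  chains
}

#' Align contigs to reference genomes
#'
#' Unique `k`-mer anchors are seeded per (contig, reference, strand), chained
#' colinearly (chains break at gaps or diagonal jumps beyond
#' `gap_threshold`), and each chain is scored by banded alignment of the
#' inter-anchor gaps with end extension. Blocks with identity >=
#' `min_identity` and length >= `min_block` are reported.
#'
#' @param contigs a ContigSet (or named character vector).
#' @param refs named character vector of reference genome sequences.
#' @param k anchor k-mer size (default 21).
#' @param min_block minimum block length on the contig (bp, default 500).
#' @param min_identity minimum block identity (default 0.9).
#' @param gap_threshold chain break distance (bp, default 1000).
#' @return data.frame of alignment blocks: contig, ref, strand, qstart, qend,
#'   rstart, rend (0-based half-open), matches, mismatches, insertions,
#'   deletions, identity, length.
#' @export
align_to_reference <- function(contigs, refs, k = 21, min_block = 500,
                               min_identity = 0.9, gap_threshold = 1000) {
  if (inherits(contigs, "ContigSet")) {
    cs <- stats::setNames(contigs$seq, contigs$id)
  } else cs <- contigs
  out <- list()
  for (ci in seq_along(cs)) {
    qseq <- cs[[ci]]
    for (ri in seq_along(refs)) {
      hits <- cpp_anchor_hits(qseq, refs[[ri]], k)
      if (!nrow(hits)) next
      for (s in c(1, -1)) {
        h <- hits[hits$strand == s, , drop = FALSE]
        if (!nrow(h)) next
        if (s == 1) {
          q <- qseq
          qp <- h$qpos
        } else {
          q <- cpp_revcomp(qseq)
          qp <- nchar(qseq) - k - h$qpos
        }
        o <- order(qp)
        qp <- qp[o]; rp <- h$rpos[o]
        for (ch in chain_hits(qp, rp, gap_threshold)) {
          if (length(ch$qpos) * k < 50) next  # too little exact support
          st <- tryCatch(
            cpp_chain_stats(q, refs[[ri]], ch$qpos, ch$rpos, as.integer(k),
                            30L),
            error = function(e) NULL)
          if (is.null(st)) next
          alen <- st$matches + st$mismatches + st$deletions
          ident <- st$matches /
            max(1, st$matches + st$mismatches + st$insertions + st$deletions)
          blen <- st$qend - st$qstart
          if (ident < min_identity || blen < min_block) next
          qstart <- st$qstart; qend <- st$qend
          if (s == -1) { # map back to forward contig coordinates
            L <- nchar(qseq)
            tmp <- qstart
            qstart <- L - qend
            qend <- L - tmp
          }
          out[[length(out) + 1]] <- data.frame(
            contig = names(cs)[ci], ref = names(refs)[ri], strand = s,
            qstart = qstart, qend = qend, rstart = st$rstart, rend = st$rend,
            matches = st$matches, mismatches = st$mismatches,
            insertions = st$insertions, deletions = st$deletions,
            identity = ident, length = blen, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), ref = character(),
                      strand = integer(), qstart = integer(),
                      qend = integer(), rstart = integer(), rend = integer(),
                      matches = numeric(), mismatches = numeric(),
                      insertions = numeric(), deletions = numeric(),
                      identity = numeric(), length = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# union length of intervals on a (possibly circular) reference of length L
union_ref_bases <- function(rstart, rend, L, circular = FALSE) {
  if (!length(rstart)) return(0)
  iv <- cbind(pmax(0, rstart), pmin(rend, if (circular) 2 * L else L))
  if (circular) {
    # fold intervals onto [0, L)
    folded <- list()
    for (i in seq_len(nrow(iv))) {
      a <- iv[i, 1]; b <- iv[i, 2]
      if (b <= L) folded[[length(folded) + 1]] <- c(a, b)
      else {
        folded[[length(folded) + 1]] <- c(a, L)
        folded[[length(folded) + 1]] <- c(0, min(b - L, L))
      }
    }
    iv <- do.call(rbind, folded)
  }
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (!nrow(iv)) return(0)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; lo <- iv[1, 1]; hi <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] > hi) { tot <- tot + hi - lo; lo <- iv[i, 1]; hi <- iv[i, 2] }
    else hi <- max(hi, iv[i, 2])
  }
  tot + hi - lo
}

#' Aligned genome fraction
#'
#' Percent of the reference covered by at least one alignment block
#' (interval union; circular references fold coordinates modulo length).
#'
#' @param blocks alignment blocks against one reference.
#' @param ref_len reference length (bp).
#' @param circular is the reference a closed replicon.
#' @return percent in \[0, 100\].
#' @export
aligned_genome_fraction <- function(blocks, ref_len, circular = FALSE) {
  100 * union_ref_bases(blocks$rstart, blocks$rend, ref_len, circular) /
    ref_len
}

#' Assembly purity
#'
#' `1 - unaligned_bp / ref_len`, floored at 0: the fraction of the reference
#' length not offset by assembled sequence that aligns nowhere.
#'
#' @param unaligned_bp MAG bases covered by no alignment block.
#' @param ref_len reference genome length (> 0).
#' @return fraction in \[0, 1\].
#' @export
purity <- function(unaligned_bp, ref_len) {
  if (ref_len <= 0) stop("reference length must be positive")
  max(0, 1 - unaligned_bp / ref_len)
}

# per-contig unaligned bases given that contig's blocks
contig_unaligned <- function(blocks, contig_lens) {
  tot <- 0
  for (cid in names(contig_lens)) {
    b <- blocks[blocks$contig == cid, , drop = FALSE]
    cov <- union_ref_bases(b$qstart, b$qend, contig_lens[[cid]])
    tot <- tot + contig_lens[[cid]] - cov
  }
  tot
}

#' Count misassembly breakpoints
#'
#' One breakpoint between consecutive blocks of a contig (ordered along the
#' contig) that map to different references, different strands, or with a
#' reference gap/overlap beyond `gap_threshold` (computed on the circle for
#' circular references).
#'
#' @param blocks alignment blocks (possibly several contigs).
#' @param ref_lens named reference lengths.
#' @param ref_circular named logical circularity flags.
#' @param gap_threshold QUAST-style distance threshold (bp, default 1000).
#' @return integer breakpoint count.
#' @export
misassembly_count <- function(blocks, ref_lens, ref_circular = NULL,
                              gap_threshold = 1000) {
  if (!nrow(blocks)) return(0L)
  if (is.null(ref_circular)) {
    ref_circular <- stats::setNames(rep(FALSE, length(ref_lens)),
                                    names(ref_lens))
  }
  n <- 0L
  for (cid in unique(blocks$contig)) {
    b <- blocks[blocks$contig == cid, , drop = FALSE]
    b <- b[order(b$qstart), , drop = FALSE]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      b1 <- b[i, ]; b2 <- b[i + 1, ]
      if (b1$ref != b2$ref || b1$strand != b2$strand) { n <- n + 1L; next }
      qgap <- b2$qstart - b1$qend
      rgap <- if (b1$strand == 1) b2$rstart - b1$rend
              else b1$rstart - b2$rend
      L <- ref_lens[[b1$ref]]
      if (isTRUE(ref_circular[[b1$ref]])) {
        rgap <- ((rgap + L / 2) %% L) - L / 2  # signed distance on the circle
      }
      if (abs(rgap - qgap) > gap_threshold) n <- n + 1L
    }
  }
  n
}

#' Assembly quality score (Phred scale)
#'
#' `Q = -10 log10((mismatches + insertions + deletions) / aligned)`, capped
#' at `cap` when there are zero errors.
#'
#' @param mismatches,insertions,deletions error counts (bp).
#' @param aligned aligned bases (> 0).
#' @param cap Q ceiling for error-free assemblies (default 90).
#' @return numeric Phred score.
#' @export
qscore <- function(mismatches, insertions, deletions, aligned, cap = 90) {
  if (aligned <= 0) stop("aligned bases must be positive")
  err <- mismatches + insertions + deletions
  if (err <= 0) return(cap)
  min(cap, -10 * log10(err / aligned))
}

#' N50 of contig lengths
#' @param lengths numeric vector of contig lengths (non-empty).
#' @return the largest L such that contigs >= L sum to at least half the
#'   total.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Contiguity: the longest contig as a percentage of the assembly
#' @param lengths numeric vector of contig lengths (non-empty).
#' @return percent in (0, 100].
#' @export
contiguity <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  100 * max(lengths) / sum(lengths)
}

#' Evaluate MAGs against truth genomes
#'
#' Per MAG: best reference (maximal aligned bases; ties broken by reference
#' id), aligned genome fraction, purity, misassembly and indel rates,
#' Q-score, N50, contiguity and contig count, plus a `summary` attribute with
#' mean AGF, mean purity and median Q.
#'
#' @param mags named list of ContigSets (one per MAG).
#' @param truth truth table from [generate_community()] (genomes and
#'   circularity), or a named character vector of reference sequences.
#' @param gap_threshold misassembly distance threshold (bp).
#' @return data.frame with one row per MAG (attribute `"summary"` holds the
#'   cohort means/medians).
#' @export
evaluate_mags <- function(mags, truth, gap_threshold = 1000) {
  if (is.character(truth)) {
    truth <- list(genomes = truth,
                  circular = stats::setNames(rep(FALSE, length(truth)),
                                             names(truth)))
  }
  refs <- truth$genomes
  ref_lens <- stats::setNames(nchar(refs), names(refs))
  rows <- list()
  for (mi in seq_along(mags)) {
    mag <- mags[[mi]]
    mag_id <- names(mags)[mi]
    contig_lens <- stats::setNames(nchar(mag$seq), mag$id)
    blocks <- align_to_reference(mag, refs, gap_threshold = gap_threshold)
    if (nrow(blocks)) {
      ab <- tapply(blocks$qend - blocks$qstart, blocks$ref, sum)
      best <- names(ab)[order(-ab, names(ab))][1]
    } else best <- NA_character_
    if (is.na(best)) {
      rows[[length(rows) + 1]] <- data.frame(
        mag = mag_id, ref = NA_character_, agf = 0, purity = 0,
        misassemblies_per_mb = NA_real_, indels_per_100kb = NA_real_,
        qscore = NA_real_, n50 = n50(contig_lens),
        contiguity = contiguity(contig_lens),
        n_contigs = nrow(mag), total_bp = sum(contig_lens),
        stringsAsFactors = FALSE)
      next
    }
    bb <- blocks[blocks$ref == best, , drop = FALSE]
    agf <- aligned_genome_fraction(bb, ref_lens[[best]],
                                   isTRUE(truth$circular[[best]]))
    unaligned <- contig_unaligned(blocks, contig_lens)
    pur <- purity(unaligned, ref_lens[[best]])
    mis <- misassembly_count(bb, ref_lens, truth$circular, gap_threshold)
    aligned <- sum(bb$matches + bb$mismatches + bb$deletions)
    q <- qscore(sum(bb$mismatches), sum(bb$insertions), sum(bb$deletions),
                aligned)
    indels <- sum(bb$insertions + bb$deletions)
    rows[[length(rows) + 1]] <- data.frame(
      mag = mag_id, ref = best, agf = agf, purity = pur,
      misassemblies_per_mb = mis / (sum(contig_lens) / 1e6),
      indels_per_100kb = indels / (aligned / 1e5),
      qscore = q, n50 = n50(contig_lens),
      contiguity = contiguity(contig_lens),
      n_contigs = nrow(mag), total_bp = sum(contig_lens),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    rep <- data.frame(mag = character(), ref = character(), agf = numeric(),
                      purity = numeric(), misassemblies_per_mb = numeric(),
                      indels_per_100kb = numeric(), qscore = numeric(),
                      n50 = numeric(), contiguity = numeric(),
                      n_contigs = integer(), total_bp = numeric(),
                      stringsAsFactors = FALSE)
    attr(rep, "summary") <- list(mean_agf = NA_real_, mean_purity = NA_real_,
                                 median_q = NA_real_)
    return(rep)
  }
  rep <- do.call(rbind, rows)
  attr(rep, "summary") <- list(mean_agf = mean(rep$agf),
                               mean_purity = mean(rep$purity),
                               median_q = median(rep$qscore, na.rm = TRUE))
  rep
}
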