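# Iteration controller: reference-based quality assessment, the qualified /
# retained / MIMAG-tier gates, read subtraction, the <2% stop rule, sketch
# ANI and dereplication, and the full iterative pipeline driver.

#' Default pipeline configuration
#'
#' Desk-scale defaults for the iterative hybrid assembly pipeline. Values are
#' grouped by stage; everything is overridable by passing a modified copy.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    io = list(min_mean_q = 30, min_long_len = 1000),
    binning = list(cov_weight = 3, min_bin_bases = 10000,
                   linkage = "average", metric = "euclidean"),
    phasing = list(k = 15, w = 10, min_score = 3, tie_ratio = 0.8,
                   min_frac_long = 0.006, min_frac_short = 0.08),
    assembly = list(min_long_reads = 50, min_overlap = 500,
                    min_chain_score = 10, consensus_rounds = 2,
                    polish_rounds = 2, final_polish_rounds = 2,
                    min_bridges = 3, cov_mad_limit = 3.5,
                    tnf_dist_limit = 0.12),
    iterate = list(stop_threshold = 0.02, max_iter = 11,
                   working_long_bases = NULL, working_short_bases = NULL,
                   subtract_frac_long = 0.04, subtract_frac_short = 0.4),
    derep = list(primary_ani = 0.90, secondary_ani = 0.97, min_cov = 0.65)
  )
}

# ---- quality records and gates --------------------------------------------

#' Construct a QualityRecord
#' @param completeness percent in \[0, 100\].
#' @param contamination percent >= 0.
#' @param n_contigs contig count (>= 1).
#' @param n50,total_bp assembly size statistics (bp).
#' @param circular_all all contigs closed/circular.
#' @param rrna_full full-length rRNA-like marker locus recovered.
#' @return list of class `QualityRecord`.
#' @export
quality_record <- function(completeness, contamination, n_contigs,
                           n50 = NA_real_, total_bp = NA_real_,
                           circular_all = FALSE, rrna_full = FALSE) {
  stopifnot(completeness >= 0, completeness <= 100, contamination >= 0,
            n_contigs >= 1)
  structure(list(completeness = completeness, contamination = contamination,
                 n_contigs = n_contigs, n50 = n50, total_bp = total_bp,
                 circular_all = circular_all, rrna_full = rrna_full),
            class = "QualityRecord")
}

#' Does a MAG qualify for read subtraction?
#'
#' Qualified genomes have completeness above 90 percent, contamination below
#' 10 percent and fewer than 30 contigs (all bounds strict).
#'
#' @param q a [quality_record()].
#' @return logical.
#' @export
is_qualified <- function(q) {
  q$completeness > 90 && q$contamination < 10 && q$n_contigs < 30
}

#' Is a MAG retained at the end of an iteration?
#'
#' Retained MAGs have completeness above 50 percent and contamination below
#' 10 percent (strict bounds).
#'
#' @param q a [quality_record()].
#' @return logical.
#' @export
retain_filter <- function(q) {
  q$completeness > 50 && q$contamination < 10
}

#' MIMAG-style tier of a MAG
#'
#' `complete` when every contig is closed/circular (even below 90 percent
#' completeness); else `HQ` at completeness >= 90, contamination <= 5 and a
#' full-length rRNA-like marker; else `MQ` at completeness >= 50 and
#' contamination <= 10; else `failed`.
#'
#' @param q a [quality_record()].
#' @return one of `"complete"`, `"HQ"`, `"MQ"`, `"failed"`.
#' @export
classify_tier <- function(q) {
  if (isTRUE(q$circular_all)) return("complete")
  if (q$completeness >= 90 && q$contamination <= 5 && isTRUE(q$rrna_full)) {
    return("HQ")
  }
  if (q$completeness >= 50 && q$contamination <= 10) return("MQ")
  "failed"
}

#' Reference-based quality assessment of a MAG
#'
#' The built-in estimator for synthetic mode: completeness is the aligned
#' genome fraction of the best-matching truth genome; contamination is
#' 100 x (MAG bases aligning to other truth genomes / total aligned bases);
#' the rRNA-like flag requires the best genome's planted marker locus to be
#' recovered at >= 99 percent identity over >= 95 percent of its length.
#' An external estimator (CheckM-class) can be plugged in wherever a
#' QualityRecord is accepted.
#'
#' @param contigs the MAG's ContigSet (non-empty).
#' @param truth truth table from [generate_community()].
#' @return a [quality_record()] with attribute `"ref"` (best genome id).
#' @export
assess_quality <- function(contigs, truth) {
  if (is.null(contigs) || nrow(contigs) == 0) stop("empty contig set")
  if (is.null(truth$genomes)) stop("reference-mode estimator needs truth genomes")
  refs <- truth$genomes
  blocks <- align_to_reference(contigs, refs)
  lens <- stats::setNames(nchar(contigs$seq), contigs$id)
  if (!nrow(blocks)) {
    q <- quality_record(0, 0, nrow(contigs), n50 = n50(lens),
                        total_bp = sum(lens),
                        circular_all = all(contigs$circular))
    attr(q, "ref") <- NA_character_
    return(q)
  }
  ab <- tapply(blocks$qend - blocks$qstart, blocks$ref, sum)
  best <- names(ab)[order(-ab, names(ab))][1]
  bb <- blocks[blocks$ref == best, , drop = FALSE]
  agf <- aligned_genome_fraction(bb, nchar(refs[[best]]),
                                 isTRUE(truth$circular[[best]]))
  total_aligned <- sum(blocks$qend - blocks$qstart)
  other <- sum(blocks$qend[blocks$ref != best] -
                 blocks$qstart[blocks$ref != best])
  contam <- 100 * other / max(1, total_aligned)
  rrna <- FALSE
  if (!is.null(truth$marker) && best %in% names(truth$marker)) {
    mk <- truth$marker[[best]]
    mb <- align_to_reference(stats::setNames(mk, "marker"),
                             stats::setNames(contigs$seq, contigs$id),
                             min_block = 200, min_identity = 0.99)
    if (nrow(mb)) {
      cov <- union_ref_bases(mb$qstart, mb$qend, nchar(mk))
      rrna <- cov >= 0.95 * nchar(mk)
    }
  }
  q <- quality_record(min(100, agf), contam, nrow(contigs),
                      n50 = n50(lens), total_bp = sum(lens),
                      circular_all = all(contigs$circular), rrna_full = rrna)
  attr(q, "ref") <- best
  q
}

#' Relative abundance of MAGs by consumed read bases
#'
#' Abundance of a MAG is the total base count of the reads it consumed
#' divided by the base count of the full original data set.
#'
#' @param mags list of MAG records with `consumed_read_ids`.
#' @param total_dataset_bases base count of the full (pre-iteration) data.
#' @param read_bases named vector mapping read id to its length.
#' @return numeric fractions (one per MAG, sums to <= 1).
#' @export
relative_abundance <- function(mags, total_dataset_bases, read_bases) {
  vapply(mags, function(m) {
    ids <- intersect(m$consumed_read_ids, names(read_bases))
    sum(read_bases[ids]) / total_dataset_bases
  }, numeric(1))
}

#' Should the iteration loop stop?
#'
#' Stops when the qualified abundance reconstructed this iteration falls
#' below `threshold` (strict), or at `max_iter` iterations.
#'
#' @param state an IterationState (needs `qualified_abundance` and
#'   `iteration`).
#' @param threshold abundance stop threshold (default 0.02).
#' @param max_iter iteration cap (default 11).
#' @return logical.
#' @export
should_stop <- function(state, threshold = 0.02, max_iter = 11) {
  state$qualified_abundance < threshold || state$iteration >= max_iter
}

# ---- sketch ANI and dereplication -----------------------------------------

genome_kmer_set <- function(seqs, k) {
  h <- unlist(lapply(seqs, cpp_canon_kmers, k = k), use.names = FALSE)
  sort(unique(h))
}

#' Estimate ANI between two genomes by k-mer bottom sketching
#'
#' Jaccard similarity J of the bottom-`sketch` canonical `k`-mers of the
#' union gives `ani = 1 + (1/k) ln(2J / (1 + J))` (clamped to \[0, 1\]);
#' `coverage` is the fraction of `a`'s sketch k-mers found anywhere in `b`.
#'
#' @param a,b character vectors of genome/contig sequences (>= 10 kb total).
#' @param k k-mer size (default 21).
#' @param sketch sketch size (default 5000).
#' @return list with `ani` and `coverage`.
#' @export
estimate_ani <- function(a, b, k = 21, sketch = 5000) {
  ka <- genome_kmer_set(a, k)
  kb <- genome_kmer_set(b, k)
  if (!length(ka) || !length(kb)) return(list(ani = 0, coverage = 0))
  sa <- head(ka, sketch)
  sb <- head(kb, sketch)
  su <- head(sort(unique(c(sa, sb))), sketch)
  inter <- sum(su %in% sa & su %in% sb)
  J <- inter / length(su)
  ani <- if (J <= 0) 0 else min(1, max(0, 1 + log(2 * J / (1 + J)) / k))
  cov <- mean(sa %in% kb)
  list(ani = ani, coverage = cov)
}

#' Dereplicate MAGs into representative genomes
#'
#' Single-linkage primary clusters at `ani >= primary_ani` with alignment
#' coverage >= `min_cov`, secondary clusters within them at
#' `ani >= secondary_ani`; each secondary cluster keeps the MAG maximizing
#' `completeness - 5 x contamination + 0.5 log10(N50)`.
#'
#' @param mags list of MAG records (`contigs`, `quality`).
#' @param primary_ani,secondary_ani,min_cov dereplication thresholds
#'   (defaults 0.90 / 0.97 / 0.65).
#' @param k,sketch [estimate_ani()] parameters.
#' @return the representative subset of `mags` (same structure).
#' @export
dereplicate <- function(mags, primary_ani = 0.90, secondary_ani = 0.97,
                        min_cov = 0.65, k = 21, sketch = 5000) {
  n <- length(mags)
  if (n <= 1) return(mags)
  ani <- matrix(0, n, n)
  cov <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e1 <- estimate_ani(mags[[i]]$contigs$seq, mags[[j]]$contigs$seq,
                         k, sketch)
      e2 <- estimate_ani(mags[[j]]$contigs$seq, mags[[i]]$contigs$seq,
                         k, sketch)
      ani[i, j] <- ani[j, i] <- max(e1$ani, e2$ani)
      cov[i, j] <- cov[j, i] <- max(e1$coverage, e2$coverage)
    }
  }
  cluster_sl <- function(idx, amat, cmat, thr_ani, thr_cov) {
    parent <- seq_along(idx)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_along(idx)[-1]) {
      for (j in seq_len(i - 1)) {
        if (amat[idx[i], idx[j]] >= thr_ani &&
            cmat[idx[i], idx[j]] >= thr_cov) {
          parent[find(i)] <- find(j)
        }
      }
    }
    vapply(seq_along(idx), find, integer(1))
  }
  score <- vapply(mags, function(m) {
    m$quality$completeness - 5 * m$quality$contamination +
      0.5 * log10(max(m$quality$n50, 10))
  }, numeric(1))
  keep <- integer(0)
  prim <- cluster_sl(seq_len(n), ani, cov, primary_ani, min_cov)
  for (pc in unique(prim)) {
    idx <- which(prim == pc)
    sec <- cluster_sl(idx, ani, cov, secondary_ani, min_cov)
    for (sc in unique(sec)) {
      members <- idx[sec == sc]
      keep <- c(keep, members[which.max(score[members])])
    }
  }
  mags[sort(keep)]
}

# ---- iteration driver ------------------------------------------------------

#' Initialize the iteration state
#'
#' @param long,short full filtered ReadSets.
#' @param truth truth table (reference-mode quality estimation).
#' @return an `IterationState`.
#' @export
init_state <- function(long, short, truth = NULL) {
  structure(list(iteration = 0L, long = long, short = short, truth = truth,
                 total_bases0 = total_bases(long) + total_bases(short),
                 read_bases = stats::setNames(c(nchar(long$seq),
                                                nchar(short$seq)),
                                              c(long$id, short$id)),
                 mags = list(), leftover = NULL,
                 qualified_abundance = 1, stopped = FALSE, log = list()),
            class = "IterationState")
}

#' Run one iteration of the iterative hybrid assembly
#'
#' Draft-assembles the (optionally subsampled) remaining long reads, bins the
#' draft contigs by composition and coverage, phases long and short reads
#' into the bins, hybrid-assembles each bin, gates MAG quality against the
#' truth genomes, subtracts the reads assigned to qualified MAGs from the
#' remaining set, and appends retained MAGs to the state.
#'
#' @param state an `IterationState`.
#' @param config pipeline configuration (see [default_config()]).
#' @return the updated state (`qualified_abundance`, `mags`, `long`, `short`,
#'   `iteration` advanced).
#' @export
run_iteration <- function(state, config = default_config()) {
  it <- state$iteration + 1L
  state$iteration <- it
  if (!length(state$long)) {
    state$qualified_abundance <- 0
    state$stopped <- TRUE
    return(state)
  }
  wl <- state$long; ws <- state$short
  icfg <- config$iterate
  if (!is.null(icfg$working_long_bases) &&
      total_bases(wl) > icfg$working_long_bases) {
    wl <- subsample_to_bases(wl, icfg$working_long_bases,
                             seed = 7000 + it)
  }
  if (!is.null(icfg$working_short_bases) && length(ws) &&
      total_bases(ws) > icfg$working_short_bases) {
    ws <- subsample_to_bases(ws, icfg$working_short_bases,
                             seed = 8000 + it)
  }
  # step 2: community-level draft assembly of the working long reads
  draft <- tryCatch(
    mini_olc_assemble(wl, min_overlap = config$assembly$min_overlap,
                      min_chain_score = config$assembly$min_chain_score,
                      consensus_rounds = 1),
    error = function(e) NULL)
  keepable <- !is.null(draft) && nrow(draft) > 0
  if (keepable) {
    # carry forward leftover contigs from earlier iterations
    if (!is.null(state$leftover) && nrow(state$leftover)) {
      lo <- state$leftover
      lo$id <- paste0("prev_", lo$id)
      draft <- rbind(draft, lo)
      class(draft) <- c("ContigSet", "data.frame")
    }
    draft <- draft[nchar(draft$seq) >= 1000, , drop = FALSE]
    class(draft) <- c("ContigSet", "data.frame")
    keepable <- nrow(draft) > 0
  }
  if (!keepable) {
    state$qualified_abundance <- 0
    state$stopped <- TRUE
    return(state)
  }
  # step 3 + 5: bin the draft contigs
  bn <- bin_contigs(draft, cov_weight = config$binning$cov_weight,
                    min_bin_bases = config$binning$min_bin_bases,
                    linkage = config$binning$linkage,
                    metric = config$binning$metric)
  bins <- bn$bins
  real <- bins[!vapply(bins, is_leftover, logical(1))]
  leftover_ids <- unlist(lapply(bins[vapply(bins, is_leftover, logical(1))],
                                `[[`, "contig_ids"))
  state$leftover <- draft[draft$id %in% leftover_ids, , drop = FALSE]
  class(state$leftover) <- c("ContigSet", "data.frame")
  if (!length(real)) {
    state$qualified_abundance <- 0
    state$stopped <- TRUE
    return(state)
  }
  # phase reads into bins
  idx <- build_minimizer_index(bins, draft, k = config$phasing$k,
                               w = config$phasing$w)
  asg_l <- assign_reads(wl, idx, config$phasing$min_score,
                        config$phasing$tie_ratio,
                        config$phasing$min_frac_long)
  asg_s <- if (length(ws)) assign_reads(ws, idx, config$phasing$min_score,
                                        config$phasing$tie_ratio,
                                        config$phasing$min_frac_short)
           else NULL
  # per-bin hybrid assembly and gating
  new_mags <- list()
  qualified_seqs <- list()
  gate_mag <- function(contigs, id) {
    q <- tryCatch(assess_quality(contigs, state$truth),
                  error = function(e) NULL)
    if (is.null(q)) return(invisible(NULL))
    mag <- list(id = id, contigs = contigs, quality = q,
                tier = classify_tier(q), iteration = it,
                consumed_read_ids = character(),
                relative_abundance = NA_real_, ref = attr(q, "ref"))
    if (is_qualified(q)) qualified_seqs[[id]] <<- contigs
    if (retain_filter(q)) new_mags[[id]] <<- mag
    invisible(q)
  }
  for (bi in seq_along(real)) {
    bid <- real[[bi]]$bin_id
    bl <- rs_subset(wl, which(asg_l$bin_id == bid))
    bs <- if (!is.null(asg_s)) rs_subset(ws, which(asg_s$bin_id == bid))
          else read_set(platform = "short")
    res <- assemble_bin(bl, bs, backend = "mini_olc", config = config)
    if (res$status != "ok") next
    id <- sprintf("iter%02d_%s", it, bid)
    q <- gate_mag(res$contigs, id)
    # an under-split bin assembles its genomes as separate contigs but fails
    # retention on contamination; re-gate each contig on its own
    if (!is.null(q) && !retain_filter(q) && q$contamination >= 10 &&
        nrow(res$contigs) >= 2 && nrow(res$contigs) <= 8) {
      for (ci in seq_len(nrow(res$contigs))) {
        sub <- res$contigs[ci, , drop = FALSE]
        class(sub) <- c("ContigSet", "data.frame")
        gate_mag(sub, sprintf("%s_split%d", id, ci))
      }
    }
  }
  # subtract reads assigned to qualified MAGs (fresh assignment against the
  # final MAG sequences, over the full remaining set)
  consumed_bases <- 0
  if (length(qualified_seqs)) {
    qbins <- lapply(names(qualified_seqs), function(nm) {
      list(bin_id = nm,
           contig_ids = paste(nm, qualified_seqs[[nm]]$id, sep = "."),
           centroid = NULL, long_read_ids = character(),
           short_read_ids = character())
    })
    allq <- do.call(rbind, lapply(names(qualified_seqs), function(nm) {
      cs <- qualified_seqs[[nm]]
      cs$id <- paste(nm, cs$id, sep = ".")
      cs
    }))
    class(allq) <- c("ContigSet", "data.frame")
    qidx <- build_minimizer_index(qbins, allq, k = config$phasing$k,
                                  w = config$phasing$w)
    subl <- assign_reads(state$long, qidx, config$phasing$min_score,
                         config$phasing$tie_ratio,
                         config$iterate$subtract_frac_long)
    subs <- if (length(state$short)) {
      assign_reads(state$short, qidx, config$phasing$min_score,
                   config$phasing$tie_ratio,
                   config$iterate$subtract_frac_short)
    } else NULL
    for (nm in names(new_mags)) {
      if (!nm %in% names(qualified_seqs)) next
      ids <- c(subl$read_id[!is.na(subl$bin_id) & subl$bin_id == nm],
               if (!is.null(subs))
                 subs$read_id[!is.na(subs$bin_id) & subs$bin_id == nm])
      new_mags[[nm]]$consumed_read_ids <- ids
    }
    consumed_l <- subl$read_id[!is.na(subl$bin_id)]
    consumed_s <- if (!is.null(subs)) subs$read_id[!is.na(subs$bin_id)]
                  else character()
    consumed_bases <- sum(state$read_bases[c(consumed_l, consumed_s)])
    state$long <- subtract_reads(state$long, consumed_l)
    state$short <- subtract_reads(state$short, consumed_s)
  }
  for (nm in names(new_mags)) {
    new_mags[[nm]]$relative_abundance <-
      sum(state$read_bases[new_mags[[nm]]$consumed_read_ids]) /
      state$total_bases0
  }
  state$mags <- c(state$mags, new_mags)
  state$qualified_abundance <- consumed_bases / state$total_bases0
  state$log[[it]] <- list(iteration = it, bins = length(real),
                          mags = length(new_mags),
                          qualified_abundance = state$qualified_abundance)
  state
}

#' Run the full iterative hybrid assembly pipeline
#'
#' Repeats [run_iteration()] until [should_stop()] fires, then dereplicates
#' the collected MAGs.
#'
#' @param long,short filtered ReadSets (the full data set).
#' @param truth truth table for reference-mode quality estimation.
#' @param config pipeline configuration.
#' @return list with `mags` (dereplicated), `state` (final), and `summary`
#'   (one row per MAG).
#' @export
run_hcbha <- function(long, short, truth, config = default_config()) {
  state <- init_state(long, short, truth)
  repeat {
    state <- run_iteration(state, config)
    if (state$stopped || should_stop(state, config$iterate$stop_threshold,
                                     config$iterate$max_iter)) break
  }
  mags <- dereplicate(state$mags,
                      primary_ani = config$derep$primary_ani,
                      secondary_ani = config$derep$secondary_ani,
                      min_cov = config$derep$min_cov)
  list(mags = mags, state = state, summary = mags_summary(mags))
}

#' Summary table of MAG records
#' @param mags list of MAG records.
#' @return data.frame (id, tier, completeness, contamination, n_contigs,
#'   n50, circular, abundance, iteration).
#' @export
mags_summary <- function(mags) {
  if (!length(mags)) {
    return(data.frame(id = character(), tier = character(),
                      completeness = numeric(), contamination = numeric(),
                      n_contigs = integer(), n50 = numeric(),
                      circular = logical(), abundance = numeric(),
                      iteration = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(mags, function(m) {
    data.frame(id = m$id, tier = m$tier,
               completeness = m$quality$completeness,
               contamination = m$quality$contamination,
               n_contigs = m$quality$n_contigs, n50 = m$quality$n50,
               circular = m$quality$circular_all,
               abundance = m$relative_abundance, iteration = m$iteration,
               stringsAsFactors = FALSE)
  }))
}
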