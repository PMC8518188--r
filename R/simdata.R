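# Synthetic community and hybrid read-set generator. Provides ground truth
# (genome of origin and exact coordinates per read) so phasing, assembly and
# evaluation can be scored without external data.

#' Describe a synthetic community
#'
#' @param n_genomes number of genomes (>= 1).
#' @param length_range (min, max) genome length in bp; min >= 5000.
#' @param target_ani optional scalar target pairwise average nucleotide
#'   identity in (0.5, 1]; genomes are then derived from a common ancestor by
#'   point substitution so that each pair sits at about this identity. `NULL`
#'   generates independent random genomes (unrelated, ANI ~ background).
#' @param n_repeats,repeat_len exact internal duplications planted per genome.
#' @param abundance `"even"` or `"lognormal"`; lognormal uses `ab_sigma`
#'   (sdlog) and normalizes to 1.
#' @param ab_sigma sdlog of the lognormal abundance model.
#' @param gc_range GC-content range for unrelated genomes (each genome draws
#'   its own GC, giving species-like compositional signatures).
#' @param circular are genomes closed circular replicons (default TRUE).
#' @param marker_len length of the planted rRNA-like marker locus; the locus
#'   stands in for the full-length rRNA operon of the MIMAG high-quality tier
#'   and is recorded in the truth table for downstream detection.
#' @param seed integer seed.
#' @return a `CommunitySpec` list.
#' @export
community_spec <- function(n_genomes, length_range = c(20000, 50000),
                           target_ani = NULL, n_repeats = 0, repeat_len = 0,
                           abundance = c("even", "lognormal"), ab_sigma = 1,
                           gc_range = c(0.35, 0.65), circular = TRUE,
                           marker_len = 1500, seed = 1) {
  abundance <- match.arg(abundance)
  stopifnot(n_genomes >= 1, length_range[1] >= 5000,
            length_range[1] <= length_range[2])
  if (!is.null(target_ani) &&
      (target_ani <= 0.5 || target_ani > 1)) {
    stop("target_ani must lie in (0.5, 1]")
  }
  structure(list(n_genomes = n_genomes, length_range = length_range,
                 target_ani = target_ani, n_repeats = n_repeats,
                 repeat_len = repeat_len, abundance = abundance,
                 ab_sigma = ab_sigma, gc_range = gc_range,
                 circular = circular, marker_len = marker_len, seed = seed),
            class = "CommunitySpec")
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# species-like genome: first-order Markov DNA with a genome-specific GC
# content and a random dinucleotide bias (log-normal perturbation of the
# transition rows), giving each genome a distinct oligonucleotide signature
random_genome <- function(n, gc = 0.5, bias_sd = 0.2) {
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  P <- matrix(rep(p0, each = 4), 4, 4) * exp(matrix(rnorm(16, 0, bias_sd),
                                                    4, 4))
  P <- P / rowSums(P)
  cpp_markov_dna(as.integer(n), P, p0)
}

#' Generate a synthetic community with ground truth
#'
#' Genomes are i.i.d.-composition random DNA. Unrelated genomes (no
#' `target_ani`) each draw their own GC content from `gc_range`, giving them
#' distinct strand-symmetric tetranucleotide signatures the way distinct
#' species have. With `target_ani` set, all genomes derive from one ancestor
#' by point substitution at rate (1 - ANI) / 2 each, so pairwise identity is
#' about the target (strain-like genomes share the ancestor's composition).
#' Each genome then receives `n_repeats` exact internal duplications and one
#' planted rRNA-like marker locus. Deterministic given `spec$seed`.
#'
#' @param spec a [community_spec()].
#' @return list with `genomes` (a ContigSet; coverage 0, circular per spec)
#'   and `truth`: genome sequences, abundances (sum 1), circularity, the
#'   per-genome marker sequence and flag, and an (initially empty) read
#'   coordinate table.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "CommunitySpec"))
  with_seed(spec$seed, {
    n <- spec$n_genomes
    lens <- round(runif(n, spec$length_range[1], spec$length_range[2]))
    ids <- sprintf("genome_%02d", seq_len(n))
    if (is.null(spec$target_ani)) {
      gcs <- runif(n, spec$gc_range[1], spec$gc_range[2])
      seqs <- vapply(seq_len(n), function(i) random_genome(lens[i], gcs[i]),
                     character(1))
    } else {
      # common ancestor at the max length, each genome substituted at rate r
      anc <- random_dna(max(lens))
      r <- (1 - spec$target_ani) / 2
      seqs <- vapply(seq_len(n), function(i) {
        s <- substr(anc, 1, lens[i])
        cpp_mutate_seqs(s, r, 0, 0)$seq[[1]]
      }, character(1))
    }
    # exact internal duplications
    if (spec$n_repeats > 0 && spec$repeat_len > 0) {
      seqs <- vapply(seqs, function(s) {
        for (j in seq_len(spec$n_repeats)) {
          L <- nchar(s)
          src <- sample.int(L - spec$repeat_len, 1)
          piece <- substr(s, src, src + spec$repeat_len - 1)
          at <- sample.int(L, 1)
          s <- paste0(substr(s, 1, at), piece, substr(s, at + 1, L))
        }
        s
      }, character(1), USE.NAMES = FALSE)
    }
    # planted rRNA-like marker locus (recorded for HQ-tier detection)
    markers <- vapply(seq_len(n), function(i) random_dna(spec$marker_len),
                      character(1))
    seqs <- vapply(seq_len(n), function(i) {
      L <- nchar(seqs[i])
      at <- sample.int(L, 1)
      paste0(substr(seqs[i], 1, at), markers[i], substr(seqs[i], at + 1, L))
    }, character(1))
    ab <- switch(spec$abundance,
                 even = rep(1 / n, n),
                 lognormal = {
                   x <- rlnorm(n, 0, spec$ab_sigma)
                   x / sum(x)
                 })
    truth <- list(
      genomes = stats::setNames(seqs, ids),
      abundance = stats::setNames(ab, ids),
      circular = stats::setNames(rep(spec$circular, n), ids),
      marker = stats::setNames(markers, ids),
      rrna_flag = stats::setNames(rep(TRUE, n), ids),
      reads = data.frame(read_id = character(), genome = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE)
    )
    genomes <- contig_set(ids, seqs, coverage = 0, circular = spec$circular)
    list(genomes = genomes, truth = truth)
  })
}

# expected per-genome coverage: depth is the community-average depth; genome g
# receives depth * n * abundance_g (even abundances -> every genome at depth)
genome_coverages <- function(truth, depth) {
  depth * length(truth$abundance) * truth$abundance
}

draw_interval <- function(len, rlen, circular) {
  # 0-based start; circular genomes wrap (end may exceed len)
  if (circular) {
    s <- sample.int(len, 1) - 1L
  } else {
    rlen <- min(rlen, len)
    s <- sample.int(len - rlen + 1L, 1) - 1L
  }
  c(s, s + rlen)
}

extract_interval <- function(seq, s, e, circular) {
  len <- nchar(seq)
  if (e <= len) return(substr(seq, s + 1, e))
  stopifnot(circular)
  paste0(substr(seq, s + 1, len), substr(seq, 1, e - len))
}

#' Simulate error-prone long reads
#'
#' Read lengths are lognormal (median `length_mean`, sd factor
#' `length_sd_factor`) floored at `min_len`; start positions are uniform
#' (circular genomes wrap) and strands uniform. Errors are i.i.d. per base
#' with a 40:30:30 substitution:insertion:deletion mix of the total error
#' rate `1 - mean_accuracy`. Deterministic given `seed`.
#'
#' @param truth a truth table from [generate_community()].
#' @param mean_accuracy target mean read accuracy in `[0.7, 1)`; default 0.867.
#' @param depth community-average long-read depth (x).
#' @param length_mean median read length (bp).
#' @param length_sd_factor lognormal sd factor (sdlog = log of this).
#' @param min_len minimum emitted read length (bp).
#' @param error_mix substitution/insertion/deletion proportions (sum 1).
#' @param seed integer seed.
#' @return list with `reads` (a long ReadSet) and updated `truth` whose read
#'   table records (read_id, genome, start, end, strand), 0-based half-open
#'   pre-error coordinates.
#' @export
simulate_long_reads <- function(truth, mean_accuracy = 0.867, depth = 30,
                                length_mean = 8000, length_sd_factor = 2,
                                min_len = 1000,
                                error_mix = c(0.4, 0.3, 0.3), seed = 1) {
  stopifnot(mean_accuracy >= 0.7, mean_accuracy <= 1, depth > 0)
  with_seed(seed, {
    covs <- genome_coverages(truth, depth)
    glens <- nchar(truth$genomes)
    target <- sum(covs * glens)
    w <- truth$abundance * glens
    w <- w / sum(w)
    # draw reads until the base target is met
    ids <- character(); gms <- character(); sta <- integer(); en <- integer()
    str <- character(); seqs <- character()
    tot <- 0; i <- 0
    while (tot < target) {
      i <- i + 1
      g <- sample(names(truth$genomes), 1, prob = w)
      rlen <- max(min_len, round(rlnorm(1, log(length_mean),
                                        log(length_sd_factor))))
      circ <- truth$circular[[g]]
      rlen <- min(rlen, glens[[g]])
      iv <- draw_interval(glens[[g]], rlen, circ)
      s <- extract_interval(truth$genomes[[g]], iv[1], iv[2], circ)
      st <- if (runif(1) < 0.5) "+" else "-"
      if (st == "-") s <- cpp_revcomp(s)
      ids[i] <- sprintf("long_%06d", i)
      gms[i] <- g; sta[i] <- iv[1]; en[i] <- iv[2]; str[i] <- st
      seqs[i] <- s
      tot <- tot + rlen
    }
    err <- 1 - mean_accuracy
    # alignment compresses interacting adjacent events (e.g. an insertion
    # next to a deletion realigns as one substitution): realigned edit rate
    # ~ r (1 - 0.39 r) for the default error mix, so plant events at the
    # first-order-corrected rate to make the *realigned* accuracy hit the
    # target
    rate <- err * (1 + 0.39 * err)
    mut <- cpp_mutate_seqs(seqs, rate * error_mix[1], rate * error_mix[2],
                           rate * error_mix[3])
    q <- max(2L, round(-10 * log10(max(err, 1e-9))))
    quals <- vapply(nchar(mut$seq), function(n) strrep(intToUtf8(33 + q), n),
                    character(1))
    rs <- read_set(ids, mut$seq, quals, "long")
    truth$reads <- rbind(truth$reads,
                         data.frame(read_id = ids, genome = gms, start = sta,
                                    end = en, strand = str,
                                    stringsAsFactors = FALSE))
    list(reads = rs, truth = truth)
  })
}

#' Simulate accurate paired short reads
#'
#' Proper FR pairs with insert size ~ Normal(`insert_mean`, `insert_sd`)
#' (truncated to at least `read_len`). Errors are substitution-only; per-base
#' Phred qualities are emitted from a two-level model whose mixture is chosen
#' so the expected error equals `error_rate`, so qualities are consistent
#' with the realized errors.
#'
#' @param truth truth table from [generate_community()].
#' @param depth community-average short-read depth (x, counting both mates).
#' @param read_len read length (bp), default 150 (2 x 150 mode).
#' @param insert_mean,insert_sd fragment size model (bp).
#' @param error_rate expected substitution rate (default 0.003).
#' @param seed integer seed.
#' @return list with `reads` (a short ReadSet, ids suffixed `/1`, `/2`) and
#'   updated `truth` (fragment coordinates recorded per mate).
#' @export
simulate_short_reads <- function(truth, depth = 100, read_len = 150,
                                 insert_mean = 350, insert_sd = 50,
                                 error_rate = 0.003, seed = 1) {
  stopifnot(read_len <= insert_mean, depth > 0)
  with_seed(seed, {
    covs <- genome_coverages(truth, depth)
    glens <- nchar(truth$genomes)
    n_pairs_g <- round(covs * glens / (2 * read_len))
    ids <- character(); gms <- character(); sta <- integer(); en <- integer()
    str <- character(); seqs <- character(); mate <- character()
    idx <- 0; pair <- 0
    for (g in names(truth$genomes)) {
      circ <- truth$circular[[g]]
      for (j in seq_len(n_pairs_g[[g]])) {
        pair <- pair + 1
        ins <- max(read_len, round(rnorm(1, insert_mean, insert_sd)))
        ins <- min(ins, glens[[g]])
        iv <- draw_interval(glens[[g]], ins, circ)
        frag <- extract_interval(truth$genomes[[g]], iv[1], iv[2], circ)
        fwd <- runif(1) < 0.5 # fragment strand
        if (!fwd) frag <- cpp_revcomp(frag)
        r1 <- substr(frag, 1, read_len)
        r2 <- cpp_revcomp(substr(frag, ins - read_len + 1, ins))
        # record both mates with fragment-interval coordinates
        base <- sprintf("short_%07d", pair)
        for (m in 1:2) {
          idx <- idx + 1
          ids[idx] <- paste0(base, "/", m)
          gms[idx] <- g; sta[idx] <- iv[1]; en[idx] <- iv[2]
          str[idx] <- if (fwd) "+" else "-"
          seqs[idx] <- if (m == 1) r1 else r2
          mate[idx] <- paste0("R", m)
        }
      }
    }
    # two-level quality model solving the expected error rate
    q_hi <- 40L; q_lo <- 10L
    e_hi <- 10^(-q_hi / 10); e_lo <- 10^(-q_lo / 10)
    p_lo <- min(1, max(0, (error_rate - e_hi) / (e_lo - e_hi)))
    err <- cpp_short_read_errors(seqs, q_hi, q_lo, p_lo)
    rs <- read_set(ids, err$seq, err$qual, "short", mate)
    truth$reads <- rbind(truth$reads,
                         data.frame(read_id = ids, genome = gms, start = sta,
                                    end = en, strand = str,
                                    stringsAsFactors = FALSE))
    list(reads = rs, truth = truth)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits genomes.fasta, long.fastq.gz, short_R1.fastq.gz, short_R2.fastq.gz,
#' truth.tsv and abundances.tsv under `dir`.
#'
#' @param truth truth table with reads recorded.
#' @param long,short ReadSets from the simulators.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated <- function(truth, long, short, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$genomes, file.path(dir, "genomes.fasta"))
  write_fastq(long, file.path(dir, "long.fastq.gz"))
  r1 <- rs_subset(short, which(short$mate == "R1"))
  r2 <- rs_subset(short, which(short$mate == "R2"))
  write_fastq(r1, file.path(dir, "short_R1.fastq.gz"))
  write_fastq(r2, file.path(dir, "short_R2.fastq.gz"))
  write.table(truth$reads, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ab <- data.frame(genome = names(truth$abundance),
                   abundance = as.numeric(truth$abundance))
  write.table(ab, file.path(dir, "abundances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
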