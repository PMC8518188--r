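#' @useDynLib hcbha, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad rnorm rlnorm runif cutree hclust dist sd
#' @importFrom utils head write.table read.table
NULL

# ---- ReadSet ---------------------------------------------------------------

#' Construct a ReadSet
#'
#' A ReadSet is the package's currency for sequencing reads: parallel vectors
#' of read id, sequence, optional Phred+33 quality string, plus a platform tag
#' (`"long"` for error-prone single-end long reads, `"short"` for accurate
#' paired short reads) and an optional mate tag (`"R1"`/`"R2"`).
#'
#' @param id character vector of unique read ids.
#' @param seq character vector of ACGTN sequences (non-ACGT mapped to N).
#' @param qual optional character vector of Phred+33 quality strings
#'   (`NA_character_` where absent); lengths must match `seq`.
#' @param platform `"long"` or `"short"`.
#' @param mate optional character vector (`"R1"`, `"R2"` or `NA`).
#' @return An object of class `ReadSet` with fields `id`, `seq`, `qual`,
#'   `mate`, `platform` and `total_bases`.
#' @export
read_set <- function(id = character(), seq = character(), qual = NULL,
                     platform = c("long", "short"), mate = NULL) {
  platform <- match.arg(platform)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (anyDuplicated(id)) stop("read ids must be unique within a ReadSet")
  if (length(seq) && any(!nzchar(seq))) stop("empty read sequence")
  seq <- gsub("[^ACGT]", "N", seq)
  if (is.null(qual)) qual <- rep(NA_character_, length(seq))
  if (length(qual) != length(seq)) stop("qual and seq lengths differ")
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad)) {
    stop(sprintf("quality length differs from sequence length for read '%s'",
                 id[which(bad)[1]]))
  }
  if (is.null(mate)) mate <- rep(NA_character_, length(seq))
  structure(list(id = id, seq = seq, qual = qual, mate = mate,
                 platform = platform,
                 total_bases = sum(nchar(seq))),
            class = "ReadSet")
}

#' @export
length.ReadSet <- function(x) length(x$id)

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d %s reads, %s bases\n", length(x),
              x$platform, format(x$total_bases, big.mark = ",")))
  invisible(x)
}

#' Subset a ReadSet by index or read id
#' @param rs a ReadSet.
#' @param i integer/logical index or character vector of read ids.
#' @return a ReadSet.
#' @export
rs_subset <- function(rs, i) {
  if (is.character(i)) i <- match(i, rs$id)
  read_set(rs$id[i], rs$seq[i], rs$qual[i], rs$platform, rs$mate[i])
}

#' Total bases in a ReadSet
#' @param rs a ReadSet.
#' @return integer-valued numeric, the sum of read lengths.
#' @export
total_bases <- function(rs) rs$total_bases

# ---- ContigSet -------------------------------------------------------------

#' Construct a contig table
#'
#' Contigs are kept as a plain data.frame with columns `id`, `seq`,
#' `coverage` (mean long-read depth) and `circular`.
#'
#' @param id character contig ids.
#' @param seq character contig sequences.
#' @param coverage numeric mean depth (>= 0).
#' @param circular logical closed-replicon flag.
#' @return data.frame of class `ContigSet`.
#' @export
contig_set <- function(id = character(), seq = character(), coverage = 0,
                       circular = FALSE) {
  seq <- toupper(as.character(seq))
  if (length(seq) && any(!nzchar(seq))) stop("empty contig sequence")
  seq <- gsub("[^ACGT]", "N", seq)
  df <- data.frame(id = as.character(id), seq = seq,
                   coverage = rep_len(as.numeric(coverage), length(id)),
                   circular = rep_len(as.logical(circular), length(id)),
                   stringsAsFactors = FALSE)
  if (any(df$coverage < 0)) stop("coverage must be >= 0")
  class(df) <- c("ContigSet", "data.frame")
  df
}

# ---- FASTA / FASTQ ---------------------------------------------------------

#' Parse a FASTA file
#'
#' Headers are truncated at the first whitespace; sequences are uppercased and
#' non-ACGT characters are mapped to N. Gzip input is handled transparently.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return named character vector of sequences (names = header tokens).
#' @export
parse_fasta <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop(sprintf("FASTA parse error at line 1: sequence before header"))
  }
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- stats::setNames(rep("", length(ids)), NULL)
  out[as.integer(names(seqs))] <- seqs
  out <- toupper(out)
  out <- gsub("[^ACGT]", "N", out)
  names(out) <- ids
  out
}

#' Write sequences to FASTA (80-column wrapped)
#' @param seqs named character vector (or ContigSet).
#' @param path output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "ContigSet")) seqs <- stats::setNames(seqs$seq, seqs$id)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 80)
    writeLines(substring(s, starts, pmin(starts + 79, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a FASTQ file into a ReadSet
#'
#' Expects 4-line records with Phred+33 qualities. Read ids ending in `/1` or
#' `/2` keep the suffix in the id and get the corresponding mate tag.
#'
#' @param path path to a (optionally gzipped) FASTQ file.
#' @param platform `"long"` or `"short"`.
#' @return a ReadSet.
#' @export
parse_fastq <- function(path, platform = c("long", "short")) {
  platform <- match.arg(platform)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) return(read_set(platform = platform))
  if (length(lines) %% 4 != 0) {
    stop(sprintf("FASTQ parse error: %d lines is not a multiple of 4",
                 length(lines)))
  }
  ids <- lines[seq(1, length(lines), 4)]
  if (any(!startsWith(ids, "@"))) {
    bad <- which(!startsWith(ids, "@"))[1]
    stop(sprintf("FASTQ parse error at line %d: header must start with '@'",
                 (bad - 1) * 4 + 1))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", ids))
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf(
      "FASTQ parse error at line %d: quality length (%d) != sequence length (%d) for read '%s'",
      (bad[1] - 1) * 4 + 4, nchar(quals[bad[1]]), nchar(seqs[bad[1]]), ids[bad[1]]))
  }
  mate <- rep(NA_character_, length(ids))
  mate[endsWith(ids, "/1")] <- "R1"
  mate[endsWith(ids, "/2")] <- "R2"
  read_set(ids, seqs, quals, platform, mate)
}

#' Write a ReadSet to FASTQ
#' @param rs a ReadSet; reads without qualities are written at a constant I
#'   (Q40) placeholder quality.
#' @param path output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  qual <- rs$qual
  miss <- is.na(qual)
  if (any(miss)) qual[miss] <- vapply(nchar(rs$seq[miss]), function(n)
    strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", rs$id), rs$seq, "+", qual)), con)
  invisible(path)
}

# ---- Quality helpers -------------------------------------------------------

#' Mean Phred score per read
#' @param rs a ReadSet with qualities on every read.
#' @return numeric vector of arithmetic mean Phred scores.
#' @export
mean_phred <- function(rs) {
  if (anyNA(rs$qual)) stop("reads without qualities present")
  vapply(rs$qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Filter short reads on mean base quality
#'
#' Retains exactly the reads whose arithmetic mean Phred score is at least
#' `min_mean_q` (default 30). Mates are filtered independently; orphaned
#' mates stay in the set.
#'
#' @param rs a short-read ReadSet with qualities.
#' @param min_mean_q Phred threshold (default 30).
#' @return a ReadSet.
#' @export
filter_short_reads <- function(rs, min_mean_q = 30) {
  stopifnot(rs$platform == "short")
  if (!length(rs)) return(rs)
  rs_subset(rs, mean_phred(rs) >= min_mean_q)
}

#' Filter long reads on length
#'
#' Retains exactly the reads with length >= `min_len` (default 1000 bp).
#'
#' @param rs a long-read ReadSet.
#' @param min_len minimum length in bp.
#' @return a ReadSet.
#' @export
filter_long_reads <- function(rs, min_len = 1000) {
  stopifnot(rs$platform == "long")
  if (!length(rs)) return(rs)
  rs_subset(rs, nchar(rs$seq) >= min_len)
}

# run code under a local RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly subsample a ReadSet to a base target
#'
#' Reads are drawn uniformly at random without replacement until the
#' cumulative base count first reaches `target_bases`. Deterministic given
#' `seed`. If the input holds fewer bases than the target the whole input is
#' returned with a warning.
#'
#' @param rs a ReadSet.
#' @param target_bases target cumulative bases (> 0).
#' @param seed integer seed.
#' @return a ReadSet (a sub-multiset of `rs`, input order not preserved).
#' @export
subsample_to_bases <- function(rs, target_bases, seed) {
  stopifnot(target_bases > 0)
  if (total_bases(rs) <= target_bases) {
    if (total_bases(rs) < target_bases) {
      warning("input smaller than subsample target; returning whole ReadSet")
    }
    return(rs)
  }
  perm <- with_seed(seed, sample.int(length(rs)))
  cum <- cumsum(nchar(rs$seq)[perm])
  n <- which(cum >= target_bases)[1]
  rs_subset(rs, sort(perm[seq_len(n)]))
}

#' Reverse-complement DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) cpp_revcomp(x)
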