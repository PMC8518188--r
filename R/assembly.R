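# Per-bin hybrid assembly: a built-in desk-scale overlap-layout-consensus
# long-read assembler, a short-read pileup polisher, long-read contig-end
# bridging (contiguity enhancement) and coverage/composition contig filtering
# (bin accuracy promotion). External assemblers plug in through the backend
# contract used by assemble_bin().

oriented_seq <- function(seq, strand) if (strand > 0) seq else cpp_revcomp(seq)

# vertex encoding: read r (1..n), strand +1/-1 -> integer
vtx <- function(r, s) 2L * r + (s < 0)
vtx_read <- function(v) v %/% 2L
vtx_strand <- function(v) if (v %% 2L == 0) 1L else -1L
vtx_rc <- function(v) if (v %% 2L == 0) v + 1L else v - 1L

#' Built-in mini overlap-layout-consensus long-read assembler
#'
#' All-vs-all candidate overlaps are found by shared-minimizer diagonal
#' chaining; contained reads are removed; greedy best-overlap non-branching
#' paths are laid out with alignment-refined junctions; circularity is set
#' when a path's ends overlap each other; the layout is polished by an
#' anchored long-read pileup consensus. Coverage is recorded from minimizer
#' read assignment to the final contigs.
#'
#' @param long a long-read ReadSet (>= 1 read).
#' @param min_overlap minimum usable overlap (bp, default 500).
#' @param min_chain_score minimum chained minimizer count (default 10).
#' @param k,w overlap-detection minimizer parameters (default 11, 5).
#' @param max_occ repeat-masking occurrence cap for overlap seeds.
#' @param consensus_rounds long-read pileup consensus rounds (default 2).
#' @param contain_tol containment overhang tolerance (bp).
#' @param min_density minimum chained-minimizer density (score per overlap
#'   bp); overlaps below it (typical of reads from diverged genomes) are
#'   ignored for containment and layout.
#' @return a ContigSet with `coverage` and `circular` set.
#' @export
mini_olc_assemble <- function(long, min_overlap = 500, min_chain_score = 10,
                              k = 11, w = 5, max_occ = 60,
                              consensus_rounds = 2, contain_tol = 150,
                              min_density = 0.009) {
  n <- length(long)
  if (n < 1) stop("no long reads to assemble")
  seqs <- long$seq
  lens <- nchar(seqs)
  ov <- if (n > 1) {
    cpp_find_overlaps(seqs, k, w, max_occ, 150L, min_chain_score, min_overlap)
  } else {
    data.frame(a = integer(), b = integer(), orient = integer(),
               diag = integer(), ov_len = integer(), score = integer(),
               span = integer())
  }
  ov <- ov[ov$score >= min_density * ov$ov_len, , drop = FALSE]
  # --- containment -----------------------------------------------------------
  contained <- rep(FALSE, n)
  container <- rep(NA_integer_, n)
  if (nrow(ov)) {
    o <- order(-ov$ov_len, -ov$score, ov$a, ov$b)
    for (i in o) {
      a <- ov$a[i]; b <- ov$b[i]; d <- ov$diag[i]
      la <- lens[a]; lb <- lens[b]
      b_in_a <- d >= -contain_tol && d + lb <= la + contain_tol
      a_in_b <- d <= contain_tol && d + lb >= la - contain_tol
      if (b_in_a && a_in_b) { # near-equal: contain the later index
        if (!contained[b]) { contained[b] <- TRUE; container[b] <- a }
      } else if (b_in_a) {
        if (!contained[b]) { contained[b] <- TRUE; container[b] <- a }
      } else if (a_in_b) {
        if (!contained[a]) { contained[a] <- TRUE; container[a] <- b }
      }
    }
  }
  # --- dovetail edges --------------------------------------------------------
  edges <- NULL
  if (nrow(ov)) {
    keep <- !contained[ov$a] & !contained[ov$b]
    dv <- ov[keep, , drop = FALSE]
    if (nrow(dv)) {
      s_b <- ifelse(dv$orient == 0, 1L, -1L)
      u <- integer(0); v <- integer(0); ol <- integer(0); sc <- integer(0)
      for (i in seq_len(nrow(dv))) {
        a <- dv$a[i]; b <- dv$b[i]; d <- dv$diag[i]
        if (d > 0) { # suffix of a+ overlaps prefix of oriented b
          u <- c(u, vtx(a, 1L)); v <- c(v, vtx(b, s_b[i]))
        } else if (d < 0) { # suffix of oriented b overlaps prefix of a+
          u <- c(u, vtx(b, s_b[i])); v <- c(v, vtx(a, 1L))
        } else next
        ol <- c(ol, dv$ov_len[i]); sc <- c(sc, dv$score[i])
      }
      edges <- data.frame(u = u, v = v, ov = ol, score = sc)
    }
  }
  # --- greedy best-overlap path construction --------------------------------
  succ <- new.env(parent = emptyenv())
  pred <- new.env(parent = emptyenv())
  out_used <- rep(FALSE, 2 * n + 2)
  in_used <- rep(FALSE, 2 * n + 2)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  closures <- list()
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[order(-edges$ov, -edges$score, edges$u, edges$v), ]
    for (i in seq_len(nrow(edges))) {
      u <- edges$u[i]; v <- edges$v[i]
      ru <- vtx_read(u); rv <- vtx_read(v)
      if (ru == rv) next
      if (out_used[u] || in_used[v] || out_used[vtx_rc(v)] ||
          in_used[vtx_rc(u)]) next
      if (find(ru) == find(rv)) {
        # would close a cycle: keep as a circularization candidate
        closures[[length(closures) + 1]] <- list(u = u, v = v,
                                                 ov = edges$ov[i])
        out_used[u] <- TRUE; in_used[v] <- TRUE
        out_used[vtx_rc(v)] <- TRUE; in_used[vtx_rc(u)] <- TRUE
        next
      }
      out_used[u] <- TRUE; in_used[v] <- TRUE
      out_used[vtx_rc(v)] <- TRUE; in_used[vtx_rc(u)] <- TRUE
      assign(as.character(u), c(v, edges$ov[i]), envir = succ)
      assign(as.character(vtx_rc(v)), c(vtx_rc(u), edges$ov[i]), envir = succ)
      assign(as.character(v), u, envir = pred)
      assign(as.character(vtx_rc(u)), vtx_rc(v), envir = pred)
      parent[find(ru)] <- find(rv)
    }
  }
  closure_map <- new.env(parent = emptyenv())
  for (cl in closures) assign(as.character(cl$u), cl, envir = closure_map)
  # --- extract paths ---------------------------------------------------------
  visited <- rep(FALSE, n)
  paths <- list()
  for (r in seq_len(n)) {
    if (visited[r] || contained[r]) next
    # walk back to the path head from (r, +)
    start <- vtx(r, 1L)
    seen <- c(vtx_read(start))
    repeat {
      p <- mget(as.character(start), envir = pred, ifnotfound = list(NULL))[[1]]
      if (is.null(p) || vtx_read(p) %in% seen) break
      start <- p
      seen <- c(seen, vtx_read(p))
    }
    verts <- start
    ovs <- integer(0)
    cur <- start
    repeat {
      nx <- mget(as.character(cur), envir = succ, ifnotfound = list(NULL))[[1]]
      if (is.null(nx) || vtx_read(nx[1]) %in% vtx_read(verts)) break
      verts <- c(verts, nx[1])
      ovs <- c(ovs, nx[2])
      cur <- nx[1]
    }
    visited[vtx_read(verts)] <- TRUE
    # circular closure from tail to head?
    circ_ov <- NA_integer_
    cl <- mget(as.character(cur), envir = closure_map,
               ifnotfound = list(NULL))[[1]]
    if (!is.null(cl) && cl$v == start && length(verts) > 1) circ_ov <- cl$ov
    paths[[length(paths) + 1]] <- list(verts = verts, ovs = ovs,
                                       circ_ov = circ_ov)
  }
  # --- layout ----------------------------------------------------------------
  # junction acceptance: two error-prone reads of one template align at an
  # edit fraction well below this; spurious overlaps between diverged
  # genomes land above it and split the path there
  junction_max_edit <- 0.28
  layout_one <- function(p) {
    verts <- p$verts
    segs <- list()
    seq_out <- oriented_seq(seqs[vtx_read(verts[1])], vtx_strand(verts[1]))
    if (length(verts) > 1) {
      for (i in seq_along(p$ovs)) {
        nxt <- oriented_seq(seqs[vtx_read(verts[i + 1])],
                            vtx_strand(verts[i + 1]))
        ovl <- p$ovs[i]
        la <- nchar(seq_out)
        tlen <- min(la, ovl + 600L)
        tail_a <- substr(seq_out, la - tlen + 1, la)
        hb <- min(400L, nchar(nxt))
        loc <- cpp_locate_prefix(substr(nxt, 1, hb), tail_a)
        ok <- loc$edits <= junction_max_edit * hb &&
          abs(loc$rstart - (tlen - ovl)) <= 350
        if (ok) {
          cut <- la - tlen + loc$rstart
          seq_out <- paste0(substr(seq_out, 1, cut), nxt)
        } else { # reject the junction: close this contig, start a new one
          segs[[length(segs) + 1]] <- list(seq = seq_out, circular = FALSE)
          seq_out <- nxt
        }
      }
    }
    circular <- FALSE
    if (!is.na(p$circ_ov) && !length(segs)) {
      la <- nchar(seq_out)
      tlen <- min(la - 1L, p$circ_ov + 600L)
      tail_a <- substr(seq_out, la - tlen + 1, la)
      hb <- min(400L, la)
      loc <- cpp_locate_prefix(substr(seq_out, 1, hb), tail_a)
      if (loc$edits <= junction_max_edit * hb &&
          abs(loc$rstart - (tlen - p$circ_ov)) <= 350) {
        seq_out <- substr(seq_out, 1, la - tlen + loc$rstart)
        circular <- TRUE
      }
    }
    segs[[length(segs) + 1]] <- list(seq = seq_out, circular = circular)
    segs
  }
  laid <- do.call(c, lapply(paths, layout_one))
  # a path that walks a circular replicon past its origin duplicates the
  # start near the end; detect the wrap by locating the contig head again
  # downstream and trim to one turn
  wrap_trim <- function(l) {
    if (l$circular) return(l)
    L <- nchar(l$seq)
    if (L < 6000) return(l)
    hb <- 400L
    off <- 1200L
    region <- substr(l$seq, off + 1, L)
    loc <- cpp_locate_prefix(substr(l$seq, 1, hb), region)
    if (loc$edits <= 0.3 * hb && off + loc$rstart >= 1000 &&
        off + loc$rstart < L - 200) {
      l$seq <- substr(l$seq, 1, off + loc$rstart)
      l$circular <- TRUE
    }
    l
  }
  laid <- lapply(laid, wrap_trim)
  contigs <- contig_set(sprintf("ctg_%03d", seq_along(laid)),
                        vapply(laid, `[[`, character(1), "seq"),
                        coverage = 1,
                        circular = vapply(laid, `[[`, logical(1), "circular"))
  # --- drop redundant parallel contigs --------------------------------------
  contigs <- dedup_contigs(contigs)
  # --- consensus -------------------------------------------------------------
  for (r in seq_len(consensus_rounds)) {
    contigs$seq <- vapply(contigs$seq, function(s) {
      cpp_pileup_polish(s, seqs, 13L, 30L, 2L, 0.5, 4L)$seq
    }, character(1), USE.NAMES = FALSE)
  }
  contigs$coverage <- contig_coverage(contigs, long)
  contigs
}

# greedy OLC without transitive reduction can lay out two parallel paths over
# one replicon; drop contigs almost fully contained in (or duplicating) a
# longer contig of the same assembly
dedup_contigs <- function(contigs, min_frac = 0.8, circ_frac = 0.3,
                          min_density = 0.006) {
  n <- nrow(contigs)
  if (n < 2) return(contigs)
  ov <- cpp_find_overlaps(contigs$seq, 11L, 5L, 120L, 200L, 20L, 1000L)
  if (!nrow(ov)) return(contigs)
  # density gate: parallel drafts of one template share dense minimizer
  # chains; diverged genomes only sparse ones
  ov <- ov[ov$score >= min_density * ov$ov_len, , drop = FALSE]
  if (!nrow(ov)) return(contigs)
  lens <- nchar(contigs$seq)
  drop <- rep(FALSE, n)
  ov <- ov[order(-ov$ov_len), , drop = FALSE]
  for (i in seq_len(nrow(ov))) {
    a <- ov$a[i]; b <- ov$b[i]
    if (drop[a] || drop[b]) next
    # rotated circular duplicates only chain along one arc, so a lower
    # overlap fraction suffices when both contigs are circular
    frac <- if (contigs$circular[a] && contigs$circular[b]) circ_frac
            else min_frac
    if (ov$ov_len[i] >= frac * min(lens[a], lens[b])) {
      drop[if (lens[a] < lens[b]) a else b] <- TRUE
    }
  }
  out <- contigs[!drop, , drop = FALSE]
  class(out) <- c("ContigSet", "data.frame")
  out
}

# mean long-read depth per contig by minimizer assignment
contig_coverage <- function(contigs, long) {
  if (!length(long)) return(rep(0, nrow(contigs)))
  pseudo <- lapply(seq_len(nrow(contigs)), function(i) {
    list(bin_id = contigs$id[i], contig_ids = contigs$id[i], centroid = NULL,
         long_read_ids = character(), short_read_ids = character())
  })
  idx <- build_minimizer_index(pseudo, contigs, k = 15, w = 10)
  asg <- assign_reads(long, idx, min_score = 3, tie_ratio = 0.99,
                      min_score_frac = 0.006)
  bases <- tapply(nchar(long$seq), factor(asg$bin_id, levels = contigs$id),
                  sum, default = 0)
  as.numeric(bases) / nchar(contigs$seq)
}

#' Polish contigs with accurate short reads
#'
#' Short reads are anchored to the draft by unique `k_anchor`-mers, locally
#' aligned in a +-`band` bp band, and per-column pileup votes (including
#' insertion and deletion calls) are applied when supported by at least
#' `min_depth` reads with at least `min_frac` agreement. Regions without
#' anchored coverage are left unchanged.
#'
#' @param contigs a ContigSet (or a single character sequence).
#' @param short a short-read ReadSet.
#' @param rounds polish iterations (default 2).
#' @param k_anchor anchor k-mer size (default 21).
#' @param band alignment band (bp, default 20).
#' @param min_depth,min_frac vote thresholds (default 3 reads, 0.7).
#' @return same shape as `contigs`, polished.
#' @export
polish_with_short_reads <- function(contigs, short, rounds = 2,
                                    k_anchor = 21, band = 20,
                                    min_depth = 3, min_frac = 0.7) {
  single <- is.character(contigs)
  seqs <- if (single) contigs else contigs$seq
  if (length(short) == 0) {
    warning("no short reads; drafts returned unchanged")
    return(contigs)
  }
  for (r in seq_len(rounds)) {
    res <- lapply(seqs, function(s) {
      cpp_pileup_polish(s, short$seq, as.integer(k_anchor), as.integer(band),
                        as.integer(min_depth), min_frac, 2L)
    })
    anchored <- vapply(res, `[[`, numeric(1), "n_anchored")
    if (all(anchored == 0)) {
      warning("no short reads anchored to draft; returned unchanged")
      break
    }
    seqs <- vapply(res, `[[`, character(1), "seq")
  }
  if (single) return(seqs)
  contigs$seq <- seqs
  contigs
}

# contig placements of one read in read-forward coordinates
read_contig_spans <- function(ovrow, lens_contig, lens_read) {
  lc <- lens_contig[ovrow$a]
  lr <- lens_read
  d <- ovrow$diag
  a0 <- max(0L, d); a1 <- min(lc, d + lr)       # contig interval
  r0p <- max(0L, -d); r1p <- min(lr, lc - d)    # oriented-read interval
  if (ovrow$orient == 1) {
    r0 <- lr - r1p; r1 <- lr - r0p; strand <- -1L
  } else {
    r0 <- r0p; r1 <- r1p; strand <- 1L
  }
  list(c0 = a0, c1 = a1, r0 = r0, r1 = r1, strand = strand)
}

#' Enhance contiguity by long-read bridging of contig ends
#'
#' Pairs of contig ends consistently spanned by at least `min_bridges` long
#' reads (each anchored over at least `min_overlap` bp on both contigs, with
#' consistent orientation and ordering) are merged; the junction gap is
#' filled with the best bridging read's subsequence. A read spanning one
#' contig's two ends circularizes it. Conflicting orderings for the same
#' contig pair cancel the merge. N50 never decreases.
#'
#' @param contigs a ContigSet (polished).
#' @param long the bin's long-read ReadSet.
#' @param min_bridges minimum supporting reads (default 3).
#' @param min_overlap minimum anchoring on each contig (bp, default 500).
#' @param end_tol how close to a contig end an alignment must reach (bp).
#' @return a ContigSet.
#' @export
improve_contiguity <- function(contigs, long, min_bridges = 3,
                               min_overlap = 500, end_tol = 150) {
  nc <- nrow(contigs)
  if (nc == 0 || !length(long)) return(contigs)
  seqs <- c(contigs$seq, long$seq)
  ov <- cpp_find_overlaps(seqs, 11L, 5L, 60L, 150L, 10L,
                          as.integer(min_overlap))
  if (!nrow(ov)) return(contigs)
  ov <- ov[ov$a <= nc & ov$b > nc & ov$score >= 0.009 * ov$ov_len, ,
           drop = FALSE]
  if (!nrow(ov)) return(contigs)
  lens_c <- nchar(contigs$seq)
  # collect end-spanning placements per read
  placements <- split(seq_len(nrow(ov)), ov$b)
  junctions <- list()
  add_j <- function(key, read, e1, s2, best) {
    j <- junctions[[key]]
    if (is.null(j)) j <- list(n = 0L, reads = list())
    j$n <- j$n + 1L
    j$reads[[length(j$reads) + 1]] <- list(read = read, e1 = e1, s2 = s2,
                                           anchored = best)
    junctions[[key]] <<- j
  }
  for (bname in names(placements)) {
    rows <- placements[[bname]]
    ridx <- ov$b[rows[1]] - nc
    lr <- nchar(long$seq[ridx])
    sp <- lapply(rows, function(i) {
      s <- read_contig_spans(ov[i, ], lens_c, lr)
      s$contig <- ov$a[i]
      s
    })
    # order placements along the read
    sp <- sp[order(vapply(sp, `[[`, numeric(1), "r0"))]
    if (length(sp) == 1 && contigs$circular[sp[[1]]$contig]) next
    for (i in seq_along(sp)) {
      for (j in seq_along(sp)) {
        if (i == j && length(sp) > 1) next
        A <- sp[[i]]; B <- sp[[j]]
        if (i == j) { # potential self-circularization: need two placements
          next
        }
        if (B$r0 < A$r1 - 2000) next   # wrong order / too much overlap
        if (B$r0 > A$r1 + 50000) next
        # A must reach its downstream end, B its upstream end
        okA <- if (A$strand > 0) A$c1 >= lens_c[A$contig] - end_tol
               else A$c0 <= end_tol
        okB <- if (B$strand > 0) B$c0 <= end_tol
               else B$c1 >= lens_c[B$contig] - end_tol
        if (!okA || !okB) next
        key <- paste(A$contig, A$strand, B$contig, B$strand, sep = ":")
        add_j(key, ridx, A$r1, B$r0, min(A$c1 - A$c0, B$c1 - B$c0))
      }
    }
    # self-circularization: one read hitting both ends of the same contig
    if (length(sp) >= 2) {
      for (i in seq_along(sp)) for (j in seq_along(sp)) {
        if (i == j) next
        A <- sp[[i]]; B <- sp[[j]]
        if (A$contig != B$contig || A$strand != B$strand) next
        if (B$r0 < A$r1 - 2000) next
        okA <- if (A$strand > 0) A$c1 >= lens_c[A$contig] - end_tol
               else A$c0 <= end_tol
        okB <- if (B$strand > 0) B$c0 <= end_tol
               else B$c1 >= lens_c[B$contig] - end_tol
        if (okA && okB) {
          add_j(paste("circ", A$contig, sep = ":"), ridx, A$r1, B$r0, 0)
        }
      }
    }
  }
  if (!length(junctions)) return(contigs)
  support <- vapply(junctions, `[[`, integer(1), "n")
  # conflicting orderings for a pair cancel each other
  keys <- names(junctions)
  drop <- rep(FALSE, length(keys))
  parse_key <- function(k) strsplit(k, ":", fixed = TRUE)[[1]]
  for (i in seq_along(keys)) {
    p <- parse_key(keys[i])
    if (p[1] == "circ") next
    rev_key <- paste(p[3], -as.integer(p[4]), p[1], -as.integer(p[2]),
                     sep = ":")
    alt_key <- paste(p[3], p[4], p[1], p[2], sep = ":")
    for (other in c(alt_key)) {
      oi <- match(other, keys)
      if (!is.na(oi) && support[oi] >= min_bridges &&
          support[i] >= min_bridges) {
        drop[i] <- TRUE
      }
    }
    # a key and its reverse-complement describe the same junction; dedupe
    oi <- match(rev_key, keys)
    if (!is.na(oi) && oi < i) drop[i] <- TRUE
  }
  ordk <- order(-support)
  used_end <- character()
  merged_away <- integer()
  out <- contigs
  for (i in ordk) {
    if (drop[i] || support[i] < min_bridges) next
    p <- parse_key(keys[i])
    best <- junctions[[i]]$reads[[which.max(vapply(junctions[[i]]$reads,
                                                   `[[`, numeric(1),
                                                   "anchored"))]]
    rseq <- long$seq[best$read]
    if (p[1] == "circ") {
      ci <- as.integer(p[2])
      if (ci %in% merged_away || out$circular[ci]) next
      res <- splice_junction(out$seq[ci], out$seq[ci], rseq, best$e1, best$s2,
                             circular = TRUE)
      if (is.null(res)) next
      out$seq[ci] <- res
      out$circular[ci] <- TRUE
      next
    }
    c1 <- as.integer(p[1]); s1 <- as.integer(p[2])
    c2 <- as.integer(p[3]); s2 <- as.integer(p[4])
    if (c1 %in% merged_away || c2 %in% merged_away || c1 == c2) next
    e1key <- paste(c1, "down", s1); e2key <- paste(c2, "up", s2)
    ends <- c(paste(c1, if (s1 > 0) "R" else "L"),
              paste(c2, if (s2 > 0) "L" else "R"))
    if (any(ends %in% used_end)) next
    if (out$circular[c1] || out$circular[c2]) next
    sA <- oriented_seq(out$seq[c1], s1)
    sB <- oriented_seq(out$seq[c2], s2)
    res <- splice_junction(sA, sB, rseq, best$e1, best$s2, circular = FALSE)
    if (is.null(res)) next
    used_end <- c(used_end, ends)
    wl <- nchar(out$seq[c(c1, c2)])
    out$seq[c1] <- res
    out$coverage[c1] <- sum(out$coverage[c(c1, c2)] * wl) / sum(wl)
    merged_away <- c(merged_away, c2)
  }
  if (length(merged_away)) out <- out[-merged_away, , drop = FALSE]
  class(out) <- c("ContigSet", "data.frame")
  self_circularize(out)
}

# a contig whose start is duplicated near its end (as after merging the two
# arcs of a circular replicon) is trimmed and flagged circular
self_circularize <- function(contigs, head_bp = 400L, max_ov = 4000L) {
  for (i in seq_len(nrow(contigs))) {
    if (contigs$circular[i]) next
    L <- nchar(contigs$seq[i])
    if (L < 6000) next
    tl <- min(max_ov, L - 1000L)
    tail_s <- substr(contigs$seq[i], L - tl + 1, L)
    loc <- cpp_locate_prefix(substr(contigs$seq[i], 1, head_bp), tail_s)
    if (loc$edits <= 0.1 * head_bp && loc$rstart < tl - 50) {
      contigs$seq[i] <- substr(contigs$seq[i], 1, L - tl + loc$rstart)
      contigs$circular[i] <- TRUE
    }
  }
  contigs
}

# splice two oriented contigs (or one, circularizing) across a bridging read;
# e1/s2 are approximate read-forward coordinates where A ends and B starts
splice_junction <- function(sA, sB, rseq, e1, s2, circular = FALSE) {
  lr <- nchar(rseq)
  tailA <- substr(sA, max(1, nchar(sA) - 400 + 1), nchar(sA))
  w1 <- c(max(0, e1 - 900), min(lr, e1 + 300))
  loc1 <- cpp_locate_prefix(tailA, substr(rseq, w1[1] + 1, w1[2]))
  if (loc1$edits > 0.45 * nchar(tailA)) return(NULL)
  re <- w1[1] + loc1$rend            # read pos where A ends
  headB <- substr(sB, 1, min(400, nchar(sB)))
  w2 <- c(max(0, s2 - 300), min(lr, s2 + 900))
  loc2 <- cpp_locate_prefix(headB, substr(rseq, w2[1] + 1, w2[2]))
  if (loc2$edits > 0.45 * nchar(headB)) return(NULL)
  rs <- w2[1] + loc2$rstart          # read pos where B starts
  if (circular) {
    # B is the same contig; overlap of end onto start trims the end
    if (rs >= re) {
      return(paste0(sA, substr(rseq, re + 1, rs)))
    }
    ovl <- re - rs
    if (ovl >= nchar(sA)) return(NULL)
    return(substr(sA, 1, nchar(sA) - ovl))
  }
  if (rs >= re) {
    return(paste0(sA, substr(rseq, re + 1, rs), sB))
  }
  ovl <- re - rs
  if (ovl >= nchar(sB)) return(NULL)
  paste0(sA, substr(sB, ovl + 1, nchar(sB)))
}

#' Promote bin accuracy by dropping outlier contigs
#'
#' Contigs whose phased long-read coverage deviates from the bin median by
#' more than `cov_mad_limit` robust MADs, or whose tetranucleotide profile
#' sits further than `tnf_dist_limit` (Euclidean, frequency scale) from the
#' bin's length-weighted centroid, are removed and returned separately so the
#' caller can return them to the leftover pool.
#'
#' @param contigs a ContigSet.
#' @param long the bin's phased long reads (for coverage).
#' @param cov_mad_limit robust MAD multiple (default 3.5).
#' @param tnf_dist_limit TNF distance limit (default 0.12).
#' @param cov_min_frac also drop contigs below this fraction of the bin's
#'   maximum contig coverage; catches stray low-coverage contigs in bins too
#'   small for the median/MAD statistic to be meaningful (default 0.15).
#' @return list with `contigs` (kept) and `dropped` (ContigSet).
#' @export
promote_bin <- function(contigs, long, cov_mad_limit = 3.5,
                        tnf_dist_limit = 0.12, cov_min_frac = 0.15) {
  if (nrow(contigs) == 0) stop("empty bin")
  cov <- contig_coverage(contigs, long)
  med <- median(cov)
  md <- mad(cov)
  scale <- max(md, 0.1 * med, 1e-9)
  cov_ok <- abs(cov - med) <= cov_mad_limit * scale
  cov_ok <- cov_ok & cov >= cov_min_frac * max(cov)
  tnf <- t(vapply(contigs$seq, tnf_profile, numeric(136), USE.NAMES = FALSE))
  # per-dimension median centroid: robust to a minority of contaminant
  # contigs that would drag a length-weighted mean
  centroid <- apply(tnf, 2, median)
  tnf_d <- sqrt(rowSums((tnf - matrix(centroid, nrow(tnf), 136,
                                      byrow = TRUE))^2))
  tnf_ok <- tnf_d <= tnf_dist_limit
  keep <- cov_ok & tnf_ok
  if (!any(keep)) stop("bin collapse: all contigs dropped by promotion")
  kept <- contigs[keep, , drop = FALSE]
  dropped <- contigs[!keep, , drop = FALSE]
  kept$coverage <- cov[keep]
  class(kept) <- class(dropped) <- c("ContigSet", "data.frame")
  list(contigs = kept, dropped = dropped)
}

#' Assemble one candidate bin (backend, polish, bridge, promote)
#'
#' Orchestrates the hybrid assembly of a single bin: the long-read backend,
#' short-read polishing, contig-end bridging, bin promotion, and a final
#' polish round after merging. A backend failure marks the bin failed
#' without stopping the pipeline.
#'
#' @param long,short the bin's phased ReadSets.
#' @param backend `"mini_olc"` or a function
#'   `(long, short, config) -> ContigSet` honouring the backend contract.
#' @param config pipeline configuration (see [default_config()]).
#' @return list with `status` (`"ok"`/`"failed"`), `contigs`, `dropped`,
#'   and `message` on failure.
#' @export
assemble_bin <- function(long, short, backend = "mini_olc",
                         config = default_config()) {
  ac <- config$assembly
  if (length(long) < ac$min_long_reads) {
    return(list(status = "failed", contigs = NULL, dropped = NULL,
                message = sprintf("too few long reads (%d < %d)",
                                  length(long), ac$min_long_reads)))
  }
  run <- function() {
    contigs <- if (is.function(backend)) {
      backend(long, short, config)
    } else {
      mini_olc_assemble(long, min_overlap = ac$min_overlap,
                        min_chain_score = ac$min_chain_score,
                        consensus_rounds = ac$consensus_rounds)
    }
    contigs <- polish_with_short_reads(contigs, short,
                                       rounds = ac$polish_rounds)
    contigs <- improve_contiguity(contigs, long,
                                  min_bridges = ac$min_bridges)
    pr <- promote_bin(contigs, long, cov_mad_limit = ac$cov_mad_limit,
                      tnf_dist_limit = ac$tnf_dist_limit)
    contigs <- polish_with_short_reads(pr$contigs, short,
                                       rounds = ac$final_polish_rounds)
    list(status = "ok", contigs = contigs, dropped = pr$dropped,
         message = NULL)
  }
  tryCatch(suppressWarnings(run()), error = function(e) {
    list(status = "failed", contigs = NULL, dropped = NULL,
         message = conditionMessage(e))
  })
}
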