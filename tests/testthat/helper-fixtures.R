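# shared fixture helpers: small deterministic sequences and communities

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only mutated copy with the realized identity attached
mutated_copy <- function(seq, rate, seed = 1) {
  set.seed(seed)
  mut <- hcbha:::cpp_mutate_seqs(seq, rate, 0, 0)
  structure(mut$seq[[1]], identity = 1 - mut$n_sub[1] / nchar(seq))
}

# tiling error-free reads over a (circular) genome
tiling_reads <- function(genome, read_len, step, circular = FALSE) {
  L <- nchar(genome)
  g2 <- if (circular) paste0(genome, genome) else genome
  starts <- seq(1, if (circular) L else max(1, L - read_len + 1), by = step)
  seqs <- substring(g2, starts, starts + read_len - 1)
  seqs <- seqs[nchar(seqs) == read_len]
  read_set(sprintf("t%04d", seq_along(seqs)), seqs, platform = "long")
}

# quick community + hybrid reads fixture
sim_fixture <- function(n_genomes = 3, len = c(20000, 30000), ani = 0.80,
                        long_depth = 30, short_depth = 60, seed = 42) {
  spec <- community_spec(n_genomes, len, target_ani = ani, seed = seed)
  cm <- generate_community(spec)
  lr <- simulate_long_reads(cm$truth, depth = long_depth, seed = seed + 1)
  sr <- simulate_short_reads(lr$truth, depth = short_depth, seed = seed + 2)
  list(truth = sr$truth, genomes = cm$genomes, long = lr$reads,
       short = sr$reads)
}

read_genome_of <- function(rs, truth) {
  truth$reads$genome[match(rs$id, truth$reads$read_id)]
}
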