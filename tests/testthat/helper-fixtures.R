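# shared fixtures: all built in code at test time

BASES <- c("A", "C", "G", "T")

# independent per-site brute-force consensus evaluator (plain conditional
# logic, no shared code with call_consensus)
brute_consensus_site <- function(counts, min_depth = 3, min_dominant_freq = 0.80) {
  depth <- sum(counts)
  if (depth < min_depth) return("-")
  mx <- max(counts)
  if (sum(counts == mx) != 1L) return("-")
  if (mx / depth < min_dominant_freq) return("-")
  BASES[which.max(counts)]
}

random_pileup <- function(L, seed, lambda = 1.2) {
  set.seed(seed)
  counts <- matrix(rpois(4L * L, lambda), 4L, L, dimnames = list(BASES, NULL))
  structure(list(ref_id = "r", length = L, counts = counts,
                 depth = as.integer(colSums(counts))),
            class = "pileup")
}

# one ungapped alignment row
make_aln <- function(read_id, ref_start, seq, strand = "+", mapq = 60L,
                     sample = "s", ref_id = "r") {
  out <- data.frame(read_id = read_id, sample = sample, ref_id = ref_id,
                    ref_start = as.integer(ref_start), strand = strand,
                    mapq = as.integer(mapq),
                    cigar = sprintf("%dM", nchar(seq)), seq = seq,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_alignments", "data.frame")
  out
}

bind_aln <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("read_alignments", "data.frame")
  out
}

msa_from_rows <- function(rows, ref_id = "r") {
  structure(list(ref_id = ref_id,
                 column_coords = seq_len(nchar(rows[[1]])) - 1L,
                 rows = unlist(rows)), class = "ref_msa")
}

msa_from_genomes <- function(genomes, ref_id = "r") {
  msa_from_rows(genomes, ref_id = ref_id)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(BASES, n, replace = TRUE), collapse = "")
}

unrooted_rf <- function(t1, t2) phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))

# the constructed recombination scenario: 7 strains in a 5+2 clade structure,
# a 2 kb host-to-host import (nu = 0.05) from the small clade into the large
# one, spanning half of a 4 kb alignment
recomb_scenario <- function(seed) {
  tre <- paste0("(((a:0.43,b:0.43):0.43,(c:0.43,(d:0.215,e:0.215):0.215):0.43)",
                ":0.14,(f:0.86,g:0.86):0.14);")
  p <- sim_params(genome_length = 4000, n_species = 1,
                  n_strains_per_species = 7,
                  within_species_divergence = 0.05, mean_tract_length = 400,
                  depth_per_strain = 5, seed = seed)
  ss <- simulate_strain_set(p, strain_tree = ape::read.tree(text = tre))
  inj <- inject_recombination(ss$genomes, ss$truth, "sp1_st1", "sp1_st6",
                              1000, 3000, tract_divergence = 0.05)
  list(msa = msa_from_genomes(inj$genomes),
       truth_tree = ss$truth$strain_trees$sp1,
       tract = c(1000, 3000), recipient = "sp1_st1")
}
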