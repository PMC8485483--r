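test_that("parameter validation names the offending field", {
  expect_error(sim_params(gc_content = 1.5), "gc_content")
  expect_error(sim_params(min_fragment_length = 20), "min_fragment_length")
  expect_error(sim_params(genome_length = 5000, mean_tract_length = 2000),
               "genome_length")
  expect_error(sim_params(damage_rate_5p = -0.1), "damage_rate_5p")
  expect_error(sim_params(depth_per_strain = 0), "depth_per_strain")
})

test_that("zero divergence and zero recombination give identical strains", {
  p <- sim_params(genome_length = 20000, n_species = 1,
                  n_strains_per_species = 4, within_species_divergence = 0,
                  recomb_rate_per_branch = 0, seed = 3)
  ss <- simulate_strain_set(p)
  expect_length(unique(ss$genomes), 1L)
  expect_equal(nrow(ss$truth$mutations), 0L)
})

test_that("pairwise strain divergence matches the closed-form expectation", {
  # two strains at within-divergence w diverge by the JC-expected mismatch
  # fraction 3/4 (1 - exp(-4w/3)); averaged over >= 20 seeds
  w <- 0.01; L <- 20000
  obs <- vapply(1:20, function(seed) {
    p <- sim_params(genome_length = L, n_species = 1,
                    n_strains_per_species = 2, within_species_divergence = w,
                    seed = seed)
    ss <- simulate_strain_set(p)
    a <- strsplit(ss$genomes[[1]], "")[[1]]
    b <- strsplit(ss$genomes[[2]], "")[[1]]
    mean(a != b)
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-4 * w / 3))
  se <- sqrt(expected * (1 - expected) / (L * 20))
  expect_lt(abs(mean(obs) - expected), 4 * se)
})

test_that("recombination tracts carry elevated mismatch density at the nu rate", {
  p <- sim_params(genome_length = 40000, n_species = 1,
                  n_strains_per_species = 2, within_species_divergence = 0,
                  recomb_rate_per_branch = 1.5, mean_tract_length = 2000,
                  tract_divergence = 0.05, seed = 8)
  ss <- simulate_strain_set(p)
  tr <- ss$truth$recomb_tracts
  expect_gt(nrow(tr), 0L)
  # with zero clonal divergence the clonal frame is the species root; the
  # only mismatches are inside recorded tracts, at ~ the JC(nu) density
  root_p <- sim_params(genome_length = 40000, n_species = 1,
                       n_strains_per_species = 2,
                       within_species_divergence = 0,
                       recomb_rate_per_branch = 0, seed = 8)
  clonal <- simulate_strain_set(root_p)$genomes[[1]]
  cv <- strsplit(clonal, "")[[1]]
  dens <- vapply(seq_len(nrow(tr)), function(k) {
    sv <- strsplit(ss$genomes[[tr$strain[k]]], "")[[1]]
    idx <- (tr$start[k] + 1L):tr$end[k]
    mean(sv[idx] != cv[idx])
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  expect_true(all(abs(dens - expected) < 0.03))
  # outside all tracts the strains match the clonal frame exactly
  for (g in names(ss$genomes)) {
    sv <- strsplit(ss$genomes[[g]], "")[[1]]
    outside <- rep(TRUE, length(sv))
    gt <- tr[tr$strain == g, , drop = FALSE]
    for (k in seq_len(nrow(gt))) outside[(gt$start[k] + 1L):gt$end[k]] <- FALSE
    expect_true(all(sv[outside] == cv[outside]))
  }
})

test_that("simulation is deterministic and FASTQ output is byte-identical", {
  p <- sim_params(genome_length = 20000, n_species = 1,
                  n_strains_per_species = 2, depth_per_strain = 3, seed = 5)
  s1 <- simulate_strain_set(p); r1 <- simulate_reads(s1$genomes, s1$truth, p)
  s2 <- simulate_strain_set(p); r2 <- simulate_reads(s2$genomes, s2$truth, p)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(r1$reads, r2$reads)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1$reads, f1); write_fastq(r2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("read count matches depth * genome_length / mean fragment length", {
  p <- sim_params(genome_length = 30000, n_species = 1,
                  n_strains_per_species = 1, depth_per_strain = 10, seed = 2)
  sim <- simulate_reads(simulate_strain_set(p)$genomes,
                        simulate_strain_set(p)$truth, p)
  emitted_mean <- mean(nchar(sim$reads$seq))
  expected_n <- p$depth_per_strain * p$genome_length / emitted_mean
  expect_lt(abs(nrow(sim$reads) - expected_n) / expected_n, 0.05)
  expect_true(all(nchar(sim$reads$seq) >= p$min_fragment_length))
})

test_that("clean reads match their source slice; damage is localised C->T/G->A", {
  p <- sim_params(genome_length = 20000, n_species = 1,
                  n_strains_per_species = 1, damage_rate_5p = 0,
                  seq_error = 0, depth_per_strain = 2, seed = 6)
  ss <- simulate_strain_set(p)
  sim <- simulate_reads(ss$genomes, ss$truth, p)
  g <- strsplit(ss$genomes[[1]], "")[[1]]
  rt <- sim$truth$read_truth
  for (i in seq_len(min(nrow(rt), 500L))) {
    slice <- paste0(g[(rt$ref_start[i] + 1L):rt$ref_end[i]], collapse = "")
    aln_seq <- sim$alignments$seq[i]
    expect_identical(aln_seq, slice)   # reference-orientation conservation
  }

  pd <- sim_params(genome_length = 20000, n_species = 1,
                   n_strains_per_species = 1, damage_rate_5p = 0.4,
                   damage_decay = 0.3, seq_error = 0, depth_per_strain = 2,
                   seed = 7)
  ssd <- simulate_strain_set(pd)
  simd <- simulate_reads(ssd$genomes, ssd$truth, pd)
  gd <- strsplit(ssd$genomes[[1]], "")[[1]]
  rtd <- simd$truth$read_truth
  reads <- setNames(simd$reads$seq, simd$reads$read_id)
  for (i in seq_len(min(nrow(rtd), 300L))) {
    slice <- gd[(rtd$ref_start[i] + 1L):rtd$ref_end[i]]
    src_read <- if (rtd$strand[i] == "+") slice else
      unname(rev(c(A = "T", C = "G", G = "C", T = "A")[slice]))
    obs <- strsplit(reads[[rtd$read_id[i]]], "")[[1]]
    mism <- which(obs != src_read)
    recorded <- if (nzchar(rtd$damaged_positions[i]))
      as.integer(strsplit(rtd$damaged_positions[i], ",")[[1]]) else integer(0)
    expect_identical(mism, recorded)
    expect_true(all(src_read[mism] %in% c("C", "G")))
    expect_true(all(obs[mism] == ifelse(src_read[mism] == "C", "T", "A")))
  }
})

test_that("tiling coverage mode guarantees full breadth at the target depth", {
  p <- sim_params(genome_length = 15000, n_species = 1,
                  n_strains_per_species = 1, damage_rate_5p = 0, seq_error = 0,
                  mean_tract_length = 1500, depth_per_strain = 4,
                  coverage_mode = "tiling", seed = 9)
  ss <- simulate_strain_set(p)
  sim <- simulate_reads(ss$genomes, ss$truth, p)
  cov <- integer(p$genome_length)
  for (i in seq_len(nrow(sim$alignments))) {
    idx <- (sim$alignments$ref_start[i] + 1L):
      (sim$alignments$ref_start[i] + nchar(sim$alignments$seq[i]))
    cov[idx] <- cov[idx] + 1L
  }
  expect_true(all(cov >= 4L))
})

test_that("gene families respect designed occupancy and binomial expectation", {
  gs <- setNames(rep(c("spA", "spB"), each = 6), sprintf("g%02d", 1:12))
  full <- simulate_gene_families(5, 1.0, gs, seed = 1)
  expect_true(all(full$truth_matrix))
  occ <- matrix(rep(c(1, 0), each = 3), 3, 2, dimnames = list(NULL, c("spA", "spB")))
  spec <- simulate_gene_families(3, occ, gs, seed = 2)
  expect_true(all(spec$truth_matrix[, gs == "spA"]))
  expect_false(any(spec$truth_matrix[, gs == "spB"]))
  # 200 families at 0.95: count present in > 90% of genomes ~ Binomial
  many <- simulate_gene_families(200, 0.95, gs, seed = 3)
  n_core <- sum(rowMeans(many$truth_matrix) > 0.9)
  pc <- pbinom(10, 12, 0.95, lower.tail = FALSE)   # >10 of 12 genomes
  expect_lt(abs(n_core - 200 * pc), 4 * sqrt(200 * pc * (1 - pc)))
})
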