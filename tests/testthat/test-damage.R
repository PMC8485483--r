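test_that("single-read profiles match hand-computed values", {
  # reference "CT", read "TT": position 1 is a C read as T, position 2 a T
  prof <- misincorporation_profile(make_aln("r1", 0, "TT"), "CTAAA", window = 5)
  expect_equal(prof$ct_5p[1], 1.0)
  expect_true(is.nan(prof$ct_5p[2]))   # no reference C at read position 2
  expect_equal(prof$n_obs_5p[1:2], c(1L, 0L))

  # same molecule on the minus strand: stored seq is reference-oriented, the
  # read 5' end is the right-hand side in reference coordinates
  ref <- "AAGAA"                      # revcomp(read-orientation C at 5' pos 1)
  prof2 <- misincorporation_profile(make_aln("r2", 1, "AA", strand = "-"), ref,
                                    window = 5)
  expect_equal(prof2$ct_5p[1], 1.0)   # ref G + read A on minus = C->T in read
})

test_that("zero-damage reads give an all-zero profile and fail authentication", {
  p <- sim_params(genome_length = 20000, n_species = 1,
                  n_strains_per_species = 1, damage_rate_5p = 0, seq_error = 0,
                  depth_per_strain = 3, seed = 4)
  ss <- simulate_strain_set(p)
  sim <- simulate_reads(ss$genomes, ss$truth, p)
  prof <- misincorporation_profile(sim$alignments, ss$genomes[[1]])
  expect_true(all(prof$ct_5p[prof$n_obs_5p > 0] == 0))
  expect_true(all(prof$ga_3p[prof$n_obs_3p > 0] == 0))
  expect_false(authenticate(prof)$authentic)
})

test_that("authentication decision rule evaluates thresholds exactly", {
  fake <- function(ct1, baseline, n1 = 1000L) {
    structure(list(window = 25L,
                   ct_5p = c(ct1, rep(0, 24)), ga_3p = rep(NaN, 25),
                   n_obs_5p = c(n1, rep(0L, 24)), n_obs_3p = rep(0L, 25),
                   interior_ct_baseline = baseline, interior_n = 10000L),
              class = "damage_profile")
  }
  expect_true(authenticate(fake(0.25, 0.01))$authentic)
  expect_false(authenticate(fake(0.0, 0.001))$authentic)
  expect_false(authenticate(fake(0.04, 0.001))$authentic)  # below 0.05 floor
  expect_false(authenticate(fake(0.10, 0.06))$authentic)   # < 2x baseline
  ins <- authenticate(fake(0.25, 0.01, n1 = 0L))
  expect_true(is.na(ins$authentic))
  expect_equal(ins$status, "insufficient data")
})

test_that("profile of a mixture is the count-weighted pool of the parts", {
  ref <- random_dna(3000, seed = 11)
  p <- sim_params(genome_length = 20000, n_species = 1,
                  n_strains_per_species = 2, damage_rate_5p = 0.3,
                  seq_error = 0.01, depth_per_strain = 2, seed = 12)
  ss <- simulate_strain_set(p)
  sim <- simulate_reads(ss$genomes, ss$truth, p)
  a <- sim$alignments[sim$alignments$sample == "sp1_st1", ]
  b <- sim$alignments[sim$alignments$sample == "sp1_st2", ]
  class(a) <- class(b) <- c("read_alignments", "data.frame")
  refg <- ss$genomes[[1]]
  pa <- misincorporation_profile(a, refg)
  pb <- misincorporation_profile(b, refg)
  pool <- misincorporation_profile(sim$alignments, refg)
  num <- ifelse(pa$n_obs_5p > 0, pa$ct_5p * pa$n_obs_5p, 0) +
         ifelse(pb$n_obs_5p > 0, pb$ct_5p * pb$n_obs_5p, 0)
  den <- pa$n_obs_5p + pb$n_obs_5p
  expect_equal(pool$ct_5p[den > 0], (num / den)[den > 0], tolerance = 1e-12)
  expect_equal(pool$n_obs_5p, den)
})

test_that("reverse-complementing reference and reads swaps ct_5p and ga_3p", {
  p <- sim_params(genome_length = 20000, n_species = 1,
                  n_strains_per_species = 1, damage_rate_5p = 0.3,
                  seq_error = 0.005, depth_per_strain = 2, seed = 13)
  ss <- simulate_strain_set(p)
  sim <- simulate_reads(ss$genomes, ss$truth, p)
  refg <- ss$genomes[[1]]
  L <- nchar(refg)
  aln <- sim$alignments
  fwd <- misincorporation_profile(aln, refg)

  rc <- aln
  lens <- nchar(aln$seq)
  rc$ref_start <- L - (aln$ref_start + lens)
  rc$seq <- vapply(aln$seq, function(s) paleostrain:::revcomp(s), character(1),
                   USE.NAMES = FALSE)
  class(rc) <- c("read_alignments", "data.frame")
  rev_prof <- misincorporation_profile(rc, paleostrain:::revcomp(refg))
  expect_equal(rev_prof$ct_5p, fwd$ga_3p)
  expect_equal(rev_prof$ga_3p, fwd$ct_5p)
  expect_equal(rev_prof$n_obs_5p, fwd$n_obs_3p)
})

test_that("alignments without pairing information raise a format error", {
  bad <- data.frame(read_id = "r", mapq = 60)
  expect_error(misincorporation_profile(bad, "ACGT"), "pairing")
})
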