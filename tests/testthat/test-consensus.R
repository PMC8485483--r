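test_that("read gate applies strict 'below' exclusion semantics", {
  ref <- strrep("A", 100)
  at <- function(mapq, len, nmis) {
    seq <- paste0(c(rep("A", len - nmis), rep("C", nmis)), collapse = "")
    make_aln("r", 0, seq, mapq = mapq)
  }
  # equality at every threshold passes
  expect_true(gate_read(at(30, 30, 0), ref))
  expect_true(gate_read(at(60, 100, 3), ref))     # identity exactly 0.97
  # one unit below each threshold fails
  expect_false(gate_read(at(29, 30, 0), ref))
  expect_false(gate_read(at(60, 29, 0), ref))
  expect_false(gate_read(at(60, 100, 4), ref))    # identity 0.96
})

test_that("pileup accumulates only gated reads at matched columns", {
  ref <- random_dna(200, seed = 21)
  expect_equal(sum(build_pileup(make_aln("r", 0, substr(ref, 1, 40))[0, ],
                                ref)$depth), 0L)
  perfect <- bind_aln(make_aln("r1", 0, substr(ref, 1, 30)),
                      make_aln("r2", 0, substr(ref, 1, 30)),
                      make_aln("r3", 0, substr(ref, 1, 30)),
                      make_aln("r4", 0, substr(ref, 1, 30)),
                      make_aln("r5", 0, substr(ref, 1, 30)))
  pu <- build_pileup(perfect, ref)
  expect_equal(pu$depth[1:30], rep(5L, 30))
  expect_equal(pu$depth[31:200], rep(0L, 170))
  # a low-mapq read among perfect ones contributes nothing
  with_bad <- bind_aln(perfect, make_aln("bad", 50, substr(ref, 51, 90),
                                         mapq = 10))
  pu2 <- build_pileup(with_bad, ref)
  expect_equal(pu2$depth[51:90], rep(0L, 40))
  expect_equal(pu2$counts, pu$counts)
})

test_that("pileup rejects alignments against a different reference", {
  aln <- make_aln("r", 0, "ACGTACGTACGTACGTACGTACGTACGTAC", ref_id = "other")
  expect_error(build_pileup(aln, strrep("A", 50), ref_id = "main"),
               "other.*main")
})

test_that("consensus calling honours depth, dominance and tie rules", {
  mk <- function(a, c, g, t) {
    counts <- matrix(c(a, c, g, t), 4, 1, dimnames = list(BASES, NULL))
    structure(list(ref_id = "r", length = 1L, counts = counts,
                   depth = as.integer(sum(counts))), class = "pileup")
  }
  expect_equal(call_consensus(mk(2, 0, 0, 0))$sequence, "-")   # depth 2 < 3
  expect_equal(call_consensus(mk(3, 0, 0, 0))$sequence, "A")   # depth 3 passes
  expect_equal(call_consensus(mk(8, 0, 2, 0))$sequence, "A")   # freq 0.80 passes
  expect_equal(call_consensus(mk(79, 0, 21, 0))$sequence, "-") # freq 0.79
  expect_equal(call_consensus(mk(5, 0, 5, 0))$sequence, "-")   # tie: no dominant
})

test_that("consensus matches the brute-force site evaluator on random pileups", {
  for (seed in 1:25) {
    pu <- random_pileup(2000, seed)
    got <- strsplit(call_consensus(pu)$sequence, "")[[1]]
    want <- vapply(seq_len(pu$length),
                   function(i) brute_consensus_site(pu$counts[, i]),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("raising thresholds never converts a gap into a base", {
  pu <- random_pileup(3000, 99)
  base <- strsplit(call_consensus(pu, 3, 0.80)$sequence, "")[[1]]
  deeper <- strsplit(call_consensus(pu, 5, 0.80)$sequence, "")[[1]]
  stricter <- strsplit(call_consensus(pu, 3, 0.95)$sequence, "")[[1]]
  expect_true(all(deeper == base | deeper == "-"))
  expect_true(all(stricter == base | stricter == "-"))
})

test_that("breadth and presence follow the inclusive depth-3 reading", {
  mkdepth <- function(depth_vec) {
    counts <- matrix(0L, 4L, length(depth_vec), dimnames = list(BASES, NULL))
    counts[1L, ] <- as.integer(depth_vec)
    structure(list(ref_id = "r", length = length(depth_vec), counts = counts,
                   depth = as.integer(depth_vec)), class = "pileup")
  }
  expect_equal(breadth_of_coverage(mkdepth(rep(10, 100))), 1.0)
  expect_true(detect_presence(1.0))
  half <- mkdepth(c(rep(3, 50), rep(0, 50)))
  expect_equal(breadth_of_coverage(half), 0.5)
  expect_true(detect_presence(0.5))          # >= 50% is present
  expect_equal(breadth_of_coverage(mkdepth(rep(2, 100))), 0.0)
  expect_false(detect_presence(0.0))
  expect_error(breadth_of_coverage(mkdepth(integer(0))), "zero-length")
})
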