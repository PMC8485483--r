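test_that("local hits recover exact and mutated reference slices", {
  ref <- random_dna(6000, seed = 31)
  q <- substr(ref, 2001, 4000)
  h <- find_local_hits(q, ref)
  expect_equal(nrow(h), 1L)
  expect_equal(h$ref_start, 2000L)
  expect_equal(h$ref_end, 4000L)
  expect_equal(h$length, 2000L)
  expect_equal(h$identity, 1.0)

  set.seed(32)
  qv <- strsplit(q, "")[[1]]
  mut <- sample(length(qv), 60)                      # 3% substitutions
  qv[mut] <- vapply(qv[mut], function(b)
    sample(setdiff(BASES, b), 1), character(1))
  h2 <- find_local_hits(paste0(qv, collapse = ""), ref)
  expect_gt(sum(h2$length), 1800)
  expect_lt(abs(sum(h2$matches) / sum(h2$length) - 0.97), 0.01)

  # no shared 9-mer: query from a disjoint alphabet path
  expect_equal(nrow(find_local_hits(strrep("A", 100), strrep("C", 5000))), 0L)
})

test_that("reverse-strand hits report forward query coordinates", {
  ref <- random_dna(4000, seed = 33)
  q <- paleostrain:::revcomp(substr(ref, 1001, 2500))
  h <- find_local_hits(q, ref)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(c(h$query_start, h$query_end), c(0L, 1500L))
  expect_equal(c(h$ref_start, h$ref_end), c(1000L, 2500L))
  expect_identical(h$aligned_query, h$aligned_ref)   # perfect hit, ref-oriented
})

test_that("hit filtering is strict at both thresholds", {
  base <- find_local_hits(random_dna(1000, seed = 34),
                          random_dna(1000, seed = 34))  # one perfect hit
  h <- base[rep(1, 3), ]
  h$length <- c(500L, 501L, 501L)
  h$identity <- c(0.99, 0.95, 0.951)
  kept <- filter_hits(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$identity, 0.951)
})

test_that("row projection fills uncovered spans and resolves overlaps by identity", {
  ref <- random_dna(2000, seed = 35)
  h1 <- find_local_hits(substr(ref, 1, 600), ref)
  h2 <- find_local_hits(substr(ref, 1001, 1700), ref)
  h2$ref_start <- 1000L; h2$ref_end <- 1700L   # reanchor second hit
  both <- rbind(h1, h2)
  class(both) <- c("local_hits", "data.frame")
  row <- strsplit(project_row(both, ref), "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  expect_identical(row[1:600], rv[1:600])
  expect_identical(row[1001:1700], rv[1001:1700])
  expect_true(all(row[601:1000] == "-"))
  expect_true(all(row[1701:2000] == "-"))

  # overlapping hits disagreeing at one column: higher identity wins
  ov <- both[c(1, 1), ]
  ov$identity <- c(0.99, 0.96)
  aq <- strsplit(ov$aligned_query[2], "")[[1]]
  aq[10] <- setdiff(BASES, aq[10])[1]
  ov$aligned_query[2] <- paste0(aq, collapse = "")
  class(ov) <- c("local_hits", "data.frame")
  row2 <- strsplit(project_row(ov, ref), "")[[1]]
  expect_identical(row2[10], rv[10])
})

test_that("projection fidelity: consensus rows project identically", {
  ref <- random_dna(500, seed = 36)
  cg <- structure(list(ref_id = "r", sequence = ref,
                       breadth_at_min_depth = 1), class = "consensus_genome")
  expect_identical(project_row(cg, ref, ref_id = "r"), ref)
  expect_error(project_row(cg, ref, ref_id = "other"), "other")
})

test_that("MSA cleaning drops rows then columns with strict thresholds", {
  set.seed(37)
  m <- matrix(sample(BASES, 10 * 1000, replace = TRUE), 10, 1000,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  m[1, 1:600] <- "-"                     # row g01: 60% gaps -> dropped
  m[2, 1:100] <- "-"                     # 10% gaps -> kept
  m[2:3, 901:950] <- "-"                 # cols 901..950: 2/9 surviving missing
  m[4, 951:1000] <- "-"                  # cols 951..1000: 1/9 missing -> kept
  msa <- paleostrain:::msa_from_matrix(m, "r")
  out <- clean_msa(msa)
  expect_identical(names(out$rows), sprintf("g%02d", 2:10))
  # over the 9 surviving rows, every marked column stretch is missing in at
  # least 1/9 = 11.1% > 10% of rows, so only columns 101..900 survive
  expect_identical(out$column_coords, 100:899)
  # genus mode keeps all rows, column rule only: columns missing in two of
  # ten rows (20%) drop, columns missing in one row (10%) stay
  gen <- clean_msa(msa, mode = "genus")
  expect_equal(length(gen$rows), 10L)
  expect_identical(gen$column_coords, c(100:899, 950:999))
  expect_error(clean_msa(paleostrain:::msa_from_matrix(
    matrix("-", 3, 10, dimnames = list(c("a", "b", "c"), NULL)), "r")),
    "emptied")
})

test_that("a row at exactly 50% gaps and a column at exactly 10% are retained", {
  m <- matrix("A", 10, 100, dimnames = list(sprintf("g%02d", 1:10), NULL))
  m[1, 1:50] <- "-"                      # exactly 50% gaps
  m[2, 60] <- "-"                        # column 60: 1/10 missing = 10%
  out <- clean_msa(paleostrain:::msa_from_matrix(m, "r"))
  expect_equal(length(out$rows), 10L)
  expect_equal(length(out$column_coords), 100L)
})

test_that("cleaning is invariant to row order and meets its post-condition", {
  set.seed(38)
  m <- matrix(sample(c(BASES, "-"), 8 * 400, replace = TRUE,
                     prob = c(rep(0.22, 4), 0.12)), 8, 400,
              dimnames = list(sprintf("g%d", 1:8), NULL))
  msa <- paleostrain:::msa_from_matrix(m, "r")
  perm <- paleostrain:::msa_from_matrix(m[sample(8), ], "r")
  a <- clean_msa(msa); b <- clean_msa(perm)
  expect_setequal(names(a$rows), names(b$rows))
  expect_identical(a$column_coords, b$column_coords)
  mm <- paleostrain:::msa_matrix(a)
  expect_true(all(colMeans(mm == "-" | mm == "N") <= 0.10))
})

test_that("local hits survive a tabular round trip", {
  ref <- random_dna(3000, seed = 39)
  h <- find_local_hits(substr(ref, 101, 1200), ref, query_id = "contig1")
  f <- tempfile(fileext = ".tsv")
  paleostrain:::write_tsv(h, f)
  h2 <- read_local_hits(f)
  expect_equal(h2$ref_start, h$ref_start)
  expect_identical(h2$aligned_query, h$aligned_query)
  expect_identical(project_row(h2, ref), project_row(h, ref))
})
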