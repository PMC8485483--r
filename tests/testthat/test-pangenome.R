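test_that("identical sequences collapse into one cluster; distant families split", {
  g <- data.frame(genome_id = sprintf("g%d", 1:4),
                  gene_id = sprintf("x%d", 1:4),
                  sequence = rep(random_dna(600, seed = 71), 4),
                  stringsAsFactors = FALSE)
  cl <- cluster_genes(g, 0.85)
  expect_length(cl$clusters, 1L)

  two <- rbind(g, data.frame(genome_id = sprintf("g%d", 1:4),
                             gene_id = sprintf("y%d", 1:4),
                             sequence = rep(random_dna(600, seed = 72), 4)))
  cl2 <- cluster_genes(two, 0.80)
  expect_length(cl2$clusters, 2L)
  # partition property: every gene in exactly one cluster
  expect_setequal(cl2$members$gene_id, two$gene_id)
  expect_equal(anyDuplicated(cl2$members$gene_id), 0L)
})

test_that("greedy clustering is deterministic under the ordering rule", {
  gs <- setNames(rep(c("spA", "spB"), each = 3), sprintf("g%d", 1:6))
  fam <- simulate_gene_families(30, 0.9, gs, seed = 73)
  shuffled <- fam$genes[sample(nrow(fam$genes)), ]
  c1 <- cluster_genes(fam$genes, 0.80)
  c2 <- cluster_genes(shuffled, 0.80)
  expect_identical(c1$centroids, c2$centroids)
  expect_identical(c1$members[order(c1$members$gene_id), c("cluster_id", "gene_id")],
                   c2$members[order(c2$members$gene_id), c("cluster_id", "gene_id")])
})

test_that("core rule is strictly greater-than, verified by brute force", {
  mk <- function(m, sp) {
    rownames(m) <- sprintf("cluster%02d", seq_len(nrow(m)))
    colnames(m) <- names(sp)
    attr(m, "species") <- sp
    class(m) <- c("presence_absence", class(m))
    m
  }
  sp10 <- setNames(rep("s", 10), sprintf("g%d", 1:10))
  m <- matrix(TRUE, 3, 10)
  m[2, 1] <- FALSE          # 9/10 = 90%: NOT core under strict > 0.90
  pa <- mk(m, sp10)
  expect_identical(core_genes(pa), c("cluster01", "cluster03"))
  sp20 <- setNames(rep("s", 20), sprintf("g%d", 1:20))
  m2 <- matrix(TRUE, 1, 20); m2[1, 1] <- FALSE    # 19/20 = 95%: core
  expect_identical(core_genes(mk(m2, sp20)), "cluster01")

  set.seed(74)
  for (k in 1:20) {
    m3 <- matrix(runif(8 * 12) < 0.8, 8, 12)
    m3[rowSums(m3) == 0, 1] <- TRUE
    pa3 <- mk(m3, setNames(rep("s", 12), sprintf("g%d", 1:12)))
    brute <- rownames(pa3)[apply(unclass(pa3), 1, function(r) sum(r) / 12 > 0.9)]
    expect_identical(core_genes(pa3), brute)
    expect_identical(core_genes(pa3, 0), rownames(pa3))   # all have >0 presence
    expect_identical(core_genes(pa3, 1), character(0))
  }
})

test_that("species-specific rule needs >=90% at home and zero elsewhere", {
  sp <- setNames(rep(c("A", "B", "C"), each = 10), sprintf("g%02d", 1:30))
  m <- matrix(FALSE, 4, 30, dimnames = list(sprintf("cluster%d", 1:4), names(sp)))
  m[1, 1:10] <- TRUE                      # 100% of A, absent elsewhere
  m[2, 1:10] <- TRUE; m[2, 1] <- FALSE    # 90% of A (inclusive) -> specific
  m[2, 11] <- TRUE                        # ... but present in one B genome
  m[3, 1:8] <- TRUE                       # 80% of A only -> not specific
  m[4, 2:10] <- TRUE                      # 90% of A, absent elsewhere
  attr(m, "species") <- sp
  class(m) <- c("presence_absence", class(m))
  out <- species_specific_genes(m)
  expect_identical(out$A, c("cluster1", "cluster4"))
  expect_identical(out$B, character(0))
  expect_identical(out$C, character(0))
  expect_equal(length(intersect(out$A, c(out$B, out$C))), 0L)

  sp_small <- setNames(c("A", "A", "B"), c("g01", "g02", "g03"))
  m2 <- unclass(m)[, 1:3]
  attr(m2, "species") <- sp_small
  class(m2) <- c("presence_absence", class(m2))
  expect_warning(species_specific_genes(m2), "< 2 genomes")
})

test_that("concatenated core alignment has block structure and recovers topology", {
  gs <- setNames(rep(c("spA", "spB", "spC"), each = 3), sprintf("g%d", 1:9))
  fam <- simulate_gene_families(25, 1.0, gs, mutation_rate = 0.03, seed = 75)
  cl <- cluster_genes(fam$genes, 0.80)
  pa <- presence_absence(cl, gs)
  core <- core_genes(pa)
  expect_length(core, 25L)
  aln <- concatenate_core_alignment(cl, core, gs)
  blocks <- attr(aln, "blocks")
  expect_equal(nrow(blocks), 25L)
  expect_equal(max(blocks$end),
               sum(nchar(cl$centroids[sort(core)])))
  expect_equal(unique(nchar(aln$rows)), max(blocks$end))

  # identical equal-length members concatenate without gaps
  expect_false(any(grepl("-", aln$rows[1], fixed = TRUE)) &&
                 !any(fam$truth_matrix[, 1] == FALSE))
})

test_that("designed families, core and specific sets are recovered exactly", {
  gs <- setNames(rep(c("spA", "spB", "spC"), each = 4), sprintf("g%02d", 1:12))
  occ <- matrix(1.0, 40, 3, dimnames = list(NULL, c("spA", "spB", "spC")))
  occ[1:5, ] <- rep(c(1, 0, 0), each = 5)      # specific to A
  occ[6:8, ] <- rep(c(0, 1, 0), each = 3)      # specific to B
  fam <- simulate_gene_families(40, occ, gs, mutation_rate = 0.02, seed = 76)
  cl <- cluster_genes(fam$genes, 0.80)
  expect_length(cl$clusters, 40L)
  # clusters coincide with truth families
  fam_of <- setNames(fam$genes$family, fam$genes$gene_id)
  for (cid in names(cl$clusters))
    expect_length(unique(fam_of[cl$clusters[[cid]]$gene_id]), 1L)
  pa <- presence_absence(cl, gs)
  sp <- species_specific_genes(pa)
  cluster_of_family <- vapply(split(cl$members$cluster_id, fam_of[cl$members$gene_id]),
                              function(x) unique(x)[1], character(1))
  expect_setequal(sp$spA, unname(cluster_of_family[sprintf("fam%04d", 1:5)]))
  expect_setequal(sp$spB, unname(cluster_of_family[sprintf("fam%04d", 6:8)]))
  expect_length(sp$spC, 0L)
  expect_setequal(core_genes(pa), unname(cluster_of_family[sprintf("fam%04d", 9:40)]))
})
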