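#' Fragment-based average nucleotide identity between two genomes
#'
#' The query is cut into consecutive non-overlapping fragments
#' (default 1000 bp); each fragment is locally aligned to the subject with the
#' package's seed-and-extend aligner and contributes the identity of its best
#' hit. ANI is the mean identity over fragments with a retained hit; the ANI
#' distance is `1 - ani`. A hit is retained when its identity reaches
#' `min_fragment_identity` and its length reaches `min_hit_length` (short
#' spurious word matches between unrelated sequences carry high identity and
#' must not enter the mean).
#'
#' @param query,subject genome sequences (plain strings, both at least one
#'   fragment long).
#' @param fragment_length fragment size in bp (default 1000).
#' @param min_fragment_identity minimum best-hit identity for a fragment to
#'   count (default 0.30).
#' @param min_hit_length minimum best-hit length in alignment columns
#'   (default 100).
#' @param word_size seed word size passed to [find_local_hits()].
#' @return an `ani_result` list: `ani` (NA when no fragment aligns),
#'   `aligned_fraction`, `n_fragments`, `n_fragments_aligned`.
#' @export
ani_pairwise <- function(query, subject, fragment_length = 1000L,
                         min_fragment_identity = 0.30,
                         min_hit_length = 100L, word_size = 9L) {
  lq <- nchar(query)
  if (lq < fragment_length || nchar(subject) < fragment_length)
    stop("both sequences must be at least one fragment long")
  bh <- .cpp_ani_fragments(toupper(query), toupper(subject),
                           as.integer(fragment_length), as.integer(word_size),
                           1L, 2L, 20L)
  nfrag <- nrow(bh)
  idents <- ifelse(bh$length > 0L, bh$matches / bh$length, NA_real_)
  idents[!is.na(idents) &
           (bh$length < min_hit_length | idents < min_fragment_identity)] <- NA_real_
  aligned <- !is.na(idents)
  structure(list(
    ani = if (any(aligned)) mean(idents[aligned]) else NA_real_,
    aligned_fraction = sum(aligned) * fragment_length / lq,
    n_fragments = nfrag,
    n_fragments_aligned = sum(aligned)
  ), class = "ani_result")
}

#' All-pairs ANI matrix and symmetrised distances
#'
#' Computes [ani_pairwise()] for every ordered pair of genomes. ANI is
#' direction-dependent; both directions are retained and the symmetrised
#' summary used for clustering is the mean of the two. Pairs where neither
#' direction aligns stay `NA`.
#'
#' @param genomes named character vector of genome sequences.
#' @param ... passed to [ani_pairwise()].
#' @return an `ani_matrix` list: `ani` (directed matrix, query rows x subject
#'   columns), `distance` (symmetrised `1 - ANI`, zero diagonal),
#'   `aligned_fraction` (directed).
#' @export
ani_matrix <- function(genomes, ...) {
  n <- length(genomes)
  ids <- names(genomes)
  if (is.null(ids) || n < 2L) stop("need >= 2 named genomes")
  A <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  AF <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(A) <- 1; diag(AF) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- ani_pairwise(genomes[[i]], genomes[[j]], ...)
    A[i, j] <- r$ani
    AF[i, j] <- r$aligned_fraction
  }
  sym <- (A + t(A)) / 2
  na_one <- is.na(A) & !is.na(t(A))
  sym[na_one] <- t(A)[na_one]          # one defined direction is used as-is
  D <- 1 - sym
  diag(D) <- 0
  structure(list(ani = A, distance = D, aligned_fraction = AF),
            class = "ani_matrix")
}

#' Delimit species by single-linkage clustering of ANI distances
#'
#' Genomes are merged whenever their symmetrised ANI distance is strictly
#' below `max_intra_distance` (default 5%, the operational species boundary;
#' a pair at exactly 0.05 is *not* merged) and clusters are the connected
#' components of that graph (single linkage). Genomes with no defined
#' distance to anything become singletons.
#'
#' @param x an `ani_matrix` or a symmetric distance matrix with dimnames.
#' @param max_intra_distance strict merge threshold on the ANI distance
#'   (default 0.05).
#' @return named integer vector of cluster memberships (1-based, ordered by
#'   first appearance).
#' @export
delimit_species <- function(x, max_intra_distance = 0.05) {
  D <- if (inherits(x, "ani_matrix")) x$distance else x
  if (!is.matrix(D) || is.null(rownames(D))) stop("need a named distance matrix")
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- D[i, j]
    if (!is.na(dij) && dij < max_intra_distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(match(roots, unique(roots)), rownames(D))
}

#' Write an ANI distance matrix and cluster memberships as TSV
#'
#' @param am an `ani_matrix`.
#' @param clusters membership vector from [delimit_species()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_ani <- function(am, clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- data.frame(id = rownames(am$distance), am$distance, check.names = FALSE)
  write_tsv(d, file.path(dir, "ani_distance.tsv"))
  write_tsv(data.frame(genome = names(clusters), cluster = clusters),
            file.path(dir, "ani_clusters.tsv"))
  invisible(dir)
}
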