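# integer encoding of MSA rows: A=1 C=2 G=3 T=4, anything else 0 (missing)
msa_int <- function(msa) {
  m <- msa_matrix(msa)
  im <- matrix(match(m, BASES, nomatch = 0L), nrow = nrow(m),
               dimnames = dimnames(m))
  im
}

#' Jukes-Cantor distance matrix under pairwise deletion
#'
#' For every pair of rows, the proportion of differing sites `p` is computed
#' over columns where both rows carry an unambiguous base (pairwise deletion)
#' and converted to an evolutionary distance `d = -3/4 log(1 - 4p/3)`
#' substitutions/site. Pairs with `p >= 0.75` are saturated and reported as
#' `NA` with a warning; a pair with zero comparable columns is an error.
#'
#' @param msa a `ref_msa` (or integer matrix from internal use) with >= 2 rows.
#' @return a `jc_dist` list: `ids`, `d` (symmetric distance matrix),
#'   `p` (raw mismatch proportions) and `pairwise_sites` (comparable columns
#'   per pair).
#' @export
jc_distance_matrix <- function(msa) {
  im <- if (is.matrix(msa)) msa else msa_int(msa)
  n <- nrow(im)
  if (n < 2L) stop("need at least 2 rows")
  ids <- rownames(im)
  d <- p <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ns) <- as.integer(rowSums(im > 0L))
  saturated <- character(0)
  for (i in seq_len(n - 1L)) {
    xi <- im[i, ]
    for (j in (i + 1L):n) {
      xj <- im[j, ]
      comp <- xi > 0L & xj > 0L
      nc <- sum(comp)
      if (nc == 0L)
        stop(sprintf("no comparable columns between '%s' and '%s'", ids[i], ids[j]))
      pij <- sum(xi[comp] != xj[comp]) / nc
      ns[i, j] <- ns[j, i] <- nc
      p[i, j] <- p[j, i] <- pij
      if (pij >= 0.75) {
        d[i, j] <- d[j, i] <- NA_real_
        saturated <- c(saturated, sprintf("%s~%s", ids[i], ids[j]))
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * pij / 3)
      }
    }
  }
  if (length(saturated))
    warning("saturated pairs (p >= 0.75): ", paste(saturated, collapse = ", "))
  structure(list(ids = ids, d = d, p = p, pairwise_sites = ns),
            class = "jc_dist")
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard neighbor-joining agglomeration (Q-matrix minimisation) with two
#' pinned-down conventions: ties in Q are broken by the lexicographically
#' smallest pair of cluster ids (a cluster is named by its smallest member
#' leaf), and a negative branch length is clamped to zero with the deficit
#' moved to its sister branch, keeping the path length between the joined
#' leaves intact.
#'
#' @param dm a `jc_dist` from [jc_distance_matrix()], or a symmetric numeric
#'   matrix with dimnames.
#' @return an unrooted `phylo` tree with branch lengths in substitutions/site.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "jc_dist")) dm$d else dm
  if (!is.matrix(d) || is.null(rownames(d))) stop("need a named distance matrix")
  if (any(!is.finite(d))) stop("non-finite distances (saturated or missing pairs)")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  # active clusters: newick fragment + representative id (smallest leaf)
  frag <- rownames(d)
  rep_id <- rownames(d)
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_id[ij[1]], rep_id[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    new_rep <- min(rep_id[i], rep_id[j])
    dnew <- 0.5 * (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j])
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    frag <- c(frag[keep], new_frag)
    rep_id <- c(rep_id[keep], new_rep)
    dimnames(D) <- list(NULL, NULL)
  }
  # final 3-taxon star: three-point formulas
  v1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  v2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  v3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  tree <- ape::read.tree(text = nwk)
  tree
}

# canonical bipartitions of an unrooted tree: for every internal edge, the
# tip-label set on the side NOT containing the alphabetically first taxon,
# serialised as a sorted, collapsed string
tree_bipartitions <- function(tree) {
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) return(character(0))
  anchor <- sort(tree$tip.label)[1L]
  below <- descendant_tips(tree)
  internal <- tree$edge[, 2L][tree$edge[, 2L] > ntip]
  out <- character(0)
  for (nd in internal) {
    side <- sort(tree$tip.label[below[[nd]]])
    if (anchor %in% side) side <- sort(setdiff(tree$tip.label, side))
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Bootstrap support for a distance tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds a tree from
#' each pseudo-replicate, and annotates each internal bipartition of the point
#' tree with the percentage of replicates containing it.
#'
#' @param msa a `ref_msa` with >= 4 rows.
#' @param n_reps number of bootstrap pseudo-replicates (default 100);
#'   `n_reps = 0` returns the point tree without supports.
#' @param seed integer seed for the column resampling.
#' @return the point-estimate `phylo` with `node.label` carrying supports in
#'   `[0, 100]` (empty label at the root/basal node).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L) {
  im <- msa_int(msa)
  if (nrow(im) < 4L) stop("need >= 4 rows for bootstrap support")
  point <- neighbor_joining(jc_distance_matrix(im))
  if (n_reps <= 0L) return(point)
  set.seed(seed)
  bp_point <- tree_bipartitions(point)
  counts <- setNames(numeric(length(bp_point)), bp_point)
  nc <- ncol(im)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    tb <- try(neighbor_joining(jc_distance_matrix(im[, cols, drop = FALSE])),
              silent = TRUE)
    if (inherits(tb, "try-error")) next
    hit <- tree_bipartitions(tb)
    inb <- bp_point %in% hit
    counts[inb] <- counts[inb] + 1
  }
  support <- 100 * counts / n_reps
  # map supports onto internal nodes of the point tree
  ntip <- ape::Ntip(point)
  below <- descendant_tips(point)
  anchor <- sort(point$tip.label)[1L]
  labs <- character(point$Nnode)
  for (nd in (ntip + 1L):(ntip + point$Nnode)) {
    side <- sort(point$tip.label[below[[nd]]])
    if (anchor %in% side) side <- sort(setdiff(point$tip.label, side))
    key <- paste(side, collapse = "\r")
    labs[nd - ntip] <- if (key %in% names(counts))
      sprintf("%g", support[key]) else ""
  }
  point$node.label <- labs
  point
}
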