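#' Greedy identity-based gene clustering
#'
#' Sequences are sorted by decreasing length (ties by gene id) and each joins
#' the first existing cluster whose centroid it matches at
#' `min_identity` or better under global alignment — identity is matches over
#' all alignment columns with end gaps penalised, computed by the package's
#' banded aligner — otherwise it founds a new cluster with itself as centroid.
#' The ordering rule makes the partition deterministic. Since identity cannot
#' exceed `min(len)/max(len)`, pairs whose length ratio is below the threshold
#' are skipped without alignment.
#'
#' @param genes data.frame with columns `genome_id`, `gene_id`, `sequence`.
#' @param min_identity cluster membership threshold in (0, 1] (default 0.85,
#'   inclusive).
#' @return a `gene_clusters` list: `clusters` (list of member data.frames with
#'   an `identity`-to-centroid column), `centroids` (named character vector of
#'   centroid sequences), `members` (flat data.frame gene -> cluster).
#' @export
cluster_genes <- function(genes, min_identity = 0.85) {
  stopifnot(is.data.frame(genes),
            all(c("genome_id", "gene_id", "sequence") %in% names(genes)))
  if (!nrow(genes)) stop("no gene sequences supplied")
  if (!(min_identity > 0 && min_identity <= 1))
    stop("'min_identity' must be in (0, 1]")
  ord <- order(-nchar(genes$sequence), genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  lens <- nchar(g$sequence)

  cent_seq <- character(0); cent_len <- integer(0)
  assign <- integer(nrow(g)); ident <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    hit <- 0L; hit_id <- NA_real_
    if (length(cent_seq)) {
      for (k in seq_along(cent_seq)) {
        # identity <= min(len)/max(len): skip pairs that cannot reach threshold
        if (lens[i] < min_identity * cent_len[k]) next
        r <- .cpp_global_identity(g$sequence[i], cent_seq[k], 32L)
        if (!is.na(r$identity) && r$identity >= min_identity) {
          hit <- k; hit_id <- r$identity; break
        }
      }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, g$sequence[i])
      cent_len <- c(cent_len, lens[i])
      assign[i] <- length(cent_seq); ident[i] <- 1
    } else {
      assign[i] <- hit; ident[i] <- hit_id
    }
  }
  cl_ids <- sprintf("cluster%04d", seq_along(cent_seq))
  members <- data.frame(cluster_id = cl_ids[assign],
                        genome_id = g$genome_id, gene_id = g$gene_id,
                        sequence = g$sequence, identity = ident,
                        stringsAsFactors = FALSE)
  clusters <- split(members, members$cluster_id)
  structure(list(clusters = clusters,
                 centroids = setNames(cent_seq, cl_ids),
                 members = members),
            class = "gene_clusters")
}

#' Gene presence/absence matrix from clusters
#'
#' @param gc a `gene_clusters` object.
#' @param genome_species named character vector genome id -> species label;
#'   its names define the full genome set (genomes without genes included).
#' @return a `presence_absence` logical matrix (clusters x genomes) with a
#'   `species` attribute.
#' @export
presence_absence <- function(gc, genome_species) {
  stopifnot(inherits(gc, "gene_clusters"), !is.null(names(genome_species)))
  genomes <- names(genome_species)
  cl <- names(gc$clusters)
  m <- matrix(FALSE, length(cl), length(genomes), dimnames = list(cl, genomes))
  for (cid in cl) {
    gs <- unique(gc$clusters[[cid]]$genome_id)
    bad <- setdiff(gs, genomes)
    if (length(bad)) stop("cluster member from unlabelled genome: ", bad[1])
    m[cid, gs] <- TRUE
  }
  attr(m, "species") <- genome_species
  class(m) <- c("presence_absence", class(m))
  m
}

#' Core gene clusters
#'
#' Clusters present in strictly more than `core_frac` of the genomes
#' (default >90%, strict as stated: presence in exactly 90% of genomes does
#' not qualify).
#'
#' @param pa a `presence_absence` matrix.
#' @param core_frac strict presence fraction (default 0.90).
#' @return character vector of core cluster ids.
#' @export
core_genes <- function(pa, core_frac = 0.90) {
  stopifnot(inherits(pa, "presence_absence"))
  rownames(pa)[rowMeans(unclass(pa)) > core_frac]
}

#' Species-specific gene clusters
#'
#' A cluster is specific to species S when it is present in at least
#' `presence_frac` of S's genomes ("shared by 90%", read as inclusive) and
#' present in *zero* genomes of every other species ("completely absent").
#' Species-specific sets are disjoint across species by construction.
#'
#' @param pa a `presence_absence` matrix with a `species` attribute.
#' @param presence_frac inclusive within-species presence fraction
#'   (default 0.90).
#' @return named list, species -> character vector of cluster ids. Species
#'   with fewer than 2 genomes trigger a warning (the fraction is then a
#'   single genome).
#' @export
species_specific_genes <- function(pa, presence_frac = 0.90) {
  stopifnot(inherits(pa, "presence_absence"))
  sp <- attr(pa, "species")
  if (is.null(sp)) stop("presence/absence matrix lacks species labels")
  if (length(unique(sp)) < 2L) stop("need >= 2 species")
  m <- unclass(pa)
  species <- sort(unique(sp))
  small <- species[vapply(species, function(s) sum(sp == s) < 2L, logical(1))]
  if (length(small))
    warning("species with < 2 genomes: ", paste(small, collapse = ", "))
  out <- lapply(species, function(s) {
    own <- m[, names(sp)[sp == s], drop = FALSE]
    oth <- m[, names(sp)[sp != s], drop = FALSE]
    rownames(m)[rowMeans(own) >= presence_frac & rowSums(oth) == 0L]
  })
  setNames(out, species)
}

#' Concatenated core-gene alignment
#'
#' Each core cluster is aligned around its centroid (every member is globally
#' aligned to the centroid and projected onto centroid coordinates, so each
#' block has the centroid's length); a genome missing from a cluster
#' contributes an all-gap block, and a genome with several members contributes
#' its highest-identity one. Blocks are concatenated in sorted cluster-id
#' order.
#'
#' @param gc a `gene_clusters` object.
#' @param core_ids cluster ids to concatenate (e.g. from [core_genes()]).
#' @param genome_species named vector defining the genome set and order.
#' @return a `ref_msa`-like alignment (`ref_id = "core"`) whose
#'   `column_coords` are block-local offsets, with a `blocks` attribute
#'   (cluster_id, start, end in concatenated 0-based coordinates).
#' @export
concatenate_core_alignment <- function(gc, core_ids, genome_species) {
  stopifnot(inherits(gc, "gene_clusters"))
  genomes <- names(genome_species)
  core_ids <- sort(core_ids)
  if (!length(core_ids)) stop("no core clusters to concatenate")
  blocks <- list(); bounds <- list(); off <- 0L
  for (cid in core_ids) {
    cent <- gc$centroids[[cid]]
    wid <- nchar(cent)
    mem <- gc$clusters[[cid]]
    block <- matrix("-", length(genomes), wid, dimnames = list(genomes, NULL))
    for (gid in unique(mem$genome_id)) {
      if (!gid %in% genomes) next
      rows <- mem[mem$genome_id == gid, , drop = FALSE]
      sq <- rows$sequence[which.max(rows$identity)]
      proj <- if (identical(sq, cent)) cent else
        .cpp_global_projection(sq, cent, 32L)$projection
      block[gid, ] <- seq_to_vec(proj)
    }
    blocks[[cid]] <- block
    bounds[[cid]] <- data.frame(cluster_id = cid, start = off,
                                end = off + wid, stringsAsFactors = FALSE)
    off <- off + wid
  }
  m <- do.call(cbind, blocks)
  out <- msa_from_matrix(m, "core")
  attr(out, "blocks") <- do.call(rbind, bounds)
  out
}

#' Write a presence/absence matrix as CSV
#'
#' Roary-like layout: one row per gene cluster, one column per genome, with a
#' presence count column.
#'
#' @param pa a `presence_absence` matrix.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(pa, path) {
  m <- unclass(pa)
  df <- data.frame(cluster_id = rownames(m),
                   n_genomes = rowSums(m),
                   ifelse(m, 1L, 0L), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
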