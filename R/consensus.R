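#' Read-level gate for consensus reconstruction
#'
#' A read contributes to the pileup only if it passes all three read-level
#' filters. The thresholds are stated as strict "below" exclusion conditions,
#' so equality at each threshold *passes*: mapping quality 30, aligned length
#' 30 nt and identity 0.97 are all retained.
#'
#' @param alignments a `read_alignments` data.frame.
#' @param reference reference sequence (used to compute identity and aligned
#'   length when the `identity` / `aligned_length` columns are absent).
#' @param min_mq minimum mapping quality (reads with `mapq < min_mq` are
#'   excluded; default 30).
#' @param min_len minimum aligned read length in nt (default 30).
#' @param min_identity minimum read identity, matches over aligned columns
#'   with indel columns counted as mismatches (default 0.97).
#' @return logical vector, one entry per alignment.
#' @export
gate_read <- function(alignments, reference = NULL, min_mq = 30,
                      min_len = 30, min_identity = 0.97) {
  if (!all(c("identity", "aligned_length") %in% names(alignments))) {
    if (is.null(reference))
      stop("supply 'reference' or precomputed identity/aligned_length columns")
    st <- alignment_stats(alignments, reference)
    alignments$identity <- st$identity
    alignments$aligned_length <- st$aligned_length
  }
  alignments$mapq >= min_mq &
    alignments$aligned_length >= min_len &
    alignments$identity >= min_identity
}

#' Build a per-site allele pileup from gated read alignments
#'
#' Accumulates A/C/G/T counts at matched (non-indel) reference columns using
#' only reads that pass [gate_read()]. Ambiguous read bases are skipped.
#'
#' @inheritParams gate_read
#' @param ref_id reference name; alignments carrying a different `ref_id`
#'   raise an error naming both ids. Use `NULL` to skip the check (the
#'   simulator's colinear truth alignments carry their source genome's id).
#' @return a `pileup` list: `ref_id`, `length`, `counts` (4 x length integer
#'   matrix, rows A,C,G,T) and `depth` (post-gating column sums).
#' @export
build_pileup <- function(alignments, reference, ref_id = NULL, min_mq = 30,
                         min_len = 30, min_identity = 0.97) {
  L <- nchar(reference)
  if (!is.null(ref_id)) {
    other <- setdiff(unique(alignments$ref_id), ref_id)
    if (length(other))
      stop(sprintf("alignments reference '%s' but pileup is for '%s'",
                   other[1], ref_id))
  } else {
    ref_id <- if (nrow(alignments)) alignments$ref_id[1] else "reference"
  }
  counts <- matrix(0L, 4L, L, dimnames = list(BASES, NULL))
  if (nrow(alignments)) {
    keep <- gate_read(alignments, reference, min_mq, min_len, min_identity)
    kept <- alignments[keep, , drop = FALSE]
    if (nrow(kept)) {
      cols <- alignment_columns(kept, reference)
      code <- match(cols$base, BASES)
      ok <- !is.na(code)
      idx <- (cols$ref_pos[ok]) * 4L + code[ok]     # 1..4L
      counts[] <- tabulate(idx, nbins = 4L * L)
    }
  }
  structure(list(ref_id = ref_id, length = L, counts = counts,
                 depth = as.integer(colSums(counts))),
            class = "pileup")
}

#' Call a reference-anchored consensus from a pileup
#'
#' A site receives its dominant allele only when the post-gating depth reaches
#' `min_depth`, the dominant allele frequency reaches `min_dominant_freq`, and
#' the dominant allele is unique; every other site is gap-filled with `'-'`.
#' Equality at the thresholds passes (depth 3 and frequency 0.80 are called);
#' a tie for the most frequent allele has no dominant allele and is gapped.
#'
#' @param pileup a `pileup` from [build_pileup()].
#' @param min_depth minimum site depth (default 3).
#' @param min_dominant_freq minimum dominant allele frequency (default 0.80).
#' @return a `consensus_genome` list: `ref_id`, `sequence` (over A,C,G,T,'-'),
#'   and `breadth_at_min_depth`, the fraction of sites with depth >= min_depth.
#' @export
call_consensus <- function(pileup, min_depth = 3, min_dominant_freq = 0.80) {
  stopifnot(inherits(pileup, "pileup"))
  cts <- pileup$counts
  depth <- pileup$depth
  maxc <- pmax(cts[1L, ], cts[2L, ], cts[3L, ], cts[4L, ])
  nmax <- (cts[1L, ] == maxc) + (cts[2L, ] == maxc) +
          (cts[3L, ] == maxc) + (cts[4L, ] == maxc)
  freq <- ifelse(depth > 0L, maxc / depth, 0)
  pass <- depth >= min_depth & freq >= min_dominant_freq & nmax == 1L
  arg <- max.col(t(cts), ties.method = "first")
  out <- rep("-", pileup$length)
  out[pass] <- BASES[arg[pass]]
  structure(list(ref_id = pileup$ref_id, sequence = vec_to_seq(out),
                 breadth_at_min_depth = mean(depth >= min_depth)),
            class = "consensus_genome")
}

#' Breadth of coverage and sample-level presence
#'
#' Breadth is the fraction of reference sites whose post-gating depth reaches
#' `min_depth`; a species is called present in a sample when at least half the
#' reference is covered at that depth. Consistent with the gap-filling rule
#' "coverage < 3 folds", the depth condition is inclusive (`depth >= 3`).
#'
#' @param pileup a `pileup`.
#' @param min_depth depth threshold (default 3).
#' @return fraction of sites at or above `min_depth`.
#' @export
breadth_of_coverage <- function(pileup, min_depth = 3) {
  stopifnot(inherits(pileup, "pileup"))
  if (pileup$length == 0L) stop("zero-length reference")
  mean(pileup$depth >= min_depth)
}

#' @rdname breadth_of_coverage
#' @param breadth breadth fraction from [breadth_of_coverage()].
#' @param threshold minimum breadth for presence (default 0.50, inclusive).
#' @return `detect_presence` returns TRUE/FALSE.
#' @export
detect_presence <- function(breadth, threshold = 0.50) {
  assert_fraction(breadth, "breadth")
  breadth >= threshold
}
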