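# Expand read alignments into per-column vectors shared by the damage and
# consensus modules. Ungapped (all-M) alignments take a fully vectorised
# path; general CIGARs (M/I/D after clip removal) are expanded per read.
#
# Returns a list of parallel vectors over aligned (match/mismatch) columns:
#   aln      index of the source alignment row
#   ref_pos  0-based reference position
#   ref_base reference base (reference orientation)
#   base     read base (reference orientation)
#   dist5    1-based distance of the column from the read 5' end
#   dist3    1-based distance from the read 3' end
#   strand   alignment strand
alignment_columns <- function(alignments, reference) {
  stopifnot(is.data.frame(alignments))
  need <- c("read_id", "ref_start", "strand", "cigar", "seq")
  if (!all(need %in% names(alignments)))
    stop("alignments lack per-base pairing information (need columns: ",
         paste(need, collapse = ", "), ")")
  refv <- seq_to_vec(toupper(reference))
  L <- length(refv)
  ungapped <- grepl("^[0-9]+M$", alignments$cigar)

  parts <- list()
  if (any(ungapped)) {
    a <- alignments[ungapped, , drop = FALSE]
    lens <- nchar(a$seq)
    idx <- rep(which(ungapped), lens)
    within <- sequence(lens)                       # 1..len per read
    ref_pos <- rep(a$ref_start, lens) + within - 1L
    if (any(ref_pos < 0L | ref_pos >= L))
      stop("alignment extends beyond the reference (length ", L, ")")
    base <- unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE)
    str <- rep(a$strand, lens)
    len_rep <- rep(lens, lens)
    dist5 <- ifelse(str == "+", within, len_rep - within + 1L)
    parts[[1L]] <- list(aln = idx, ref_pos = ref_pos,
                        ref_base = refv[ref_pos + 1L], base = base,
                        dist5 = dist5, dist3 = len_rep - dist5 + 1L,
                        strand = str)
  }
  if (any(!ungapped)) {
    rows <- which(!ungapped)
    gp <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      ops <- parse_cigar(alignments$cigar[i])
      if (any(!ops$op %in% c("M", "I", "D")))
        stop("unsupported CIGAR in alignment ", alignments$read_id[i], ": ",
             alignments$cigar[i])
      sv <- seq_to_vec(alignments$seq[i])
      read_len <- sum(ops$len[ops$op != "D"])
      rp <- alignments$ref_start[i]; qp <- 0L
      ref_pos <- integer(0); qpos <- integer(0)
      for (j in seq_len(nrow(ops))) {
        n <- ops$len[j]
        if (ops$op[j] == "M") {
          ref_pos <- c(ref_pos, rp + seq_len(n) - 1L)
          qpos <- c(qpos, qp + seq_len(n))
          rp <- rp + n; qp <- qp + n
        } else if (ops$op[j] == "I") {
          qp <- qp + n
        } else {
          rp <- rp + n
        }
      }
      if (any(ref_pos < 0L | ref_pos >= L))
        stop("alignment extends beyond the reference (length ", L, ")")
      d5 <- if (alignments$strand[i] == "+") qpos else read_len - qpos + 1L
      gp[[k]] <- list(aln = rep(i, length(ref_pos)), ref_pos = ref_pos,
                      ref_base = refv[ref_pos + 1L], base = sv[qpos],
                      dist5 = d5, dist3 = read_len - d5 + 1L,
                      strand = rep(alignments$strand[i], length(ref_pos)))
    }
    parts[[length(parts) + 1L]] <- list(
      aln = unlist(lapply(gp, `[[`, "aln")),
      ref_pos = unlist(lapply(gp, `[[`, "ref_pos")),
      ref_base = unlist(lapply(gp, `[[`, "ref_base")),
      base = unlist(lapply(gp, `[[`, "base")),
      dist5 = unlist(lapply(gp, `[[`, "dist5")),
      dist3 = unlist(lapply(gp, `[[`, "dist3")),
      strand = unlist(lapply(gp, `[[`, "strand")))
  }
  if (!length(parts))
    return(list(aln = integer(0), ref_pos = integer(0), ref_base = character(0),
                base = character(0), dist5 = integer(0), dist3 = integer(0),
                strand = character(0)))
  out <- lapply(names(parts[[1L]]), function(nm)
    unlist(lapply(parts, `[[`, nm), use.names = FALSE))
  names(out) <- names(parts[[1L]])
  out
}

# per-alignment identity and aligned length against a reference
# identity = matches / aligned columns, where indel columns count as
# mismatches; aligned_length = number of read bases placed (M + I)
alignment_stats <- function(alignments, reference) {
  n <- nrow(alignments)
  cols <- alignment_columns(alignments, reference)
  match_ct <- integer(n); m_cols <- integer(n)
  if (length(cols$aln)) {
    tab <- tabulate(cols$aln, nbins = n)
    m_cols <- tab
    eq <- cols$base == cols$ref_base & cols$base %in% BASES
    match_ct <- as.integer(tabulate(cols$aln[eq], nbins = n))
  }
  # indel columns from the CIGAR (ungapped alignments have none)
  ins <- del <- integer(n)
  gapped <- which(!grepl("^[0-9]+M$", alignments$cigar))
  for (i in gapped) {
    ops <- parse_cigar(alignments$cigar[i])
    ins[i] <- sum(ops$len[ops$op == "I"])
    del[i] <- sum(ops$len[ops$op == "D"])
  }
  aligned_cols <- m_cols + ins + del
  identity <- ifelse(aligned_cols > 0, match_ct / aligned_cols, 0)
  data.frame(aligned_length = m_cols + ins, identity = identity)
}
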