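#' Find local alignment hits of a query against a reference
#'
#' Exact-word seeding (default word size 9) with ungapped X-drop extension on
#' both strands, reported as maximal non-overlapping hits on the query
#' (best-scoring first). Reverse-strand hits carry forward-strand query
#' coordinates and a reverse-complemented `aligned_query`, so the aligned
#' strings always read in reference orientation. Coordinates are 0-based,
#' half-open. This is a desk-scale surrogate for an external local aligner;
#' [read_local_hits()] ingests external tabular hits bit-compatibly.
#'
#' @param query,reference nucleotide sequences (plain strings).
#' @param query_id id recorded in the hit table.
#' @param word_size exact-match seed length (default 9).
#' @param match,mismatch,xdrop extension scores and X-drop cutoff.
#' @return a `local_hits` data.frame: query_id, ref_start, ref_end,
#'   query_start, query_end, strand, length (alignment columns), matches,
#'   identity, aligned_ref, aligned_query.
#' @export
find_local_hits <- function(query, reference, query_id = "query",
                            word_size = 9L, match = 1L, mismatch = 2L,
                            xdrop = 20L) {
  stopifnot(nchar(query) > 0, nchar(reference) > 0)
  if (word_size < 4L || word_size > 15L) stop("'word_size' must be in 4..15")
  query <- toupper(query); reference <- toupper(reference)
  lq <- nchar(query)

  collect <- function(q, strand) {
    h <- .cpp_seed_hits(q, reference, as.integer(word_size),
                        as.integer(match), as.integer(mismatch),
                        as.integer(xdrop))
    if (!nrow(h)) return(NULL)
    h$strand <- strand
    if (strand == "-") {
      qs <- lq - h$query_end; qe <- lq - h$query_start
      h$query_start <- qs; h$query_end <- qe
    }
    h
  }
  hits <- rbind(collect(query, "+"), collect(revcomp(query), "-"))
  if (is.null(hits) || !nrow(hits)) return(empty_hits())

  hits$length <- hits$query_end - hits$query_start
  hits <- hits[!duplicated(hits[, c("query_start", "query_end", "ref_start", "strand")]), ]
  # maximal non-overlapping on the query, best (matches, length) first
  ord <- order(-hits$matches, -hits$length, hits$query_start, hits$ref_start)
  hits <- hits[ord, , drop = FALSE]
  kept <- logical(0); ks <- integer(0); ke <- integer(0)
  sel <- integer(0)
  for (i in seq_len(nrow(hits))) {
    qs <- hits$query_start[i]; qe <- hits$query_end[i]
    if (!length(ks) || all(qe <= ks | qs >= ke)) {
      sel <- c(sel, i); ks <- c(ks, qs); ke <- c(ke, qe)
    }
  }
  hits <- hits[sel, , drop = FALSE]
  hits <- hits[order(hits$query_start), , drop = FALSE]

  aq <- substring(query, hits$query_start + 1L, hits$query_end)
  minus <- hits$strand == "-"
  if (any(minus)) aq[minus] <- vapply(aq[minus], revcomp, character(1))
  out <- data.frame(query_id = query_id,
                    ref_start = hits$ref_start,
                    ref_end = hits$ref_start + hits$length,
                    query_start = hits$query_start, query_end = hits$query_end,
                    strand = hits$strand, length = hits$length,
                    matches = hits$matches,
                    identity = hits$matches / hits$length,
                    aligned_ref = substring(reference, hits$ref_start + 1L,
                                            hits$ref_start + hits$length),
                    aligned_query = aq, stringsAsFactors = FALSE)
  class(out) <- c("local_hits", "data.frame")
  out
}

empty_hits <- function() {
  out <- data.frame(query_id = character(0), ref_start = integer(0),
                    ref_end = integer(0), query_start = integer(0),
                    query_end = integer(0), strand = character(0),
                    length = integer(0), matches = integer(0),
                    identity = numeric(0), aligned_ref = character(0),
                    aligned_query = character(0), stringsAsFactors = FALSE)
  class(out) <- c("local_hits", "data.frame")
  out
}

#' Filter local hits on length and identity
#'
#' Keeps hits with `length > min_len` *and* `identity > min_identity` — both
#' strict, as the selection is stated (">500 bp", ">95%"): a 500-bp or
#' 95.0%-identity hit is dropped.
#'
#' @param hits a `local_hits` data.frame.
#' @param min_len minimum hit length, exclusive (default 500).
#' @param min_identity minimum hit identity, exclusive (default 0.95).
#' @return the filtered `local_hits`.
#' @export
filter_hits <- function(hits, min_len = 500, min_identity = 0.95) {
  out <- hits[hits$length > min_len & hits$identity > min_identity, , drop = FALSE]
  class(out) <- c("local_hits", "data.frame")
  out
}

#' Project a consensus genome or local hits onto reference coordinates
#'
#' Produces one MSA row of reference length. A consensus genome projects
#' identically (it is already in reference coordinates). Local hits write
#' their aligned query bases at matched reference columns; query insertions
#' relative to the reference are dropped and uncovered columns stay `'-'`.
#' Where hits overlap on the reference, the higher-identity hit wins, then the
#' longer, then the leftmost.
#'
#' @param source a `consensus_genome` or a `local_hits` data.frame.
#' @param reference the reference sequence.
#' @param ref_id optional reference id; a consensus genome built on a
#'   different reference raises an error.
#' @return character scalar of reference length over A,C,G,T,'-'.
#' @export
project_row <- function(source, reference, ref_id = NULL) {
  L <- nchar(reference)
  if (inherits(source, "consensus_genome")) {
    if (!is.null(ref_id) && !identical(source$ref_id, ref_id))
      stop(sprintf("consensus built on '%s', not on '%s'", source$ref_id, ref_id))
    if (nchar(source$sequence) != L)
      stop("consensus length differs from reference length")
    return(source$sequence)
  }
  if (!inherits(source, "local_hits")) stop("unsupported source for project_row")
  row <- rep("-", L)
  if (nrow(source)) {
    if (any(source$ref_end > L))
      stop("hit lies beyond the reference; was it computed on another reference?")
    # write in increasing priority: identity, then length, then leftmost wins
    ord <- order(source$identity, source$length, -source$ref_start)
    for (i in ord) {
      aq <- seq_to_vec(source$aligned_query[i])
      ar <- seq_to_vec(source$aligned_ref[i])
      keep <- ar != "-"                    # drop query insertions
      pos <- source$ref_start[i] + cumsum(keep)  # 1-based ref positions
      row[pos[keep]] <- aq[keep]
    }
    row[!row %in% c(BASES, "-")] <- "-"
  }
  vec_to_seq(row)
}

#' Assemble a reference-anchored whole-genome MSA
#'
#' Stacks projected rows (consensus genomes and/or filtered local-hit sets)
#' into a rectangular alignment in reference coordinates.
#'
#' @param sources named list of `consensus_genome` objects and/or `local_hits`
#'   data.frames.
#' @param reference reference sequence.
#' @param ref_id reference id.
#' @param include_reference add the reference itself as the first row.
#' @return a `ref_msa` list: `ref_id`, `column_coords` (0-based original
#'   reference positions per column) and `rows` (named character vector).
#' @export
build_ref_msa <- function(sources, reference, ref_id = "reference",
                          include_reference = TRUE) {
  if (!length(sources) || is.null(names(sources)))
    stop("'sources' must be a non-empty named list")
  rows <- vapply(sources, project_row, character(1),
                 reference = reference, ref_id = ref_id)
  if (include_reference)
    rows <- c(setNames(toupper(reference), ref_id), rows)
  structure(list(ref_id = ref_id,
                 column_coords = seq_len(nchar(reference)) - 1L,
                 rows = rows), class = "ref_msa")
}

#' Clean a reference-anchored MSA
#'
#' Strain mode first drops rows whose gap fraction exceeds
#' `max_row_gap_frac`, then drops columns whose missing fraction — computed on
#' the surviving rows — exceeds `max_col_missing_frac`. Genus mode applies the
#' column rule only. Both rules are strict (a row at exactly 50% gaps and a
#' column at exactly 10% missing are retained); `'-'` and `'N'` both count as
#' missing. `column_coords` is updated so retained columns keep their original
#' reference positions.
#'
#' @param msa a `ref_msa`.
#' @param max_row_gap_frac row gap-fraction threshold, exclusive (default 0.50).
#' @param max_col_missing_frac column missing-fraction threshold, exclusive
#'   (default 0.10).
#' @param mode `"strain"` (rows then columns) or `"genus"` (columns only).
#' @return the cleaned `ref_msa`.
#' @export
clean_msa <- function(msa, max_row_gap_frac = 0.50,
                      max_col_missing_frac = 0.10,
                      mode = c("strain", "genus")) {
  mode <- match.arg(mode)
  stopifnot(inherits(msa, "ref_msa"))
  m <- msa_matrix(msa)
  miss <- m == "-" | m == "N"
  if (mode == "strain") {
    row_gap <- rowMeans(miss)
    keep_rows <- row_gap <= max_row_gap_frac
    if (!any(keep_rows)) stop("alignment emptied by cleaning (all rows dropped)")
    m <- m[keep_rows, , drop = FALSE]
    miss <- miss[keep_rows, , drop = FALSE]
  }
  col_missing <- colMeans(miss)
  keep_cols <- col_missing <= max_col_missing_frac
  if (!any(keep_cols)) stop("alignment emptied by cleaning (all columns dropped)")
  m <- m[, keep_cols, drop = FALSE]
  structure(list(ref_id = msa$ref_id,
                 column_coords = msa$column_coords[keep_cols],
                 rows = apply(m, 1L, paste0, collapse = "")),
            class = "ref_msa")
}

# rows of a ref_msa as a character matrix (rows x columns)
msa_matrix <- function(msa) {
  stopifnot(inherits(msa, "ref_msa"))
  n <- nchar(msa$rows)
  if (length(unique(n)) != 1L) stop("ragged alignment rows")
  matrix(unlist(strsplit(msa$rows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(msa$rows), byrow = TRUE,
         dimnames = list(names(msa$rows), NULL))
}

msa_from_matrix <- function(m, ref_id, column_coords = NULL) {
  structure(list(ref_id = ref_id,
                 column_coords = if (is.null(column_coords)) seq_len(ncol(m)) - 1L else column_coords,
                 rows = apply(m, 1L, paste0, collapse = "")),
            class = "ref_msa")
}

#' Write / read an MSA as aligned FASTA plus a column-coordinate map
#'
#' @param msa a `ref_msa`.
#' @param path FASTA path; the coordinate map goes to `<path>.coords.tsv`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  ss <- Biostrings::DNAStringSet(msa$rows)
  Biostrings::writeXStringSet(ss, path)
  write_tsv(data.frame(column = seq_along(msa$column_coords),
                       ref_pos = msa$column_coords),
            paste0(path, ".coords.tsv"))
  invisible(path)
}

#' Read local hits from a tabular file
#'
#' Ingests 12-column local-alignment tables extended with `aligned_ref` and
#' `aligned_query` columns (tab-separated, with header), so an external
#' aligner can substitute for [find_local_hits()] bit-compatibly.
#'
#' @param path TSV file with columns query_id, ref_start, ref_end,
#'   query_start, query_end, strand, length, matches, identity, aligned_ref,
#'   aligned_query.
#' @return a `local_hits` data.frame.
#' @export
read_local_hits <- function(path) {
  df <- read_tsv(path)
  need <- c("query_id", "ref_start", "ref_end", "query_start", "query_end",
            "strand", "length", "matches", "identity", "aligned_ref",
            "aligned_query")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  class(df) <- c("local_hits", "data.frame")
  df
}
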