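#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping the package's internal representation
#' (named character vectors of upper-case sequences).
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gsub("-", "N", x)), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame with `read_id`, `seq` and `qual` columns (as
#'   produced by [simulate_reads()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write read alignments as SAM text with NM and MD tags
#'
#' Emits a minimal, spec-compliant SAM file for ungapped (all-`M`) alignments;
#' the NM and MD tags are computed against the supplied reference so external
#' tools can reconstruct the per-base pairing.
#'
#' @param alignments a `read_alignments` data.frame (see [simulate_reads()]).
#' @param reference reference sequence the alignments are anchored to.
#' @param ref_id reference name written in the header and RNAME column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, ref_id, path) {
  if (!all(grepl("^[0-9]+M$", alignments$cigar)))
    stop("write_sam supports ungapped (all-M) alignments only")
  refv <- seq_to_vec(toupper(reference))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_id, length(refv))), con)
  n <- nrow(alignments)
  lines <- character(n)
  for (i in seq_len(n)) {
    a <- alignments[i, ]
    rv <- seq_to_vec(a$seq)
    ref_slice <- refv[(a$ref_start + 1L):(a$ref_start + length(rv))]
    md <- md_tag(rv, ref_slice)
    flag <- if (a$strand == "-") 16L else 0L
    # SAM stores SEQ in reference orientation, which is how `seq` is kept
    lines[i] <- paste(a$read_id, flag, ref_id, a$ref_start + 1L, a$mapq,
                      a$cigar, "*", 0L, 0L, a$seq,
                      strrep("I", length(rv)),
                      sprintf("NM:i:%d", sum(rv != ref_slice)),
                      sprintf("MD:Z:%s", md), sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

md_tag <- function(read_ref_orient, ref_slice) {
  mism <- read_ref_orient != ref_slice
  if (!any(mism)) return(as.character(length(ref_slice)))
  pieces <- character(0); run <- 0L
  for (i in seq_along(mism)) {
    if (mism[i]) {
      pieces <- c(pieces, as.character(run), ref_slice[i]); run <- 0L
    } else run <- run + 1L
  }
  paste0(paste(pieces, collapse = ""), run)
}

#' Read SAM text into a read-alignments table
#'
#' Parses a text SAM file (as written by [write_sam()] or an external mapper)
#' into the package's `read_alignments` representation. CIGARs with
#' `M/=/X/I/D/S/H` operations are supported; the stored `seq` is the read in
#' reference orientation with soft-clipped bases removed.
#'
#' @param path SAM file path.
#' @param sample sample id recorded for all alignments (default: file stem).
#' @return a `read_alignments` data.frame.
#' @export
read_sam <- function(path, sample = NULL) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (is.null(sample)) sample <- sub("\\.sam$", "", basename(path))
  if (!length(ln)) stop("no alignment records in ", path)
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, integer(1)) < 11L)
  if (length(bad)) stop("malformed SAM record at line ", bad[1],
                        ": alignments must carry the 11 mandatory fields")
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  if (any(cigar == "*"))
    stop("alignment without CIGAR (unmapped or missing pairing information)")
  seqs <- toupper(get(10))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  # strip soft/hard clips; store read in reference orientation
  seq_ref <- character(length(seqs))
  cig_core <- character(length(seqs))
  for (i in seq_along(seqs)) {
    ops <- parse_cigar(cigar[i])
    s <- seqs[i]
    if (nrow(ops) && ops$op[1] == "S") { s <- substring(s, ops$len[1] + 1L); ops <- ops[-1, ] }
    nlast <- nrow(ops)
    if (nlast && ops$op[nlast] == "S") { s <- substring(s, 1L, nchar(s) - ops$len[nlast]); ops <- ops[-nlast, ] }
    ops <- ops[ops$op != "H", , drop = FALSE]
    if (any(!ops$op %in% c("M", "=", "X", "I", "D")))
      stop("unsupported CIGAR operation in ", cigar[i])
    seq_ref[i] <- s
    cig_core[i] <- paste0(ops$len, sub("[=X]", "M", ops$op), collapse = "")
  }
  out <- data.frame(read_id = get(1), sample = sample, ref_id = get(3),
                    ref_start = as.integer(get(4)) - 1L, strand = strand,
                    mapq = as.integer(get(5)), cigar = cig_core,
                    seq = seq_ref, stringsAsFactors = FALSE)
  class(out) <- c("read_alignments", "data.frame")
  out
}

parse_cigar <- function(cig) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cig)[[1]]
  toks <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cig))
    stop("cannot parse CIGAR: ", cig)
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

#' Write and read trees in newick format
#'
#' @param tree an ape `phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Persist the simulation ground truth as plain-text tables
#'
#' Writes the mutation, recombination-tract and read-truth tables as TSV and
#' the truth trees as newick next to them.
#'
#' @param truth a `sim_truth` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(truth$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(truth$recomb_tracts, file.path(dir, "recomb_tracts.tsv"))
  if (!is.null(truth$read_truth))
    write_tsv(truth$read_truth, file.path(dir, "read_truth.tsv"))
  if (!is.null(truth$species_tree))
    write_newick(truth$species_tree, file.path(dir, "species_tree.nwk"))
  for (sp in names(truth$strain_trees)) {
    if (!is.null(truth$strain_trees[[sp]]))
      write_newick(truth$strain_trees[[sp]], file.path(dir, paste0(sp, "_strain_tree.nwk")))
  }
  write_tsv(data.frame(genome = names(truth$species), species = truth$species),
            file.path(dir, "species_labels.tsv"))
  invisible(dir)
}
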