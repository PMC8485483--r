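BASES <- c("A", "C", "G", "T")

# sequence <-> per-base character vector
seq_to_vec <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
vec_to_seq <- function(v) paste0(v, collapse = "")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

revcomp <- function(x) {
  v <- rev(seq_to_vec(x))
  cmp <- COMPLEMENT[v]
  cmp[is.na(cmp)] <- "N"
  vec_to_seq(unname(cmp))
}

revcomp_vec <- function(v) {
  cmp <- COMPLEMENT[rev(v)]
  cmp[is.na(cmp)] <- "N"
  unname(cmp)
}

# random sequence with a given GC content
random_seq_vec <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# Exact Jukes-Cantor evolution of a base vector over branch length b
# (expected substitutions/site): each site differs with probability
# 3/4 (1 - exp(-4b/3)) and switches to a uniformly chosen other base,
# which is exactly the JC transition kernel.
evolve_jc <- function(v, b) {
  if (b <= 0) return(v)
  p <- 0.75 * (1 - exp(-4 * b / 3))
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    code <- match(v[hit], BASES)
    v[hit] <- BASES[((code - 1L + shift) %% 4L) + 1L]
  }
  v
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("'%s' must be a single %s number", name,
                        if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

# Jaccard overlap of two half-open intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- max(e1, e2) - min(s1, s2)
  if (uni <= 0) return(0)
  inter / uni
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}
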