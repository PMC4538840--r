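# Small construction utilities shared across the tests.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute the given 1-based positions with a different base
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# k distinct substitution positions spread evenly over [lo, hi]; keeping
# lo >= 3 and hi well short of the sequence end leaves a clean seed window
# at the tail and stops the local aligner from trimming the head (the
# running score never returns to zero)
spread_positions <- function(k, lo, hi) {
  p <- round(seq(lo, hi, length.out = k))
  stopifnot(!anyDuplicated(p))
  p
}

make_genome <- function(id, seqs, ...) {
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("%s_g%03d", id, seq_along(seqs))
  }
  genome(id, seqs, ...)
}

# one pair-results row with symmetric defaults
pair_row <- function(a, b, af_ab = 1, af_ba = af_ab, gani_ab = 100,
                     gani_ba = gani_ab, n_bbh = 10L) {
  data.frame(genome_a = a, genome_b = b, af_ab = af_ab, af_ba = af_ba,
             gani_ab = gani_ab, gani_ba = gani_ba, n_bbh = as.integer(n_bbh),
             stringsAsFactors = FALSE)
}

pair_rows <- function(...) do.call(rbind, list(...))

# clusters in the consolidate_cliques() output shape, from member vectors
fake_clusters <- function(...) {
  members <- list(...)
  lapply(seq_along(members), function(i) {
    m <- sort(members[[i]])
    list(cluster_id = sprintf("C%04d", i),
         kind = if (length(m) == 1) "singleton" else "clique",
         members = m, member_cliques = list())
  })
}

# write a FASTA file from a named character vector; returns the path
write_fasta <- function(seqs, path = tempfile(fileext = ".fna")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# reverse complement for test constructions
revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

empty_bbh_df <- function() {
  data.frame(gene_a = character(), gene_b = character(), identity = numeric(),
             aln_length = integer(), len_a = integer(), len_b = integer(),
             score = integer(), stringsAsFactors = FALSE)
}

# do two sequences share any exact k-length word?
shares_any_word <- function(q, s, k) {
  words <- function(x) {
    n <- nchar(x)
    if (n < k) return(character())
    unique(substring(x, 1:(n - k + 1), k:n))
  }
  length(intersect(words(q), words(s))) > 0
}
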