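#' Alignment parameters
#'
#' Settings for the k-mer seeded local aligner and the BBH retention
#' filter.  Candidate gene pairs must share at least one exact `word_size`
#' nucleotide word; each candidate pair is then aligned with an exact
#' affine-gap local (Smith-Waterman) algorithm under the given scores.  A
#' gap of length L costs `gap_open + L * gap_extend`.  The retention filter
#' keeps bidirectional best hits with at least `min_identity` percent
#' identity over at least `min_cov` of the shorter gene (both bounds
#' inclusive).
#'
#' @param word_size Seed word length in bp (>= 4).
#' @param match,mismatch Per-column scores (mismatch negative).
#' @param gap_open,gap_extend Gap penalties (negative).
#' @param min_identity Minimum percent identity for a retained BBH.
#' @param min_cov Minimum aligned fraction of the shorter gene.
#' @param both_strands If `TRUE`, also align the reverse complement of the
#'   query and keep the better alignment (genes are conventionally stored
#'   5'->3' on the coding strand, so the default searches forward only).
#' @return An object of class `align_params`.
#' @export
align_params <- function(word_size = 11L, match = 1L, mismatch = -1L,
                         gap_open = -5L, gap_extend = -2L,
                         min_identity = 70, min_cov = 0.7,
                         both_strands = FALSE) {
  word_size <- as.integer(word_size)
  stopifnot(word_size >= 4L, word_size <= 15L,
            match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            min_identity >= 0, min_identity <= 100,
            min_cov > 0, min_cov <= 1)
  structure(list(word_size = word_size, match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity, min_cov = min_cov,
                 both_strands = isTRUE(both_strands)),
            class = "align_params")
}

as_align_params <- function(params) {
  if (is.null(params)) return(align_params())
  stopifnot(inherits(params, "align_params"))
  params
}

# tolerance for >=-comparisons of derived floating point quantities
# (e.g. 0.7 * 100 is 70.00000000000001 in double arithmetic)
.f_eps <- 1e-9

#' Align one gene against another
#'
#' Returns the single best-scoring local alignment between two gene
#' sequences, or `NULL` when the pair shares no seed word or has no
#' positive-scoring alignment (the absence of a hit is a valid outcome,
#' not an error).  Identity is `100 * matches / aln_length` over the
#' reported alignment columns (gap columns included); `N` never matches.
#'
#' @param query,subject Gene sequences: character scalars, or length-1
#'   named character vectors as stored in `gani_genome$genes`.
#' @param params An [align_params()] object.
#' @return `NULL`, or a one-row data.frame with `identity`, `aln_length`,
#'   `score`, `strand` (1 forward, -1 reverse complement).
#' @examples
#' align_genes(strrep("ACGT", 75), strrep("ACGT", 75))
#' @export
align_genes <- function(query, subject, params = align_params()) {
  params <- as_align_params(params)
  q <- normalize_sequence(as.character(query)[1L])
  s <- normalize_sequence(as.character(subject)[1L])
  stopifnot(nzchar(q), nzchar(s))
  res <- cpp_align_pair(q, s, params$word_size, params$match, params$mismatch,
                        params$gap_open, params$gap_extend,
                        params$both_strands)
  if (!res$found) return(NULL)
  data.frame(identity = 100 * res$matches / res$cols,
             aln_length = res$cols, score = res$score, strand = res$strand)
}

#' Best hit of every source gene in a target genome
#'
#' For each gene of `source` with at least one seeded, positive-scoring
#' local alignment against a gene of `target`, reports the single best hit.
#' Ties are broken deterministically: score, then identity, then alignment
#' length (all descending), then lexicographically smaller target gene id,
#' then forward strand.  Genes with no hit are absent from the result.
#'
#' @param source,target `gani_genome` objects.
#' @param params An [align_params()] object.
#' @return Data.frame with columns `query_gene_id`, `subject_gene_id`,
#'   `score`, `identity`, `aln_length`, `strand`.
#' @export
best_hits <- function(source, target, params = align_params()) {
  params <- as_align_params(params)
  stopifnot(inherits(source, "gani_genome"), inherits(target, "gani_genome"))
  hits <- cpp_best_hits(unname(source$genes), unname(target$genes),
                        rank(names(target$genes), ties.method = "first"),
                        params$word_size, params$match, params$mismatch,
                        params$gap_open, params$gap_extend,
                        params$both_strands)
  data.frame(query_gene_id = names(source$genes)[hits$query_index],
             subject_gene_id = names(target$genes)[hits$subject_index],
             score = hits$score,
             identity = 100 * hits$matches / hits$aln_length,
             aln_length = hits$aln_length, strand = hits$strand,
             stringsAsFactors = FALSE)
}

#' Bidirectional best hits between two genomes
#'
#' A gene pair (ga, gb) is a BBH when gb is ga's best hit among `b`'s genes
#' and ga is gb's best hit among `a`'s genes.  Retained BBHs must show at
#' least `params$min_identity` percent identity over at least
#' `params$min_cov` of the shorter gene (both thresholds inclusive: 70.0%
#' identity and 0.70 coverage pass at the defaults).  Each gene occurs in
#' at most one retained pair, and the pair set is identical whichever
#' genome is given first.
#'
#' The reported identity and alignment length of a pair are taken from the
#' alignment computed with the gene of the lexicographically smaller genome
#' id as query (a fixed convention so that both argument orders report
#' byte-identical statistics; the two directions differ at most in
#' traceback tie-breaking).
#'
#' @param a,b `gani_genome` objects.
#' @param params An [align_params()] object.
#' @return Data.frame with columns `gene_a`, `gene_b`, `identity`,
#'   `aln_length`, `len_a`, `len_b`, `score` (genes of `a` in `gene_a`).
#' @export
bidirectional_best_hits <- function(a, b, params = align_params()) {
  params <- as_align_params(params)
  stopifnot(inherits(a, "gani_genome"), inherits(b, "gani_genome"))
  ab <- best_hits(a, b, params)
  ba <- best_hits(b, a, params)
  # mutual best: a-gene's best is gb and gb's best is that a-gene
  back <- stats::setNames(ba$subject_gene_id, ba$query_gene_id)
  mutual <- !is.na(back[ab$subject_gene_id]) &
    back[ab$subject_gene_id] == ab$query_gene_id
  ab <- ab[mutual, , drop = FALSE]
  if (!nrow(ab)) return(empty_bbh())
  # statistics from the canonical direction (smaller genome id as query)
  use_ba <- b$genome_id < a$genome_id
  if (use_ba) {
    key <- paste(ba$query_gene_id, ba$subject_gene_id)
    idx <- match(paste(ab$subject_gene_id, ab$query_gene_id), key)
    stats_df <- ba[idx, c("score", "identity", "aln_length"), drop = FALSE]
  } else {
    stats_df <- ab[, c("score", "identity", "aln_length"), drop = FALSE]
  }
  out <- data.frame(gene_a = ab$query_gene_id, gene_b = ab$subject_gene_id,
                    identity = stats_df$identity,
                    aln_length = stats_df$aln_length,
                    len_a = nchar(a$genes[ab$query_gene_id]),
                    len_b = nchar(b$genes[ab$subject_gene_id]),
                    score = stats_df$score, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  keep <- out$identity >= params$min_identity - .f_eps &
    out$aln_length >= params$min_cov * pmin(out$len_a, out$len_b) - .f_eps
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_bbh <- function() {
  data.frame(gene_a = character(), gene_b = character(), identity = numeric(),
             aln_length = integer(), len_a = integer(), len_b = integer(),
             score = integer(), stringsAsFactors = FALSE)
}
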