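#' Alignment fraction (AF) of a genome against another
#'
#' Directional statistic: the sum of the lengths of the source genome's
#' genes that participate in retained BBHs, divided by the source genome's
#' total gene length.  AF = 0 denotes the absence of BBHs and AF = 1
#' complete conservation of all protein-coding genes.
#'
#' @param source The `gani_genome` whose gene content is the denominator.
#' @param bbhs BBH table from [bidirectional_best_hits()].
#' @param side Which column of `bbhs` holds `source`'s genes: `"a"` if
#'   `source` was the first argument of [bidirectional_best_hits()],
#'   `"b"` otherwise.
#' @return AF in `[0, 1]`.
#' @export
alignment_fraction <- function(source, bbhs, side = c("a", "b")) {
  side <- match.arg(side)
  stopifnot(inherits(source, "gani_genome"))
  total <- total_gene_length(source)
  if (total == 0) stop("genome '", source$genome_id, "': total gene length is 0")
  if (!nrow(bbhs)) return(0)
  ids <- bbhs[[paste0("gene_", side)]]
  missing <- setdiff(ids, names(source$genes))
  if (length(missing)) {
    stop("BBH gene id(s) not in genome '", source$genome_id, "': ",
         paste(head(missing, 3L), collapse = ", "))
  }
  sum(nchar(source$genes[ids])) / total
}

#' Directional genome-wide average nucleotide identity (gANI)
#'
#' The sum over retained BBHs of percent identity times alignment length,
#' divided by a denominator that depends on the mode:
#' \describe{
#'   \item{`bbh_gene_lengths`}{the summed lengths of the source genome's
#'     BBH genes (the default; the directional reading consistent with
#'     AF's explicit source-genome denominator).}
#'   \item{`alignment_lengths`}{the summed alignment lengths, i.e. the
#'     length-weighted mean identity of the BBHs (direction-independent).}
#' }
#' Undefined (`NA`) when there are no retained BBHs.  Identity enters the
#' numerator in percent units, so results are percentages in `[0, 100]`
#' for `alignment_lengths` mode (and can drop below the identity cutoff in
#' `bbh_gene_lengths` mode when alignments are shorter than their genes).
#'
#' @inheritParams alignment_fraction
#' @param denominator_mode See above.
#' @return gANI percent, or `NA` when `bbhs` is empty.
#' @export
gani <- function(source, bbhs, side = c("a", "b"),
                 denominator_mode = c("bbh_gene_lengths", "alignment_lengths")) {
  side <- match.arg(side)
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(source, "gani_genome"))
  if (!nrow(bbhs)) return(NA_real_)
  numer <- sum(bbhs$identity * bbhs$aln_length)
  denom <- if (denominator_mode == "alignment_lengths") {
    sum(bbhs$aln_length)
  } else {
    ids <- bbhs[[paste0("gene_", side)]]
    missing <- setdiff(ids, names(source$genes))
    if (length(missing)) {
      stop("BBH gene id(s) not in genome '", source$genome_id, "': ",
           paste(head(missing, 3L), collapse = ", "))
    }
    sum(nchar(source$genes[ids]))
  }
  numer / denom
}

#' Compare a pair of genomes
#'
#' Runs the bidirectional best-hit search once and derives the four
#' directional statistics AF(A->B), AF(B->A), gANI(A->B), gANI(B->A).
#' The result is symmetric: swapping the arguments swaps the a/b fields
#' and leaves the values unchanged.
#'
#' @param a,b `gani_genome` objects.
#' @param params An [align_params()] object.
#' @param denominator_mode gANI denominator, see [gani()].
#' @return One-row data.frame with columns `genome_a`, `genome_b`,
#'   `af_ab`, `af_ba`, `gani_ab`, `gani_ba`, `n_bbh`; the retained BBH
#'   table is attached as attribute `"bbh"`.
#' @examples
#' g <- generate_ancestor(5, mean_len = 300, seed = 1)
#' compare_pair(g, g)
#' @export
compare_pair <- function(a, b, params = align_params(),
                         denominator_mode = c("bbh_gene_lengths",
                                              "alignment_lengths")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(a, "gani_genome"), inherits(b, "gani_genome"))
  bbhs <- bidirectional_best_hits(a, b, params)
  out <- data.frame(
    genome_a = a$genome_id, genome_b = b$genome_id,
    af_ab = alignment_fraction(a, bbhs, side = "a"),
    af_ba = alignment_fraction(b, bbhs, side = "b"),
    gani_ab = gani(a, bbhs, side = "a", denominator_mode = denominator_mode),
    gani_ba = gani(b, bbhs, side = "b", denominator_mode = denominator_mode),
    n_bbh = nrow(bbhs), stringsAsFactors = FALSE)
  attr(out, "bbh") <- bbhs
  out
}

#' All-vs-all pairwise comparison of a genome collection
#'
#' Computes [compare_pair()] for every unordered genome pair, with
#' `genome_a < genome_b` lexicographically and rows sorted the same way,
#' so output order is deterministic.
#'
#' @param genomes List of `gani_genome` objects (unique ids).
#' @param params An [align_params()] object.
#' @param denominator_mode gANI denominator, see [gani()].
#' @return Pair-results data.frame (see [write_pair_results()]).
#' @export
all_vs_all <- function(genomes, params = align_params(),
                       denominator_mode = c("bbh_gene_lengths",
                                            "alignment_lengths")) {
  denominator_mode <- match.arg(denominator_mode)
  ids <- vapply(genomes, `[[`, character(1L), "genome_id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s): ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  }
  genomes <- genomes[order(ids)]
  ids <- sort(ids)
  n <- length(genomes)
  if (n < 2L) {
    stop("all_vs_all needs at least two genomes")
  }
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      res <- compare_pair(genomes[[i]], genomes[[j]], params,
                          denominator_mode = denominator_mode)
      attr(res, "bbh") <- NULL
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
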