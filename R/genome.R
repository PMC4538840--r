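#' Construct a genome object
#'
#' A genome is the ordered set of its protein-coding gene nucleotide
#' sequences plus optional assembly/taxonomy metadata.  All downstream
#' pairwise statistics (AF, gANI) are defined over these gene sequences;
#' intergenic sequence plays no role.
#'
#' Sequences are normalised on construction: lower case is raised, `U` is
#' mapped to `T`, IUPAC ambiguity codes other than `A`/`C`/`G`/`T` are
#' mapped to `N`, and any non-IUPAC character is an error.  `N` bases are
#' retained and always count as mismatches during alignment.
#'
#' @param genome_id Character scalar, unique within a collection.
#' @param genes Named character vector of gene nucleotide sequences (names
#'   are gene ids, unique within the genome), or a
#'   [Biostrings::DNAStringSet].
#' @param genome_length Optional total assembly length in bp (used by the
#'   coding-density quality filter).
#' @param scaffold_count Optional number of scaffolds.
#' @param species_label Optional species name; `NA`, `""`, `"unclassified"`
#'   or a label ending in `sp.` mark the genome as unclassified.
#' @param is_type_strain Logical flag; `TRUE` marks the genome as the type
#'   strain of its species.
#' @return An object of class `gani_genome`.
#' @examples
#' g <- genome("G1", c(gene1 = "ATGACGTGA", gene2 = "atgccctaa"))
#' total_gene_length(g)
#' @export
genome <- function(genome_id, genes, genome_length = NA_real_,
                   scaffold_count = NA_integer_, species_label = NA_character_,
                   is_type_strain = FALSE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (methods::is(genes, "XStringSet")) {
    genes <- stats::setNames(as.character(genes), names(genes))
  }
  stopifnot(is.character(genes))
  if (length(genes) < 1L) stop("genome '", genome_id, "': no genes")
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("genome '", genome_id, "': all genes must be named")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("genome '", genome_id, "': duplicate gene id(s): ",
         paste(dup, collapse = ", "))
  }
  genes <- vapply(genes, normalize_sequence, character(1L))
  if (any(!nzchar(genes))) {
    stop("genome '", genome_id, "': zero-length gene sequence(s): ",
         paste(ids[!nzchar(genes)], collapse = ", "))
  }
  structure(
    list(genome_id = genome_id, genes = genes,
         genome_length = as.numeric(genome_length),
         scaffold_count = as.integer(scaffold_count),
         species_label = as.character(species_label),
         is_type_strain = isTRUE(is_type_strain)),
    class = "gani_genome")
}

# Raise case, map U->T, map non-ACGT IUPAC codes to N, reject anything else.
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTRYSWKMBDHVN]", "", x)
  if (nzchar(bad)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  gsub("[RYSWKMBDHV]", "N", x)
}

#' @export
print.gani_genome <- function(x, ...) {
  cat(sprintf("<gani_genome> %s: %d genes, %d bp coding", x$genome_id,
              length(x$genes), total_gene_length(x)))
  if (!is.na(x$species_label)) cat(sprintf(" [%s]", x$species_label))
  cat("\n")
  invisible(x)
}

#' Total coding length of a genome
#'
#' Sum of the lengths of all genes, in bp.  This is the AF denominator for
#' the genome when it is the source of a directional comparison.
#'
#' @param genome A `gani_genome`.
#' @return Integer, total gene length in bp.
#' @export
total_gene_length <- function(genome) {
  stopifnot(inherits(genome, "gani_genome"))
  sum(nchar(genome$genes))
}

#' Number of genes in a genome
#' @param genome A `gani_genome`.
#' @return Integer gene count.
#' @export
gene_count <- function(genome) {
  stopifnot(inherits(genome, "gani_genome"))
  length(genome$genes)
}

#' Remove genes from a genome
#'
#' Utility used when constructing genomes with controlled gene content
#' (e.g. genome-reduction scenarios).  The result keeps the remaining genes
#' in their original order.
#'
#' @param genome A `gani_genome`.
#' @param gene_ids Character vector of gene ids to drop.
#' @param new_id Optional replacement genome id.
#' @return A `gani_genome` without the named genes.
#' @export
drop_genes <- function(genome, gene_ids, new_id = genome$genome_id) {
  stopifnot(inherits(genome, "gani_genome"))
  missing <- setdiff(gene_ids, names(genome$genes))
  if (length(missing)) {
    stop("gene id(s) not in genome '", genome$genome_id, "': ",
         paste(missing, collapse = ", "))
  }
  keep <- genome$genes[setdiff(names(genome$genes), gene_ids)]
  if (!length(keep)) stop("dropping all genes of genome '", genome$genome_id, "'")
  genome(new_id, keep, genome$genome_length, genome$scaffold_count,
         genome$species_label, genome$is_type_strain)
}

# Is a species label "named"?  NA, empty, 'unclassified', or a genus-only
# 'sp.' designation all count as unlabeled.
is_named_species <- function(label) {
  !is.na(label) & nzchar(trimws(label)) &
    tolower(trimws(label)) != "unclassified" &
    !grepl("(^|\\s)sp\\.?$", tolower(trimws(label)))
}
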