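# Deterministic synthetic genome generator.
#
# All generators are pure functions of their parameters and seed (the
# caller's RNG state is saved and restored).  Divergence knobs use
# exact-count semantics — floor(d * length) substituted positions per
# gene, ceiling(g * gene_count) lost genes — so analytic expectations
# (e.g. per-gene identity exactly 1 - d) hold exactly rather than in
# distribution.  Gene lengths are drawn from the multiples of 100 bp
# spanning mean_len +/- 50%, which keeps d * length integral for the
# percent-scale divergence values used in practice.

#' Generate a random ancestral genome
#'
#' Genes are i.i.d. uniform-base sequences; at these sizes all genes are
#' pairwise dissimilar with overwhelming probability, so every gene's only
#' plausible ortholog in a derived genome is its own descendant.
#'
#' @param n_genes Number of genes (>= 1).
#' @param mean_len Mean gene length in bp (rounded to a multiple of 100,
#'   minimum 200); lengths are drawn uniformly from the multiples of 100
#'   spanning `mean_len` +/- 50%.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param genome_id Genome id (defaults to a seed-derived id).
#' @return A `gani_genome`.
#' @examples
#' g <- generate_ancestor(10, mean_len = 300, seed = 7)
#' gene_count(g)
#' @export
generate_ancestor <- function(n_genes, mean_len = 900, seed,
                              genome_id = sprintf("synth_s%d", seed)) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L, mean_len >= 200)
  mean_len <- 100 * round(mean_len / 100)
  half <- 100 * floor(mean_len / 2 / 100)
  pool <- seq(mean_len - half, mean_len + half, by = 100)
  withr::with_seed(seed, {
    lens <- sample(pool, n_genes, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1L))
    names(seqs) <- sprintf("g%04d", seq_len(n_genes))
    genome(genome_id, seqs)
  })
}

#' Evolve a genome with controlled divergence
#'
#' Applies, in order: whole-gene loss, per-gene substitutions, optional
#' indels, and draft-style truncation of gene ends.
#' \itemize{
#'   \item Gene loss removes `ceiling(g * gene_count)` genes chosen
#'     uniformly at random.
#'   \item Substitutions change exactly `floor(d * length)` distinct
#'     positions per gene, each to a base drawn uniformly from the three
#'     alternatives, so per-gene identity to the parent is exactly
#'     `1 - floor(d * length) / length`.
#'   \item Indels: `floor(indel_rate * length)` single-base insertions or
#'     deletions (coin-flip each) at uniform positions.
#'   \item Truncation clips `floor(truncate_fraction * length)` bases per
#'     gene, randomly apportioned between the 5' and 3' ends (emulating
#'     genes broken at contig boundaries in draft assemblies).
#' }
#'
#' @param genome Parent `gani_genome`.
#' @param d Substitution fraction in `[0, 1)`.
#' @param g Gene-loss fraction in `[0, 1)`.
#' @param indel_rate Indels per bp (>= 0).
#' @param truncate_fraction Fraction of each gene clipped, in `[0, 1)`.
#' @param seed Integer seed.
#' @param child_id Id of the derived genome.
#' @return A `gani_genome` with the same species metadata as the parent.
#' @export
evolve_genome <- function(genome, d = 0, g = 0, indel_rate = 0,
                          truncate_fraction = 0, seed,
                          child_id = paste0(genome$genome_id, "_ev", seed)) {
  stopifnot(inherits(genome, "gani_genome"),
            d >= 0, d < 1, g >= 0, g < 1, indel_rate >= 0,
            truncate_fraction >= 0, truncate_fraction < 1)
  withr::with_seed(seed, {
    genes <- genome$genes
    if (g > 0) {
      # epsilon guards keep the exact counts exact in double arithmetic
      # (e.g. 0.4 * 20 evaluates to 8.000000000000002)
      n_lose <- ceiling(g * length(genes) - 1e-9)
      if (n_lose >= length(genes)) stop("gene loss would remove every gene")
      lost <- sample(names(genes), n_lose)
      genes <- genes[setdiff(names(genes), lost)]
    }
    genes <- vapply(genes, mutate_gene, character(1L), d = d,
                    indel_rate = indel_rate,
                    truncate_fraction = truncate_fraction)
    genome(child_id, genes, genome$genome_length, genome$scaffold_count,
           genome$species_label, genome$is_type_strain)
  })
}

# substitutions + indels + truncation for one gene (RNG already seeded)
mutate_gene <- function(seq, d, indel_rate, truncate_fraction) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  n_sub <- floor(d * L + 1e-9)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
  }
  n_ind <- floor(indel_rate * L + 1e-9)
  if (n_ind > 0) {
    for (k in seq_len(n_ind)) {
      if (runif(1L) < 0.5 && length(chars) > 1L) {
        chars <- chars[-sample.int(length(chars), 1L)]
      } else {
        p <- sample.int(length(chars) + 1L, 1L)
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1L),
                        after = p - 1L)
      }
    }
  }
  if (truncate_fraction > 0) {
    cut <- floor(truncate_fraction * length(chars) + 1e-9)
    if (cut > 0) {
      head_cut <- sample.int(cut + 1L, 1L) - 1L
      tail_cut <- cut - head_cut
      chars <- chars[seq.int(head_cut + 1L, length(chars) - tail_cut)]
    }
  }
  paste(chars, collapse = "")
}

# controlled gene removal by cumulative length: drops a contiguous block of
# the gene list (head or tail) whose summed length is closest to `frac` of
# the total; used by plant_collection to make AF values predictable
reduce_genome <- function(genome, frac, from = c("head", "tail"), new_id) {
  from <- match.arg(from)
  lens <- nchar(genome$genes)
  cum <- cumsum(if (from == "head") lens else rev(lens))
  k <- which.min(abs(cum - frac * sum(lens)))
  ids <- if (from == "head") names(genome$genes)[seq_len(k)]
         else rev(names(genome$genes))[seq_len(k)]
  drop_genes(genome, ids, new_id = new_id)
}

#' Generate a genome collection with planted species structure
#'
#' Three scenarios used throughout testing:
#' \describe{
#'   \item{`fig2d`}{seven named species realizing all four species
#'     categories: one clean clique (single homogeneous), one species
#'     split over two clean cliques (multiple homogeneous), one clique
#'     shared by two species (single heterogeneous for both), and one
#'     species spread over two mixed cliques (multiple heterogeneous,
#'     with its two co-occupants single heterogeneous).}
#'   \item{`clique_group`}{six genomes from one ancestor: four full
#'     genomes plus two genome-reduced ones with complementary gene
#'     content, so the reduced pair falls below the AF threshold while
#'     everything else stays linked — two overlapping maximal cliques
#'     that must consolidate into a single clique-group.}
#'   \item{`bacillus_like`}{three clusters of three genomes with
#'     inter-cluster gANI inside (92, 96.5): related above the background
#'     but below the species threshold, so no inter-cluster edge exists
#'     at the defaults.}
#' }
#'
#' @param scenario One of `"fig2d"`, `"clique_group"`, `"bacillus_like"`.
#' @param seed Integer seed.
#' @param n_genes Genes per ancestral genome.
#' @param mean_len Mean gene length in bp.
#' @return A list with `genomes` (named list of `gani_genome` with species
#'   labels), `labels` (named character vector), and `truth` (list with
#'   `clusters` — list of member-id sets — plus scenario-specific fields
#'   such as `categories`).
#' @export
plant_collection <- function(scenario = c("fig2d", "clique_group",
                                          "bacillus_like"),
                             seed, n_genes = 30, mean_len = 300) {
  scenario <- match.arg(scenario)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 64L))
  s <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      sub_seeds[k]
    }
  })
  anc <- function(id) generate_ancestor(n_genes, mean_len, seed = s(),
                                        genome_id = id)
  child <- function(parent, id, d = 0.005, ...) {
    evolve_genome(parent, d = d, seed = s(), child_id = id, ...)
  }
  set_species <- function(genome, species, type = FALSE) {
    genome$species_label <- species
    genome$is_type_strain <- type
    genome
  }

  if (scenario == "fig2d") {
    spec_plan <- list(
      # species -> list of (ancestor tag, members per cluster)
      black = list(c("A1", 3L)),
      yellow = list(c("A2", 2L), c("A3", 2L)),
      pink = list(c("A4", 2L)), purple = list(c("A4", 1L)),
      blue = list(c("A5", 1L), c("A6", 1L)),
      orange = list(c("A5", 2L)), brown = list(c("A6", 1L)))
    ancestors <- list()
    for (tag in c("A1", "A2", "A3", "A4", "A5", "A6")) {
      ancestors[[tag]] <- anc(tag)
    }
    genomes <- list()
    for (sp in names(spec_plan)) {
      i <- 0L
      for (part in spec_plan[[sp]]) {
        for (k in seq_len(as.integer(part[2L]))) {
          i <- i + 1L
          id <- sprintf("%s_%02d", sp, i)
          genomes[[id]] <- set_species(child(ancestors[[part[1L]]], id), sp)
        }
      }
    }
    truth_clusters <- list(
      c("black_01", "black_02", "black_03"),
      c("yellow_01", "yellow_02"), c("yellow_03", "yellow_04"),
      c("pink_01", "pink_02", "purple_01"),
      c("blue_01", "orange_01", "orange_02"),
      c("blue_02", "brown_01"))
    categories <- c(black = "single_homogeneous",
                    yellow = "multiple_homogeneous",
                    pink = "single_heterogeneous",
                    purple = "single_heterogeneous",
                    blue = "multiple_heterogeneous",
                    orange = "single_heterogeneous",
                    brown = "single_heterogeneous")
    truth <- list(clusters = truth_clusters, categories = categories)
  } else if (scenario == "clique_group") {
    a <- anc("CGanc")
    genomes <- list()
    for (k in 1:4) {
      id <- sprintf("full_%02d", k)
      genomes[[id]] <- set_species(child(a, id), "plena")
    }
    # complementary 35% genome reductions: each reduced genome keeps enough
    # shared content with the full genomes (AF ~ 0.65 >= 0.6) but the two
    # reduced genomes overlap on only ~30% of the ancestral gene set
    # (AF ~ 0.46 < 0.6), breaking that single link
    r1 <- reduce_genome(a, 0.35, from = "head", new_id = "reduced_01")
    r2 <- reduce_genome(a, 0.35, from = "tail", new_id = "reduced_02")
    genomes[["reduced_01"]] <- set_species(child(r1, "reduced_01"), "plena")
    genomes[["reduced_02"]] <- set_species(child(r2, "reduced_02"), "plena")
    truth <- list(clusters = list(sort(names(genomes))),
                  kind = "clique_group",
                  missing_links = list(c("reduced_01", "reduced_02")))
  } else {  # bacillus_like
    a <- anc("BLanc")
    genomes <- list()
    truth_clusters <- list()
    for (cl in 1:3) {
      sub <- evolve_genome(a, d = 0.025, seed = s(),
                           child_id = sprintf("BLsub%d", cl))
      members <- character(3L)
      for (k in 1:3) {
        id <- sprintf("cl%d_%02d", cl, k)
        members[k] <- id
        genomes[[id]] <- set_species(child(sub, id),
                                     sprintf("group%d", cl))
      }
      truth_clusters[[cl]] <- members
    }
    truth <- list(clusters = truth_clusters,
                  inter_gani_range = c(92, 96.5))
  }
  labels <- vapply(genomes, `[[`, character(1L), "species_label")
  list(genomes = genomes, labels = labels, truth = truth)
}

#' Write a planted collection to disk
#'
#' Writes one gene FASTA per genome, a `metadata.tsv` sidecar and a
#' `truth.json` file (planted cluster memberships and categories) into
#' `dir`.  Synthetic genome lengths are back-calculated from a nominal
#' coding density of 1000 genes/Mb so the collection passes
#' [quality_filter()] at the default bounds.
#'
#' @param collection A list from [plant_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- list()
  for (g in collection$genomes) {
    set <- Biostrings::DNAStringSet(g$genes)
    Biostrings::writeXStringSet(set, file.path(dir,
                                               paste0(g$genome_id, ".fna")))
    md[[length(md) + 1L]] <- data.frame(
      genome_id = g$genome_id, species_label = g$species_label,
      genome_length_bp = round(gene_count(g) / 1000 * 1e6),
      scaffold_count = 1L, is_type_strain = g$is_type_strain,
      stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, md), file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(collection$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
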