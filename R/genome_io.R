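#' Read a gene FASTA file into a genome object
#'
#' Expects one FASTA record per predicted protein-coding gene (CDS),
#' nucleotide alphabet.  Record ids are the first whitespace-delimited
#' token of each header and must be unique.  Sequences are normalised as
#' described in [genome()].
#'
#' @param path Path to a FASTA file with at least one record.
#' @param genome_id Genome id; defaults to the file name without extension.
#' @return A `gani_genome`.
#' @export
read_gene_fasta <- function(path, genome_id = sub("\\.(fa|fna|fasta)$", "",
                                                  basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no genes in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- stats::setNames(as.character(set), ids)
  genome(genome_id, seqs)
}

#' Read all gene FASTA files in a directory
#'
#' @param dir Directory containing `.fa` / `.fna` / `.fasta` files, one per
#'   genome (genome id = file name without extension).
#' @param metadata Optional metadata table from [read_genome_metadata()]
#'   to attach to the genomes.
#' @return Named list of `gani_genome` objects, sorted by genome id.
#' @export
read_genome_dir <- function(dir, metadata = NULL) {
  files <- list.files(dir, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in directory: ", dir)
  genomes <- lapply(files, read_gene_fasta)
  names(genomes) <- vapply(genomes, `[[`, character(1L), "genome_id")
  genomes <- genomes[order(names(genomes))]
  if (!is.null(metadata)) genomes <- apply_metadata(genomes, metadata)
  genomes
}

#' Read a genome metadata table
#'
#' Tab-separated sidecar table keyed by genome id.  Recognised columns:
#' `genome_id` (required), `species_label`, `genome_length_bp`,
#' `scaffold_count`, `is_type_strain`.  Missing optional columns are
#' treated as all-`NA`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the five canonical columns.
#' @export
read_genome_metadata <- function(path) {
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"genome_id" %in% names(md)) stop("metadata lacks a genome_id column")
  if (anyDuplicated(md$genome_id)) {
    stop("duplicate genome_id in metadata: ",
         paste(unique(md$genome_id[duplicated(md$genome_id)]), collapse = ", "))
  }
  for (col in c("species_label", "genome_length_bp", "scaffold_count",
                "is_type_strain")) {
    if (!col %in% names(md)) md[[col]] <- NA
  }
  md$genome_length_bp <- as.numeric(md$genome_length_bp)
  md$scaffold_count <- as.integer(md$scaffold_count)
  md$is_type_strain <- as.logical(md$is_type_strain)
  md[c("genome_id", "species_label", "genome_length_bp", "scaffold_count",
       "is_type_strain")]
}

#' Attach metadata to a list of genomes
#'
#' @param genomes Named list of `gani_genome` objects.
#' @param metadata Data.frame from [read_genome_metadata()].
#' @return The list with metadata fields filled in where present.
#' @export
apply_metadata <- function(genomes, metadata) {
  idx <- match(names(genomes), metadata$genome_id)
  for (k in seq_along(genomes)) {
    i <- idx[k]
    if (is.na(i)) next
    genomes[[k]]$genome_length <- metadata$genome_length_bp[i]
    genomes[[k]]$scaffold_count <- metadata$scaffold_count[i]
    genomes[[k]]$species_label <- as.character(metadata$species_label[i])
    genomes[[k]]$is_type_strain <- isTRUE(metadata$is_type_strain[i])
  }
  genomes
}

#' Genome quality filter (coding density and scaffold count)
#'
#' Flags genomes whose predicted coding density falls outside
#' `[min_density, max_density]` genes per Mb or whose scaffold count is
#' not strictly below `max_scaffolds`.  The density filter screens out
#' genomes whose gene predictions are distorted by fragmentation or
#' annotation errors, which would otherwise distort AF and gANI.  Density
#' bounds are inclusive; the scaffold bound is strict (`<`).  The report is
#' advisory: dropping failing genomes is the caller's decision.
#'
#' @param genome A `gani_genome` with `genome_length` and `scaffold_count`
#'   metadata (if either is missing, `passed` is `NA` and the reasons
#'   mention missing metadata).
#' @param min_density,max_density Acceptable coding density in genes/Mb.
#' @param max_scaffolds Scaffold count must be strictly below this.
#' @return One-row data.frame: `genome_id`, `coding_density`,
#'   `scaffold_count`, `passed`, `reasons` (`;`-joined, empty when passed).
#' @examples
#' g <- genome("G1", c(g1 = strrep("ACGT", 100)), genome_length = 4e5,
#'             scaffold_count = 10)
#' quality_filter(g)  # density 2.5 genes/Mb: fails the density bound
#' @export
quality_filter <- function(genome, min_density = 700, max_density = 1200,
                           max_scaffolds = 2500) {
  stopifnot(inherits(genome, "gani_genome"))
  reasons <- character()
  density <- NA_real_
  if (!is.na(genome$genome_length)) {
    if (genome$genome_length == 0) {
      stop("genome '", genome$genome_id, "': genome_length is 0")
    }
    density <- gene_count(genome) / (genome$genome_length / 1e6)
  }
  if (is.na(genome$genome_length) || is.na(genome$scaffold_count)) {
    reasons <- "metadata missing"
    passed <- NA
  } else {
    if (density < min_density || density > max_density) {
      reasons <- c(reasons, "coding density")
    }
    if (genome$scaffold_count >= max_scaffolds) {
      reasons <- c(reasons, "scaffold count")
    }
    passed <- length(reasons) == 0L
  }
  data.frame(genome_id = genome$genome_id, coding_density = density,
             scaffold_count = if (is.na(genome$scaffold_count)) NA_integer_
                              else genome$scaffold_count,
             passed = passed, reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quality report for a genome collection
#'
#' @param genomes List of `gani_genome` objects.
#' @inheritParams quality_filter
#' @return Data.frame with one [quality_filter()] row per genome.
#' @export
quality_report <- function(genomes, min_density = 700, max_density = 1200,
                           max_scaffolds = 2500) {
  do.call(rbind, lapply(genomes, quality_filter, min_density = min_density,
                        max_density = max_density,
                        max_scaffolds = max_scaffolds))
}

pair_result_columns <- c("genome_a", "genome_b", "af_ab", "af_ba",
                         "gani_ab", "gani_ba", "n_bbh")

validate_pair_results <- function(df, where = "pair results") {
  missing <- setdiff(pair_result_columns, names(df))
  if (length(missing)) {
    stop(where, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  af <- c(df$af_ab, df$af_ba)
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    stop(where, ": AF values must lie in [0, 1]")
  }
  gani <- c(df$gani_ab, df$gani_ba)
  if (any(gani[!is.na(gani)] < 0 | gani[!is.na(gani)] > 100)) {
    stop(where, ": gANI values must lie in [0, 100] or be NA")
  }
  if (any(is.na(df$n_bbh)) || any(df$n_bbh < 0)) {
    stop(where, ": n_bbh must be a non-negative integer")
  }
  if (any(df$n_bbh == 0 & (df$af_ab != 0 | df$af_ba != 0))) {
    stop(where, ": AF must be 0 when n_bbh is 0")
  }
  invisible(df)
}

#' Write / read a genome pair-results table
#'
#' Fixed tab-separated format with columns `genome_a`, `genome_b`, `af_ab`,
#' `af_ba`, `gani_ab`, `gani_ba`, `n_bbh`.  AF is written with 10 decimals
#' and gANI with 9 so that a round trip is lossless to well below 1e-9;
#' undefined gANI (no retained BBHs) is serialized as `NA`.
#'
#' @param results Data.frame of pair results (one row per unordered genome
#'   pair) as produced by [compare_pair()] / [all_vs_all()].
#' @param path Output (input) file path.
#' @return `write_pair_results()` returns `path` invisibly;
#'   `read_pair_results()` returns the validated data.frame.
#' @export
write_pair_results <- function(results, path) {
  validate_pair_results(results)
  out <- data.frame(
    genome_a = results$genome_a, genome_b = results$genome_b,
    af_ab = sprintf("%.10f", results$af_ab),
    af_ba = sprintf("%.10f", results$af_ba),
    gani_ab = ifelse(is.na(results$gani_ab), "NA",
                     sprintf("%.9f", results$gani_ab)),
    gani_ba = ifelse(is.na(results$gani_ba), "NA",
                     sprintf("%.9f", results$gani_ba)),
    n_bbh = as.integer(results$n_bbh), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_results
#' @export
read_pair_results <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty pair-results file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, pair_result_columns)) {
    stop("pair-results header mismatch in ", path, " (line 1)")
  }
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 7L) {
      stop("malformed pair-results row at line ", i + 1L, " of ", path,
           ": expected 7 fields, got ", length(fields))
    }
    num <- suppressWarnings(as.numeric(fields[3:6]))
    bad <- which(is.na(num) & fields[3:6] != "NA")
    nb <- suppressWarnings(as.integer(fields[7L]))
    if (length(bad) || is.na(nb)) {
      stop("malformed pair-results row at line ", i + 1L, " of ", path)
    }
    rows[[i]] <- data.frame(genome_a = fields[1L], genome_b = fields[2L],
                            af_ab = num[1L], af_ba = num[2L],
                            gani_ab = num[3L], gani_ba = num[4L],
                            n_bbh = nb, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(genome_a = character(), genome_b = character(),
               af_ab = numeric(), af_ba = numeric(), gani_ab = numeric(),
               gani_ba = numeric(), n_bbh = integer(),
               stringsAsFactors = FALSE)
  }
  validate_pair_results(df, where = path)
  df
}
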