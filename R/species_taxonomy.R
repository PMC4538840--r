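# Audit of existing species labels against genome clusters.
#
# Genomes without a usable species name (NA, "", "unclassified", or a
# genus-only "sp." designation) never make a cluster heterogeneous: they
# are set aside from categorisation and considered only for assignment
# proposals.

# named list: species -> character vector of cluster ids occupied
occupied_units <- function(clusters, labels) {
  tab <- clusters_table(clusters)
  lab <- labels[tab$genome_id]
  named <- is_named_species(lab)
  split(tab$cluster_id[named], lab[named])
}

#' Categorize named species by their distribution across clusters
#'
#' Every named species receives exactly one of four categories based on
#' how its genomes distribute over clusters and singletons:
#' \describe{
#'   \item{single_homogeneous}{present as one singleton or in one cluster
#'     whose genomes all carry the same species name;}
#'   \item{multiple_homogeneous}{present in two or more occupied units
#'     (clusters and/or singletons), all of them "clean";}
#'   \item{single_heterogeneous}{one occupied unit, and at least one
#'     occupied non-singleton cluster also contains a genome of a
#'     different named species;}
#'   \item{multiple_heterogeneous}{two or more occupied units and at
#'     least one shared with a different named species.}
#' }
#' A singleton counts as an occupied unit; unlabeled genomes occupy
#' clusters but never make them heterogeneous.
#'
#' @param clusters Cluster list from [consolidate_cliques()].
#' @param labels Named character vector: genome id -> species label.
#' @return Data.frame with columns `species`, `category`, `n_units`,
#'   `clusters_occupied` and `co_occurring` (both `;`-joined;
#'   `co_occurring` is empty iff the category is homogeneous).
#' @export
categorize_species <- function(clusters, labels) {
  tab <- clusters_table(clusters)
  labeled <- names(labels)[is_named_species(labels)]
  absent <- setdiff(labeled, tab$genome_id)
  if (length(absent)) {
    stop("labeled genome(s) absent from clusters: ",
         paste(head(absent, 5L), collapse = ", "))
  }
  units <- occupied_units(clusters, labels)
  kind_of <- stats::setNames(
    vapply(clusters, `[[`, character(1L), "kind"),
    vapply(clusters, `[[`, character(1L), "cluster_id"))
  members_of <- stats::setNames(lapply(clusters, `[[`, "members"),
                                names(kind_of))
  rows <- lapply(sort(names(units)), function(sp) {
    occ <- sort(unique(units[[sp]]))
    co <- character()
    for (cid in occ) {
      if (kind_of[[cid]] == "singleton") next
      lab <- labels[members_of[[cid]]]
      other <- lab[is_named_species(lab) & lab != sp]
      co <- c(co, other)
    }
    co <- sort(unique(co))
    multiple <- length(occ) >= 2L
    heterogeneous <- length(co) > 0L
    category <- paste0(if (multiple) "multiple" else "single", "_",
                       if (heterogeneous) "heterogeneous" else "homogeneous")
    data.frame(species = sp, category = category, n_units = length(occ),
               clusters_occupied = paste(occ, collapse = ";"),
               co_occurring = paste(co, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Propose species assignments for unclassified genomes
#'
#' For each unlabeled genome placed in a cluster whose labeled members all
#' carry one species name, proposes that species.  Clusters containing two
#' or more named species, or no named member at all, yield no proposal.
#' Proposals are advisory output and never mutate the input labels.
#'
#' @inheritParams categorize_species
#' @return Data.frame with columns `genome_id`, `proposed_species`,
#'   `cluster_id`, `n_labeled_support` (number of labeled members backing
#'   the proposal).
#' @export
propose_assignments <- function(clusters, labels) {
  rows <- list()
  for (cl in clusters) {
    lab <- labels[cl$members]
    named <- is_named_species(lab)
    unl <- cl$members[!named]
    sp <- unique(lab[named])
    if (length(unl) && length(sp) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = sort(unl), proposed_species = sp,
        cluster_id = cl$cluster_id, n_labeled_support = sum(named),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(genome_id = character(), proposed_species = character(),
                      cluster_id = character(), n_labeled_support = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clusters that are candidate novel species
#'
#' Non-singleton clusters populated entirely by genomes without any
#' species designation represent putative novel species awaiting
#' taxonomic description.
#'
#' @inheritParams categorize_species
#' @param include_singletons Also report unlabeled singletons (default
#'   `FALSE`: a lone unclassified genome is weak evidence for novelty).
#' @return Data.frame with columns `cluster_id`, `kind`, `n_genomes`.
#' @export
novel_species_candidates <- function(clusters, labels,
                                     include_singletons = FALSE) {
  rows <- list()
  for (cl in clusters) {
    if (cl$kind == "singleton" && !include_singletons) next
    lab <- labels[cl$members]
    if (any(is_named_species(lab))) next
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl$cluster_id, kind = cl$kind,
      n_genomes = length(cl$members), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), kind = character(),
                      n_genomes = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect clusters holding type strains of multiple species
#'
#' The type strain of a species should not be highly similar to the type
#' strain of another species, so a cluster containing type strains of two
#' or more distinct named species signals a naming conflict.
#'
#' @inheritParams categorize_species
#' @param type_flags Named logical vector: genome id -> is the genome a
#'   type strain.
#' @return Data.frame with columns `cluster_id`, `n_species`, `species`
#'   (`;`-joined names of the conflicting type-strain species); one row
#'   per conflicted cluster.
#' @export
type_strain_conflicts <- function(clusters, labels, type_flags) {
  rows <- list()
  for (cl in clusters) {
    ts <- cl$members[type_flags[cl$members] %in% TRUE]
    sp <- unique(labels[ts][is_named_species(labels[ts])])
    if (length(sp) >= 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, n_species = length(sp),
        species = paste(sort(sp), collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), n_species = integer(),
                      species = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
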