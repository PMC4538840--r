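#' Build the species graph from pair results
#'
#' Nodes are genomes; an undirected edge joins two genomes when their
#' minimum pairwise AF is at least `af_min` AND their minimum pairwise
#' gANI is at least `gani_min` (both thresholds inclusive; an undefined
#' gANI fails).  Genomes mentioned in `results` (or listed in `genome_ids`)
#' but with no qualifying edge become isolated nodes, so clustering output
#' always covers the full collection.
#'
#' @param results Pair-results data.frame (one row per unordered pair;
#'   duplicate rows with conflicting values are an error).
#' @param af_min,gani_min Edge thresholds (defaults 0.6 / 96.5).
#' @param genome_ids Optional character vector of additional genome ids to
#'   include as (possibly isolated) nodes.
#' @return An object of class `species_graph`: list with `nodes` (sorted
#'   ids), `edges` (2-column character matrix, `u < v`), `adj` (named
#'   adjacency list) and `thresholds`.
#' @export
build_graph <- function(results, af_min = 0.6, gani_min = 96.5,
                        genome_ids = NULL) {
  validate_pair_results(results)
  if (any(results$genome_a == results$genome_b)) {
    stop("self-pairs are not allowed in the species graph")
  }
  # canonical orientation: genome_a < genome_b
  flip <- results$genome_a > results$genome_b
  if (any(flip)) {
    tmp <- results[flip, ]
    results[flip, c("genome_a", "genome_b")] <- tmp[, c("genome_b", "genome_a")]
    results[flip, c("af_ab", "af_ba")] <- tmp[, c("af_ba", "af_ab")]
    results[flip, c("gani_ab", "gani_ba")] <- tmp[, c("gani_ba", "gani_ab")]
  }
  key <- paste(results$genome_a, results$genome_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    for (dk in dup_keys) {
      sub <- results[key == dk, c("af_ab", "af_ba", "gani_ab", "gani_ba",
                                  "n_bbh")]
      if (nrow(unique(sub)) > 1L) {
        stop("conflicting duplicate rows for pair ",
             gsub("\r", " / ", dk, fixed = TRUE))
      }
    }
    results <- results[!duplicated(key), ]
  }
  nodes <- sort(unique(c(results$genome_a, results$genome_b, genome_ids)))
  min_af <- pmin(results$af_ab, results$af_ba)
  min_gani <- pmin(results$gani_ab, results$gani_ba)  # NA if either NA
  has_edge <- min_af >= af_min & !is.na(min_gani) & min_gani >= gani_min
  edges <- as.matrix(results[has_edge, c("genome_a", "genome_b")])
  dimnames(edges) <- NULL
  if (!nrow(edges)) edges <- matrix(character(), ncol = 2L)
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj <- lapply(adj, sort)
  structure(list(nodes = nodes, edges = edges, adj = adj,
                 thresholds = c(af_min = af_min, gani_min = gani_min)),
            class = "species_graph")
}

#' @export
print.species_graph <- function(x, ...) {
  cat(sprintf("<species_graph> %d genomes, %d edges (AF >= %g, gANI >= %g)\n",
              length(x$nodes), nrow(x$edges), x$thresholds["af_min"],
              x$thresholds["gani_min"]))
  invisible(x)
}

#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Lists every subset of genomes that is completely connected and cannot
#' be extended by any further genome.  Isolated nodes are returned as
#' size-1 cliques (classed as singletons by [consolidate_cliques()]).
#' The pivot is the vertex of P union X with the most neighbours in P
#' (ties: lexicographically smallest), and output is sorted by size
#' (descending) then lexicographic member order, so results are fully
#' deterministic.
#'
#' @param graph A `species_graph` from [build_graph()].
#' @return List of character vectors (sorted genome ids), one per maximal
#'   clique; every edge of the graph is covered by at least one clique.
#' @export
enumerate_maximal_cliques <- function(graph) {
  stopifnot(inherits(graph, "species_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(list())
  adj <- lapply(graph$adj[nodes], function(nb) match(nb, nodes))
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    pool <- c(P, X)
    cnt <- vapply(pool, function(u) sum(P %in% adj[[u]]), integer(1L))
    pivot <- pool[order(-cnt, pool)][1L]
    for (v in sort(setdiff(P, adj[[pivot]]))) {
      bk(sort(c(R, v)), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }
  bk(integer(), seq_len(n), integer())
  cliques <- lapply(out, function(ix) nodes[sort(ix)])
  keys <- vapply(cliques, paste, character(1L), collapse = "\r")
  cliques[order(-lengths(cliques), keys)]
}

#' Consolidate maximal cliques into clusters
#'
#' Builds the clique-overlap meta-graph (cliques as nodes, an edge when two
#' cliques share at least one genome) and turns each connected component
#' into one cluster: components of two or more cliques become a
#' `clique_group` (members = union of the constituent cliques), lone
#' cliques of two or more genomes stay `clique`, and size-1 cliques become
#' `singleton`.  Clusters partition the genome set.  Cluster ids are
#' assigned after sorting clusters by size (descending) then by first
#' member.
#'
#' @param cliques List of maximal cliques from
#'   [enumerate_maximal_cliques()].
#' @return List of clusters; each is a list with `cluster_id`, `kind`
#'   (`"clique"`, `"clique_group"` or `"singleton"`), `members` (sorted
#'   genome ids) and `member_cliques` (non-empty only for clique-groups).
#' @export
consolidate_cliques <- function(cliques) {
  k <- length(cliques)
  if (!k) return(list())
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  by_genome <- split(rep(seq_len(k), lengths(cliques)), unlist(cliques))
  for (ix in by_genome) {
    if (length(ix) > 1L) {
      r <- find(ix[1L])
      for (j in ix[-1L]) parent[find(j)] <- r
    }
  }
  comp <- split(seq_len(k), vapply(seq_len(k), find, integer(1L)))
  clusters <- lapply(comp, function(ix) {
    members <- sort(unique(unlist(cliques[ix])))
    if (length(ix) >= 2L) {
      list(kind = "clique_group", members = members,
           member_cliques = cliques[ix])
    } else if (length(members) >= 2L) {
      list(kind = "clique", members = members, member_cliques = list())
    } else {
      list(kind = "singleton", members = members, member_cliques = list())
    }
  })
  first <- vapply(clusters, function(cl) cl$members[1L], character(1L))
  clusters <- clusters[order(-vapply(clusters, function(cl)
    length(cl$members), integer(1L)), first)]
  for (i in seq_along(clusters)) {
    clusters[[i]] <- c(list(cluster_id = sprintf("C%04d", i)), clusters[[i]])
  }
  unname(clusters)
}

#' Cluster a genome collection at species-level thresholds
#'
#' Convenience wrapper: [build_graph()] + [enumerate_maximal_cliques()] +
#' [consolidate_cliques()].
#'
#' @inheritParams build_graph
#' @return List with `clusters` (see [consolidate_cliques()]), `cliques`,
#'   `graph`, and `table` (long data.frame with `cluster_id`, `kind`,
#'   `genome_id`).
#' @export
cluster_genomes <- function(results, af_min = 0.6, gani_min = 96.5,
                            genome_ids = NULL) {
  graph <- build_graph(results, af_min = af_min, gani_min = gani_min,
                       genome_ids = genome_ids)
  cliques <- enumerate_maximal_cliques(graph)
  clusters <- consolidate_cliques(cliques)
  list(clusters = clusters, cliques = cliques, graph = graph,
       table = clusters_table(clusters))
}

#' Long-format cluster membership table
#'
#' @param clusters Cluster list from [consolidate_cliques()].
#' @return Data.frame with columns `cluster_id`, `kind`, `genome_id`.
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster_id = character(), kind = character(),
                      genome_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, kind = cl$kind,
               genome_id = cl$members, stringsAsFactors = FALSE)
  }))
}

#' Average intra- and inter-cluster gANI and AF
#'
#' For every cluster (intra) and every pair of clusters (inter), averages
#' the directional means `(gani_ab + gani_ba) / 2` and
#' `(af_ab + af_ba) / 2` over the genome pairs found in `results`.  Pairs
#' absent from `results` are skipped and counted in `n_missing`; pairs
#' whose gANI is undefined contribute to the AF mean only and are counted
#' in `n_gani_undefined`.
#'
#' @param clusters Cluster list from [consolidate_cliques()].
#' @param results Pair-results data.frame.
#' @return Data.frame with columns `cluster_a`, `cluster_b`, `type`
#'   (`"intra"` or `"inter"`), `n_pairs`, `n_missing`,
#'   `n_gani_undefined`, `mean_af`, `mean_gani`.
#' @export
cluster_ani_summary <- function(clusters, results) {
  validate_pair_results(results)
  key <- ifelse(results$genome_a < results$genome_b,
                paste(results$genome_a, results$genome_b, sep = "\r"),
                paste(results$genome_b, results$genome_a, sep = "\r"))
  mean_gani_tbl <- stats::setNames((results$gani_ab + results$gani_ba) / 2, key)
  mean_af_tbl <- stats::setNames((results$af_ab + results$af_ba) / 2, key)

  summarize <- function(pairs_a, pairs_b) {
    k <- ifelse(pairs_a < pairs_b, paste(pairs_a, pairs_b, sep = "\r"),
                paste(pairs_b, pairs_a, sep = "\r"))
    found <- k %in% names(mean_af_tbl)
    g <- mean_gani_tbl[k[found]]
    a <- mean_af_tbl[k[found]]
    list(n_pairs = sum(found), n_missing = sum(!found),
         n_gani_undefined = sum(is.na(g)),
         mean_af = if (sum(found)) mean(a) else NA_real_,
         mean_gani = if (any(!is.na(g))) mean(g, na.rm = TRUE) else NA_real_)
  }

  rows <- list()
  nc <- length(clusters)
  for (i in seq_len(nc)) {
    mem <- clusters[[i]]$members
    if (length(mem) >= 2L) {
      prs <- utils::combn(mem, 2L)
      s <- summarize(prs[1L, ], prs[2L, ])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_a = clusters[[i]]$cluster_id,
        cluster_b = clusters[[i]]$cluster_id, type = "intra",
        n_pairs = s$n_pairs, n_missing = s$n_missing,
        n_gani_undefined = s$n_gani_undefined, mean_af = s$mean_af,
        mean_gani = s$mean_gani, stringsAsFactors = FALSE)
    }
  }
  if (nc >= 2L) {
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        grid <- expand.grid(a = clusters[[i]]$members,
                            b = clusters[[j]]$members,
                            stringsAsFactors = FALSE)
        s <- summarize(grid$a, grid$b)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_a = clusters[[i]]$cluster_id,
          cluster_b = clusters[[j]]$cluster_id, type = "inter",
          n_pairs = s$n_pairs, n_missing = s$n_missing,
          n_gani_undefined = s$n_gani_undefined, mean_af = s$mean_af,
          mean_gani = s$mean_gani, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_a = character(), cluster_b = character(),
                      type = character(), n_pairs = integer(),
                      n_missing = integer(), n_gani_undefined = integer(),
                      mean_af = numeric(), mean_gani = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cluster membership table
#'
#' Long TSV with columns `cluster_id`, `kind`, `genome_id`.  Reading
#' rebuilds the cluster list (constituent-clique detail of clique-groups
#' is not stored in this format and comes back empty).
#'
#' @param clusters Cluster list from [consolidate_cliques()].
#' @param path File path.
#' @return `write_clusters()` returns `path` invisibly; `read_clusters()`
#'   returns a cluster list.
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters_table(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("cluster_id", "kind", "genome_id")
  if (!all(need %in% names(tab))) {
    stop("cluster table lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (anyDuplicated(tab$genome_id)) {
    stop("cluster table assigns a genome to more than one cluster")
  }
  ids <- unique(tab$cluster_id)
  lapply(ids, function(cid) {
    sub <- tab[tab$cluster_id == cid, ]
    kind <- unique(sub$kind)
    if (length(kind) != 1L) stop("cluster ", cid, " has inconsistent kind")
    list(cluster_id = cid, kind = kind, members = sort(sub$genome_id),
         member_cliques = list())
  })
}
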