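test_that("species-graph edges require both minimum-pairwise thresholds", {
  res <- pair_rows(
    pair_row("a", "b", af_ab = 0.7, af_ba = 0.5, gani_ab = 99, gani_ba = 99),
    pair_row("a", "c", af_ab = 0.6, af_ba = 0.6, gani_ab = 96.5,
             gani_ba = 96.5),
    pair_row("b", "c", af_ab = 0.9, af_ba = 0.9, gani_ab = NA, gani_ba = NA,
             n_bbh = 0L) |> transform(af_ab = 0, af_ba = 0))
  g <- build_graph(res)
  # min AF 0.5 < 0.6: no a-b edge; exact 0.6 / 96.5: inclusive; NA gANI fails
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges[1, ], c("a", "c"))
  expect_identical(g$nodes, c("a", "b", "c"))
})

test_that("graph construction rejects conflicting duplicate pairs", {
  res <- pair_rows(pair_row("a", "b", af_ab = 0.9, gani_ab = 99),
                   pair_row("b", "a", af_ab = 0.8, gani_ab = 99))
  expect_error(build_graph(res), "conflicting")
  # an exact duplicate (opposite orientation) is tolerated
  res2 <- pair_rows(pair_row("a", "b", af_ab = 0.9, af_ba = 0.8,
                             gani_ab = 99, gani_ba = 98),
                    pair_row("b", "a", af_ab = 0.8, af_ba = 0.9,
                             gani_ab = 98, gani_ba = 99))
  expect_silent(build_graph(res2))
  expect_error(build_graph(pair_row("a", "a")), "self")
})

test_that("maximal cliques match textbook cases", {
  tri <- pair_rows(pair_row("a", "b"), pair_row("a", "c"), pair_row("b", "c"))
  g <- build_graph(tri)
  expect_identical(enumerate_maximal_cliques(g), list(c("a", "b", "c")))

  path <- pair_rows(pair_row("a", "b"), pair_row("b", "c", gani_ab = 99))
  gp <- build_graph(path)
  expect_identical(enumerate_maximal_cliques(gp),
                   list(c("a", "b"), c("b", "c")))

  # isolated node comes back as a size-1 clique
  iso <- pair_rows(pair_row("a", "b"), pair_row("a", "z", af_ab = 0.1,
                                                gani_ab = 80, gani_ba = 80))
  gi <- build_graph(iso)
  expect_true(any(vapply(enumerate_maximal_cliques(gi), identical,
                         logical(1), y = "z")))
})

test_that("clique enumeration equals brute force on random graphs", {
  set.seed(30)
  for (k in 1:50) {
    n <- 12
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- runif(1) < 0.4
    }
    ids <- sprintf("n%02d", 1:n)
    rows <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      rows[[length(rows) + 1L]] <- pair_row(
        ids[i], ids[j], af_ab = if (adj[i, j]) 0.9 else 0.2,
        gani_ab = if (adj[i, j]) 99 else 90)
    }
    g <- build_graph(do.call(rbind, rows))
    mine <- enumerate_maximal_cliques(g)
    orc <- lapply(oracle_cliques(adj), function(ix) ids[ix])
    expect_identical(clique_set(mine), clique_set(orc))
  }
})

test_that("clique enumeration matches on adversarial structures", {
  ids <- sprintf("n%02d", 1:8)
  complete <- do.call(rbind, apply(utils::combn(ids, 2), 2,
                                   function(p) pair_row(p[1], p[2]),
                                   simplify = FALSE))
  expect_identical(enumerate_maximal_cliques(build_graph(complete)),
                   list(ids))
  star <- do.call(rbind, lapply(ids[-1], function(v) pair_row(ids[1], v)))
  expect_identical(
    clique_set(enumerate_maximal_cliques(build_graph(star))),
    clique_set(lapply(ids[-1], function(v) c(ids[1], v))))
  # cross-check a G(10, 0.5) graph against an independent library
  set.seed(31)
  n <- 10
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <- runif(1) < 0.5
  }
  rows <- list()
  idn <- sprintf("m%02d", 1:n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rows[[length(rows) + 1L]] <- pair_row(
      idn[i], idn[j], af_ab = if (adj[i, j]) 0.9 else 0.2,
      gani_ab = if (adj[i, j]) 99 else 90)
  }
  mine <- enumerate_maximal_cliques(build_graph(do.call(rbind, rows)))
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ig_cl <- lapply(igraph::max_cliques(ig), function(v) idn[as.integer(v)])
  expect_identical(clique_set(mine), clique_set(ig_cl))
})

test_that("overlapping cliques consolidate into clique-groups", {
  cl <- consolidate_cliques(list(c("a", "b", "c"), c("c", "d", "e")))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$kind, "clique_group")
  expect_identical(cl[[1]]$members, c("a", "b", "c", "d", "e"))
  expect_length(cl[[1]]$member_cliques, 2L)

  cl2 <- consolidate_cliques(list(c("a", "b"), c("c", "d")))
  expect_identical(vapply(cl2, `[[`, character(1), "kind"),
                   c("clique", "clique"))

  cl3 <- consolidate_cliques(list(c("a", "b"), "z"))
  expect_identical(vapply(cl3, `[[`, character(1), "kind"),
                   c("clique", "singleton"))

  # transitive overlap merges into a single group
  cl4 <- consolidate_cliques(list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_length(cl4, 1L)
  expect_identical(cl4[[1]]$members, c("a", "b", "c", "d"))
})

test_that("a dense subgraph with missing links forms one clique-group", {
  # genome-reduction pattern: two 'reduced' genomes each linked to four
  # 'full' genomes but not to each other
  full <- sprintf("full%d", 1:4)
  red <- c("red1", "red2")
  rows <- list()
  for (p in utils::combn(full, 2, simplify = FALSE)) {
    rows[[length(rows) + 1L]] <- pair_row(p[1], p[2])
  }
  for (f in full) for (r in red) {
    rows[[length(rows) + 1L]] <- pair_row(f, r, af_ab = 0.65, af_ba = 1,
                                          gani_ab = 99.6, gani_ba = 99.6)
  }
  rows[[length(rows) + 1L]] <- pair_row("red1", "red2", af_ab = 0.46,
                                        af_ba = 0.46, gani_ab = 99.6,
                                        gani_ba = 99.6)
  out <- cluster_genomes(do.call(rbind, rows))
  expect_length(out$clusters, 1L)
  expect_identical(out$clusters[[1]]$kind, "clique_group")
  expect_identical(out$clusters[[1]]$members, sort(c(full, red)))
  expect_identical(clique_set(out$cliques),
                   clique_set(list(c(full, "red1"), c(full, "red2"))))
})

test_that("clusters partition the genome set, covering isolated genomes", {
  res <- pair_rows(pair_row("a", "b"),
                   pair_row("a", "x", af_ab = 0.2, gani_ab = 85),
                   pair_row("c", "d"), pair_row("c", "e"),
                   pair_row("d", "e"))
  out <- cluster_genomes(res, genome_ids = c("lonely"))
  tab <- out$table
  expect_identical(sort(tab$genome_id),
                   c("a", "b", "c", "d", "e", "lonely", "x"))
  expect_false(any(duplicated(tab$genome_id)))
  expect_identical(tab$kind[tab$genome_id == "lonely"], "singleton")
})

test_that("raising thresholds only refines the clustering", {
  set.seed(32)
  for (k in 1:10) {
    ids <- sprintf("g%02d", 1:8)
    rows <- list()
    for (p in utils::combn(ids, 2, simplify = FALSE)) {
      rows[[length(rows) + 1L]] <- pair_row(
        p[1], p[2], af_ab = runif(1, 0.3, 1), af_ba = runif(1, 0.3, 1),
        gani_ab = runif(1, 93, 100), gani_ba = runif(1, 93, 100))
    }
    res <- do.call(rbind, rows)
    loose <- cluster_genomes(res, af_min = 0.5, gani_min = 95)
    strict <- cluster_genomes(res, af_min = 0.7, gani_min = 97)
    expect_lte(nrow(strict$graph$edges), nrow(loose$graph$edges))
    # every strict clique is contained in some loose cluster
    loose_members <- lapply(loose$clusters, `[[`, "members")
    for (cl in strict$cliques) {
      expect_true(any(vapply(loose_members, function(m) all(cl %in% m),
                             logical(1))))
    }
  }
})

test_that("cluster gANI/AF summaries average the directional means", {
  clusters <- fake_clusters(c("a", "b"), "x", "y")
  res <- pair_rows(
    pair_row("a", "b", af_ab = 0.9, af_ba = 0.8, gani_ab = 98, gani_ba = 98),
    pair_row("x", "y", af_ab = 0.5, af_ba = 0.5, gani_ab = 91, gani_ba = 93))
  s <- cluster_ani_summary(clusters, res)
  intra <- s[s$type == "intra", ]
  expect_identical(nrow(intra), 1L)
  expect_equal(intra$mean_gani, 98)
  expect_equal(intra$mean_af, 0.85)
  xy <- s[s$type == "inter" & s$n_pairs > 0, ]
  expect_equal(xy$mean_gani, 92)
  # pairs absent from the table are counted, not silently dropped
  expect_identical(sum(s$n_missing), 4L)
})

test_that("cluster summaries equal an independent recomputation", {
  set.seed(33)
  coll <- plant_collection("bacillus_like", seed = 34, n_genes = 12,
                           mean_len = 300)
  res <- all_vs_all(coll$genomes)
  out <- cluster_genomes(res)
  s <- cluster_ani_summary(out$clusters, res)
  # flat recomputation with loops over the membership table
  tab <- out$table
  for (r in seq_len(nrow(s))) {
    ga <- tab$genome_id[tab$cluster_id == s$cluster_a[r]]
    gb <- tab$genome_id[tab$cluster_id == s$cluster_b[r]]
    vals_g <- c()
    vals_a <- c()
    for (u in ga) for (v in gb) {
      if (s$type[r] == "intra" && u >= v) next
      row <- res[(res$genome_a == u & res$genome_b == v) |
                   (res$genome_a == v & res$genome_b == u), ]
      if (!nrow(row)) next
      vals_g <- c(vals_g, (row$gani_ab + row$gani_ba) / 2)
      vals_a <- c(vals_a, (row$af_ab + row$af_ba) / 2)
    }
    expect_equal(s$mean_gani[r], mean(vals_g, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(s$mean_af[r], mean(vals_a), tolerance = 1e-12)
  }
})
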