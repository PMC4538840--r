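# Independent reference implementations used only to check the package:
# a plain-R affine-gap local aligner (loops, tiny inputs), a vectorized
# gapless diagonal local aligner (for substitution-only pairs), and a
# brute-force maximal-clique enumerator over all vertex subsets.
# These mirror the package's documented tie-break conventions but share
# no code with it.

# full affine-gap Smith-Waterman in plain R; gap of length L costs
# gap_open + L * gap_extend; use only on short sequences
oracle_sw <- function(q, s, match = 1, mismatch = -1, gap_open = -5,
                      gap_extend = -2) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa)
  m <- length(sa)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  acgt <- c("A", "C", "G", "T")
  best <- 0
  bi <- bj <- -1
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(E[i + 1, j] + gap_extend,
                             H[i + 1, j] + gap_open + gap_extend)
      F[i + 1, j + 1] <- max(F[i, j + 1] + gap_extend,
                             H[i, j + 1] + gap_open + gap_extend)
      eq <- qa[i] %in% acgt && qa[i] == sa[j]
      h <- max(0, H[i, j] + if (eq) match else mismatch,
               E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) {
        best <- h
        bi <- i
        bj <- j
      }
    }
  }
  if (best <= 0) return(list(found = FALSE))
  i <- bi
  j <- bj
  state <- "H"
  matches <- 0
  cols <- 0
  repeat {
    if (state == "H") {
      if (H[i + 1, j + 1] == 0) break
      eq <- qa[i] %in% acgt && qa[i] == sa[j]
      sub <- if (eq) match else mismatch
      if (H[i + 1, j + 1] == H[i, j] + sub) {
        cols <- cols + 1
        if (eq) matches <- matches + 1
        i <- i - 1
        j <- j - 1
      } else if (H[i + 1, j + 1] == F[i + 1, j + 1]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") {
      cols <- cols + 1
      if (F[i + 1, j + 1] == H[i, j + 1] + gap_open + gap_extend) {
        i <- i - 1
        state <- "H"
      } else {
        i <- i - 1
      }
    } else {
      cols <- cols + 1
      if (E[i + 1, j + 1] == H[i + 1, j] + gap_open + gap_extend) {
        j <- j - 1
        state <- "H"
      } else {
        j <- j - 1
      }
    }
  }
  list(found = TRUE, score = best, matches = matches, cols = cols,
       identity = 100 * matches / cols)
}

# gapless local aligner (vectorized rows); exact for substitution-only
# pairs where the optimal local alignment carries no gaps
oracle_diag <- function(q, s, match = 1, mismatch = -1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa)
  m <- length(sa)
  acgt <- c("A", "C", "G", "T")
  H <- matrix(0, n + 1, m + 1)
  for (i in 1:n) {
    sub <- ifelse(qa[i] == sa & qa[i] %in% acgt, match, mismatch)
    H[i + 1, 2:(m + 1)] <- pmax(0, H[i, 1:m] + sub)
  }
  best <- max(H)
  if (best <= 0) return(list(found = FALSE))
  cand <- which(H == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  i <- cand[1L, 1L] - 1L
  j <- cand[1L, 2L] - 1L
  matches <- 0
  cols <- 0
  while (i >= 1 && j >= 1 && H[i + 1, j + 1] > 0) {
    cols <- cols + 1
    if (qa[i] == sa[j] && qa[i] %in% acgt) matches <- matches + 1
    i <- i - 1
    j <- j - 1
  }
  list(found = TRUE, score = best, matches = matches, cols = cols,
       identity = 100 * matches / cols)
}

# Biostrings local alignment score under the same scoring scheme;
# score only (traceback tie conventions differ between implementations)
oracle_biostrings_score <- function(q, s, match = 1, mismatch = -1,
                                    gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      scoreOnly = TRUE)
  as.numeric(pa)
}

# all maximal cliques of an undirected graph by enumeration of all vertex
# subsets (n <= 15); adj is a symmetric logical matrix without self-loops
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  bit <- 2^(0:(n - 1))
  nb <- vapply(seq_len(n), function(i) sum(bit[adj[i, ]]), numeric(1))
  res <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, bit) > 0)
    is_clique <- all(vapply(members, function(i) {
      bitwAnd(mask, bitwOr(nb[i], bit[i])) == mask
    }, logical(1)))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), members)
    extendable <- any(vapply(outside, function(v) {
      bitwAnd(mask, nb[v]) == mask
    }, logical(1)))
    if (!extendable) res[[length(res) + 1L]] <- members
  }
  res
}

# canonical form of a clique list for set comparison
clique_set <- function(cliques) {
  sort(vapply(cliques, function(cl) paste(sort(cl), collapse = "|"),
              character(1)))
}
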