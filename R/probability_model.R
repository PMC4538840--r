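# Empirical intra-species probability model over binned (AF, gANI):
#   P[AF = a, ANI = b] = P[AF = a] * P[ANI = b | AF = a]
# estimated by histograms over intra-species genome pairs.

#' Label genome pairs by species identity
#'
#' Adds a `same_species` column to a pair-results table: `TRUE` when both
#' genomes carry the same named species label, `FALSE` when both are named
#' but differ, `NA` when either genome is unlabeled (such pairs are
#' excluded from model fitting).
#'
#' @param results Pair-results data.frame.
#' @param labels Named character vector: genome id -> species label.
#' @return `results` with a logical `same_species` column appended.
#' @export
label_pairs <- function(results, labels) {
  validate_pair_results(results)
  la <- labels[results$genome_a]
  lb <- labels[results$genome_b]
  ok <- is_named_species(la) & is_named_species(lb)
  ok[is.na(ok)] <- FALSE
  results$same_species <- ifelse(ok, la == lb, NA)
  results
}

# left-closed right-open bins, last bin closed; a small epsilon guards
# against values like 0.95 / 0.01 landing one bin low in double arithmetic
bin_index <- function(x, lo, width, nbins) {
  i <- floor((x - lo) / width + 1e-9) + 1L
  pmin(pmax(i, 1L), nbins)
}

#' Fit the empirical intra-species probability table
#'
#' Estimates `P[AF = a]` and `P[ANI = b | AF = a]` by binned histograms
#' over intra-species pairs (`same_species == TRUE`) with defined gANI.
#' Each pair is first symmetrized across its two directions (by minimum by
#' default, consistent with the minimum-pairwise edge rule; optionally by
#' mean).  AF bins span `[0, 1]`, gANI bins span `[70, 100]` (the 70%
#' identity filter bounds defined gANI from below in
#' `alignment_lengths` mode); symmetrized gANI below 70 — possible in
#' `bbh_gene_lengths` mode — is clamped into the first bin, counted and
#' warned about.
#'
#' @param pairs Labeled pair-results data.frame from [label_pairs()] (or
#'   with an equivalent `same_species` column).
#' @param af_bin_width,gani_bin_width Bin widths (defaults 0.01 and 0.1).
#' @param symmetrize `"min"` (default) or `"mean"` across the two
#'   directions of each pair.
#' @return An object of class `gani_probability_table`.
#' @examples
#' prs <- data.frame(genome_a = "a", genome_b = letters[2:5],
#'                   af_ab = c(0.95, 0.95, 0.65, 0.65),
#'                   af_ba = c(0.95, 0.95, 0.65, 0.65),
#'                   gani_ab = c(99, 97, 99, 99), gani_ba = c(99, 97, 99, 99),
#'                   n_bbh = 10L, same_species = TRUE)
#' tab <- fit_probability_table(prs)
#' intra_species_probability(tab, 0.95, 99)  # 0.5 * 0.5 = 0.25
#' @export
fit_probability_table <- function(pairs, af_bin_width = 0.01,
                                  gani_bin_width = 0.1,
                                  symmetrize = c("min", "mean")) {
  symmetrize <- match.arg(symmetrize)
  stopifnot("same_species" %in% names(pairs),
            af_bin_width > 0, af_bin_width <= 1,
            gani_bin_width > 0, gani_bin_width <= 30)
  n_inter <- sum(pairs$same_species %in% FALSE)
  n_unlabeled <- sum(is.na(pairs$same_species))
  intra <- pairs[pairs$same_species %in% TRUE, , drop = FALSE]
  comb <- if (symmetrize == "min") pmin else function(a, b) (a + b) / 2
  af <- comb(intra$af_ab, intra$af_ba)
  gani <- comb(intra$gani_ab, intra$gani_ba)
  defined <- !is.na(gani)
  n_undefined <- sum(!defined)
  af <- af[defined]
  gani <- gani[defined]
  if (!length(af)) stop("no usable intra-species pairs with defined gANI")
  n_af <- as.integer(ceiling(1 / af_bin_width - 1e-9))
  n_gani <- as.integer(ceiling(30 / gani_bin_width - 1e-9))
  af_edges <- c(0, seq_len(n_af)) * af_bin_width
  af_edges[n_af + 1L] <- 1
  gani_edges <- 70 + c(0, seq_len(n_gani)) * gani_bin_width
  gani_edges[n_gani + 1L] <- 100
  n_clamped <- sum(gani < 70)
  if (n_clamped) {
    warning(n_clamped, " pair(s) with symmetrized gANI below 70 clamped ",
            "into the first gANI bin")
  }
  ai <- bin_index(af, 0, af_bin_width, n_af)
  gi <- bin_index(gani, 70, gani_bin_width, n_gani)
  joint <- matrix(0, nrow = n_af, ncol = n_gani)
  for (k in seq_along(ai)) joint[ai[k], gi[k]] <- joint[ai[k], gi[k]] + 1
  af_counts <- rowSums(joint)
  p_af <- af_counts / length(ai)
  p_cond <- joint / ifelse(af_counts > 0, af_counts, 1)
  structure(list(af_edges = af_edges, gani_edges = gani_edges, p_af = p_af,
                 p_cond = p_cond, n_pairs = length(ai),
                 n_inter_excluded = n_inter,
                 n_unlabeled_excluded = n_unlabeled,
                 n_undefined_excluded = n_undefined, n_clamped = n_clamped,
                 af_bin_width = af_bin_width,
                 gani_bin_width = gani_bin_width, symmetrize = symmetrize),
            class = "gani_probability_table")
}

#' @export
print.gani_probability_table <- function(x, ...) {
  cat(sprintf(paste0("<gani_probability_table> %d intra-species pairs, ",
                     "%d x %d bins (AF x gANI), symmetrize = %s\n"),
              x$n_pairs, length(x$p_af), ncol(x$p_cond), x$symmetrize))
  invisible(x)
}

#' Intra-species probability of an (AF, gANI) observation
#'
#' Looks up `P[AF = a] * P[ANI = b | AF = a]` in a fitted table.
#' Vectorized over `af` / `gani`.  Empty bins give 0; an undefined (`NA`)
#' gANI gives 0; AF outside `[0, 1]` is an error; gANI outside the table
#' support is clamped into the boundary bin.
#'
#' @param table A `gani_probability_table` from [fit_probability_table()].
#' @param af,gani Numeric vectors (recycled to a common length).
#' @return Numeric vector of joint probabilities.
#' @export
intra_species_probability <- function(table, af, gani) {
  stopifnot(inherits(table, "gani_probability_table"))
  n <- max(length(af), length(gani))
  af <- rep_len(af, n)
  gani <- rep_len(gani, n)
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    stop("af must lie in [0, 1]")
  }
  ai <- bin_index(af, 0, table$af_bin_width, length(table$p_af))
  gi <- bin_index(ifelse(is.na(gani), 70, gani), 70, table$gani_bin_width,
                  ncol(table$p_cond))
  p <- table$p_af[ai] * table$p_cond[cbind(ai, gi)]
  p[is.na(gani)] <- 0
  p
}

#' Fractions of intra-species pairs passing the species thresholds
#'
#' Summary of how intra-species pairs relate to the species-level
#' thresholds: the fraction with minimum pairwise AF at least `af_min`,
#' the fraction of that AF-passing subset with minimum pairwise gANI at
#' least `gani_min`, and the fraction passing both.  Undefined gANI fails
#' the gANI condition.
#'
#' @param pairs Labeled pair-results data.frame (see [label_pairs()]).
#' @param af_min,gani_min Thresholds (defaults 0.6 / 96.5).
#' @return List with `n_intra`, `n_af_pass`, `frac_af`,
#'   `frac_gani_given_af`, `frac_both`.
#' @export
threshold_summary <- function(pairs, af_min = 0.6, gani_min = 96.5) {
  stopifnot("same_species" %in% names(pairs))
  intra <- pairs[pairs$same_species %in% TRUE, , drop = FALSE]
  if (!nrow(intra)) stop("no intra-species pairs")
  min_af <- pmin(intra$af_ab, intra$af_ba)
  min_gani <- pmin(intra$gani_ab, intra$gani_ba)
  af_pass <- min_af >= af_min
  gani_pass <- !is.na(min_gani) & min_gani >= gani_min
  list(n_intra = nrow(intra), n_af_pass = sum(af_pass),
       frac_af = mean(af_pass),
       frac_gani_given_af = if (any(af_pass)) mean(gani_pass[af_pass])
                            else NA_real_,
       frac_both = mean(af_pass & gani_pass))
}

#' False-positive-rate-calibrated probability cutoff
#'
#' Fits (or reuses) the intra-species probability table, evaluates the
#' joint probability of every inter-species pair, and returns the
#' `1 - fpr` quantile of those probabilities: classifying pairs above the
#' cutoff as intra-species then mislabels a fraction `fpr` of
#' inter-species pairs.
#'
#' @param pairs Labeled pair-results data.frame with both intra- and
#'   inter-species pairs.
#' @param fpr Tolerated inter-species false positive rate (default 0.01).
#' @param table Optional pre-fitted table; fitted from `pairs` when NULL.
#' @param ... Passed to [fit_probability_table()] when fitting.
#' @return List with `cutoff`, `n_inter`, and the `table` used.
#' @export
probability_cutoff <- function(pairs, fpr = 0.01, table = NULL, ...) {
  stopifnot(fpr > 0, fpr < 1)
  if (is.null(table)) table <- fit_probability_table(pairs, ...)
  inter <- pairs[pairs$same_species %in% FALSE, , drop = FALSE]
  if (!nrow(inter)) stop("no inter-species pairs")
  comb <- if (table$symmetrize == "min") pmin else function(a, b) (a + b) / 2
  p <- intra_species_probability(table, comb(inter$af_ab, inter$af_ba),
                                 comb(inter$gani_ab, inter$gani_ba))
  list(cutoff = as.numeric(quantile(p, 1 - fpr, names = FALSE)),
       n_inter = nrow(inter), table = table)
}

#' Write / read a probability table
#'
#' Long-format TSV holding one row per populated (AF, gANI) bin with
#' columns `af_bin_lo`, `af_bin_hi`, `gani_bin_lo`, `gani_bin_hi`,
#' `p_af`, `p_gani_given_af`, `p_joint`; bin widths, the pair count and
#' the symmetrization mode travel in `#key=value` header comments, so a
#' round trip reconstructs the full table (unpopulated bins are zero).
#'
#' @param table A `gani_probability_table`.
#' @param path File path.
#' @return `write_probability_table()` returns `path` invisibly;
#'   `read_probability_table()` returns a `gani_probability_table`.
#' @export
write_probability_table <- function(table, path) {
  stopifnot(inherits(table, "gani_probability_table"))
  pop <- which(table$p_cond > 0, arr.ind = TRUE)
  pop <- pop[order(pop[, 1L], pop[, 2L]), , drop = FALSE]
  hdr <- c(sprintf("#af_bin_width=%.17g", table$af_bin_width),
           sprintf("#gani_bin_width=%.17g", table$gani_bin_width),
           sprintf("#n_pairs=%d", table$n_pairs),
           sprintf("#symmetrize=%s", table$symmetrize))
  df <- data.frame(
    af_bin_lo = table$af_edges[pop[, 1L]],
    af_bin_hi = table$af_edges[pop[, 1L] + 1L],
    gani_bin_lo = table$gani_edges[pop[, 2L]],
    gani_bin_hi = table$gani_edges[pop[, 2L] + 1L],
    p_af = table$p_af[pop[, 1L]],
    p_gani_given_af = table$p_cond[pop],
    p_joint = table$p_af[pop[, 1L]] * table$p_cond[pop])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(sprintf, c(list("%.17g\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g"),
                                df)), con)
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("probability table lacks #", key, " header")
    sub(paste0("^#", key, "="), "", m[1L])
  }
  af_w <- as.numeric(get_meta("af_bin_width"))
  gani_w <- as.numeric(get_meta("gani_bin_width"))
  n_pairs <- as.integer(get_meta("n_pairs"))
  symmetrize <- get_meta("symmetrize")
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t")
  n_af <- as.integer(ceiling(1 / af_w - 1e-9))
  n_gani <- as.integer(ceiling(30 / gani_w - 1e-9))
  af_edges <- c(0, seq_len(n_af)) * af_w
  af_edges[n_af + 1L] <- 1
  gani_edges <- 70 + c(0, seq_len(n_gani)) * gani_w
  gani_edges[n_gani + 1L] <- 100
  ai <- bin_index(df$af_bin_lo, 0, af_w, n_af)
  gi <- bin_index(df$gani_bin_lo, 70, gani_w, n_gani)
  p_af <- numeric(n_af)
  p_af[ai] <- df$p_af
  p_cond <- matrix(0, n_af, n_gani)
  p_cond[cbind(ai, gi)] <- df$p_gani_given_af
  structure(list(af_edges = af_edges, gani_edges = gani_edges, p_af = p_af,
                 p_cond = p_cond, n_pairs = n_pairs, n_inter_excluded = NA,
                 n_unlabeled_excluded = NA, n_undefined_excluded = NA,
                 n_clamped = NA, af_bin_width = af_w,
                 gani_bin_width = gani_w, symmetrize = symmetrize),
            class = "gani_probability_table")
}
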