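worked_example_pairs <- function() {
  data.frame(genome_a = "a", genome_b = sprintf("b%d", 1:4),
             af_ab = c(0.95, 0.95, 0.65, 0.65),
             af_ba = c(0.95, 0.95, 0.65, 0.65),
             gani_ab = c(99, 97, 99, 99), gani_ba = c(99, 97, 99, 99),
             n_bbh = 10L, same_species = TRUE, stringsAsFactors = FALSE)
}

test_that("pair labeling distinguishes intra, inter and unlabeled pairs", {
  res <- pair_rows(pair_row("a", "b"), pair_row("a", "c"),
                   pair_row("a", "u"), pair_row("a", "s"))
  labels <- c(a = "X", b = "X", c = "Y", u = NA, s = "Bacillus sp.")
  lp <- label_pairs(res, labels)
  expect_identical(lp$same_species, c(TRUE, FALSE, NA, NA))
})

test_that("degenerate tables concentrate all probability in one bin", {
  prs <- data.frame(genome_a = "a", genome_b = sprintf("b%d", 1:4),
                    af_ab = 0.95, af_ba = 0.95, gani_ab = 99, gani_ba = 99,
                    n_bbh = 5L, same_species = TRUE)
  tab <- fit_probability_table(prs)
  expect_equal(sum(tab$p_af > 0), 1L)
  expect_equal(max(tab$p_af), 1)
  expect_equal(intra_species_probability(tab, 0.95, 99), 1)
  expect_equal(intra_species_probability(tab, 0.40, 99), 0)   # empty AF bin
  expect_equal(intra_species_probability(tab, 0.95, NA), 0)   # undefined gANI
  expect_error(intra_species_probability(tab, 1.2, 99), "af")
})

test_that("the 4-pair worked example reproduces the hand counts", {
  tab <- fit_probability_table(worked_example_pairs())
  expect_identical(tab$n_pairs, 4L)
  # P[AF bin of 0.95] = 0.5; P[gANI bin of 99 | AF bin of 0.95] = 0.5
  expect_equal(intra_species_probability(tab, 0.95, 99), 0.25)
  expect_equal(intra_species_probability(tab, 0.95, 97), 0.25)
  expect_equal(intra_species_probability(tab, 0.65, 99), 0.5)
  expect_equal(intra_species_probability(tab, 0.65, 97), 0)
})

test_that("inter-species and undefined pairs are excluded and counted", {
  prs <- worked_example_pairs()
  extra <- prs[c(1, 1), ]
  extra$same_species <- c(FALSE, TRUE)
  extra$gani_ab[2] <- NA
  extra$gani_ba[2] <- NA
  tab <- fit_probability_table(rbind(prs, extra))
  expect_identical(tab$n_pairs, 4L)
  expect_identical(tab$n_inter_excluded, 1L)
  expect_identical(tab$n_undefined_excluded, 1L)
  expect_error(fit_probability_table(transform(prs, same_species = FALSE)),
               "no usable intra-species pairs")
})

test_that("fitted tables satisfy the normalization invariants", {
  set.seed(40)
  for (k in 1:5) {
    n <- 60
    prs <- data.frame(genome_a = "a", genome_b = sprintf("b%03d", 1:n),
                      af_ab = runif(n, 0.3, 1), af_ba = runif(n, 0.3, 1),
                      gani_ab = runif(n, 80, 100), gani_ba = runif(n, 80, 100),
                      n_bbh = 5L,
                      same_species = sample(c(TRUE, FALSE), n, TRUE))
    if (!any(prs$same_species)) prs$same_species[1] <- TRUE
    tab <- fit_probability_table(prs)
    expect_equal(sum(tab$p_af), 1, tolerance = 1e-9)
    for (a in which(tab$p_af > 0)) {
      expect_equal(sum(tab$p_cond[a, ]), 1, tolerance = 1e-9)
    }
    expect_true(all(tab$p_af >= 0) && all(tab$p_cond >= 0))
    # joint probability reconstruction sums to one
    expect_equal(sum(tab$p_af * rowSums(tab$p_cond)), 1, tolerance = 1e-9)
    # order invariance
    tab2 <- fit_probability_table(prs[sample(n), ])
    expect_equal(tab2$p_af, tab$p_af)
    expect_equal(tab2$p_cond, tab$p_cond)
  }
})

test_that("symmetrization uses the minimum direction by default", {
  prs <- data.frame(genome_a = "a", genome_b = "b", af_ab = 0.905,
                    af_ba = 0.7, gani_ab = 99.55, gani_ba = 97.15,
                    n_bbh = 5L, same_species = TRUE)
  tab <- fit_probability_table(prs)
  expect_equal(intra_species_probability(tab, 0.7, 97.15), 1)
  expect_equal(intra_species_probability(tab, 0.905, 99.55), 0)
  tabm <- fit_probability_table(prs, symmetrize = "mean")
  expect_equal(intra_species_probability(tabm, 0.8025, 98.35), 1)
})

test_that("single-bin tables return probability one in support", {
  tab <- fit_probability_table(worked_example_pairs(), af_bin_width = 1,
                               gani_bin_width = 30)
  expect_equal(intra_species_probability(tab, 0.1, 71), 1)
  expect_equal(intra_species_probability(tab, 0.999, 99.9), 1)
})

test_that("threshold summary reports the conditional pass fractions", {
  af <- c(rep(0.9, 7), 0.4, rep(0.9, 2))
  gani <- c(rep(99, 7), 99, rep(95, 2))
  prs <- data.frame(genome_a = "a", genome_b = sprintf("b%02d", 1:10),
                    af_ab = af, af_ba = af, gani_ab = gani, gani_ba = gani,
                    n_bbh = 5L, same_species = TRUE)
  s <- threshold_summary(prs)
  expect_equal(s$frac_af, 0.9)
  expect_equal(s$frac_gani_given_af, 7 / 9)
  expect_equal(s$frac_both, 0.7)
  # undefined gANI fails the gANI condition
  prs$gani_ab[1] <- NA
  prs$gani_ba[1] <- NA
  prs$af_ab[1] <- 0.9
  s2 <- threshold_summary(prs)
  expect_equal(s2$frac_gani_given_af, 6 / 9)
})

test_that("threshold fractions track a generator-controlled cohort", {
  set.seed(41)
  n <- 400
  below <- runif(n) < 0.05  # 5% of pairs planted below the gANI threshold
  gani <- ifelse(below, runif(n, 93, 96.4), runif(n, 96.6, 100))
  prs <- data.frame(genome_a = "a", genome_b = sprintf("b%04d", 1:n),
                    af_ab = runif(n, 0.7, 1), af_ba = runif(n, 0.7, 1),
                    gani_ab = gani, gani_ba = gani, n_bbh = 5L,
                    same_species = TRUE)
  s <- threshold_summary(prs)
  expect_equal(s$frac_af, 1)
  # binomial error at n = 400: three sigmas ~ 0.033
  expect_lt(abs(s$frac_gani_given_af - 0.95), 0.04)
})

test_that("probability tables round-trip through their TSV format", {
  tab <- fit_probability_table(worked_example_pairs())
  path <- tempfile(fileext = ".tsv")
  write_probability_table(tab, path)
  back <- read_probability_table(path)
  expect_equal(back$p_af, tab$p_af, tolerance = 1e-12)
  expect_equal(back$p_cond, tab$p_cond, tolerance = 1e-12)
  expect_identical(back$n_pairs, tab$n_pairs)
  expect_identical(back$symmetrize, tab$symmetrize)
  expect_equal(intra_species_probability(back, 0.95, 99), 0.25)
})

test_that("the false-positive-calibrated cutoff isolates inter pairs", {
  set.seed(42)
  n <- 200L
  intra <- data.frame(genome_a = "a", genome_b = sprintf("i%03d", 1:n),
                      af_ab = runif(n, 0.85, 1), af_ba = runif(n, 0.85, 1),
                      gani_ab = runif(n, 98, 100), gani_ba = runif(n, 98, 100),
                      n_bbh = 5L, same_species = TRUE)
  inter <- data.frame(genome_a = "a", genome_b = sprintf("j%03d", 1:n),
                      af_ab = runif(n, 0.2, 0.6), af_ba = runif(n, 0.2, 0.6),
                      gani_ab = runif(n, 75, 90), gani_ba = runif(n, 75, 90),
                      n_bbh = 5L, same_species = FALSE)
  out <- probability_cutoff(rbind(intra, inter))
  # fully separated cohorts: every inter pair scores 0
  expect_equal(out$cutoff, 0)
  expect_identical(out$n_inter, n)
  p_intra <- intra_species_probability(out$table,
                                       pmin(intra$af_ab, intra$af_ba),
                                       pmin(intra$gani_ab, intra$gani_ba))
  expect_true(all(p_intra > out$cutoff))
})
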