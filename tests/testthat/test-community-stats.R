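# Community statistics: composition tallies, alpha diversity, rarefaction,
# Kruskal-Wallis, NB box statistics and top-N matrices.

test_that("alpha diversity matches closed forms", {
  expect_equal(alpha_diversity(c(5)),
               c(observed = 1, shannon = 0, invsimpson = 1))
  for (n in c(2, 5, 17)) {
    a <- alpha_diversity(rep(7, n))
    expect_equal(unname(a["observed"]), n)
    expect_equal(unname(a["shannon"]), log(n))
    expect_equal(unname(a["invsimpson"]), n)
  }
  # random counts vs direct formulas
  set.seed(21)
  x <- rpois(40, 8)
  a <- alpha_diversity(x)
  p <- x[x > 0] / sum(x)
  expect_equal(unname(a["shannon"]), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(unname(a["invsimpson"]), 1 / sum(p^2), tolerance = 1e-12)
  # InvSimpson bounded by Observed; empty sample is missing
  expect_lte(a[["invsimpson"]], a[["observed"]])
  expect_true(all(is.na(alpha_diversity(c(0, 0)))))
  expect_error(alpha_diversity(c(-1, 2)), "non-negative")
})

test_that("rarefaction reproduces trivial depths and the closed form", {
  counts <- c(10L, 5L, 3L, 1L, 1L)
  total <- sum(counts)
  r_full <- rarefaction_curve(counts, total, n_reps = 10, seed = 1)
  expect_equal(r_full$mean_observed, 5)
  expect_equal(r_full$sd_observed, 0)
  r1 <- rarefaction_curve(counts, 1L, n_reps = 50, seed = 1)
  expect_equal(r1$mean_observed, 1)
  expect_error(rarefaction_curve(counts, total + 1), "depth")

  # means within 3 SE of the hypergeometric expectation
  set.seed(33)
  big <- as.integer(rpois(25, 12) + 1)
  for (d in c(20L, 80L, 200L)) {
    r <- rarefaction_curve(big, d, n_reps = 400, seed = 5)
    expected <- oracle_rarefaction_expectation(big, d)
    se <- r$sd_observed / sqrt(400)
    expect_lt(abs(r$mean_observed - expected), max(3 * se, 0.05))
  }
  # monotone non-decreasing in depth (on means, with tolerance)
  rc <- rarefaction_curve(big, c(10L, 50L, 150L, 300L), n_reps = 200,
                          seed = 7)
  expect_true(all(diff(rc$mean_observed) > -0.1))
})

test_that("kruskal_wallis reproduces the hand-computed example and R", {
  kw <- kruskal_wallis(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1L)

  # identical values: H = 0, p = 1
  kw0 <- kruskal_wallis(list(A = c(2, 2), B = c(2, 2, 2)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(list(A = 1:3)), "two groups")

  # random inputs (with ties) vs stats::kruskal.test
  set.seed(44)
  for (case in 1:200) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) {
      sample(1:8, sample(3:10, 1), replace = TRUE)
    })
    got <- kruskal_wallis(groups)
    x <- unlist(groups)
    g <- factor(rep(seq_len(k), lengths(groups)))
    want <- stats::kruskal.test(x, g)
    expect_equal(got$H, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
  }
})

test_that("NB box statistics follow the interpolated-quartile/1.5 IQR rule", {
  calls <- data.table::data.table(
    otu_id = sprintf("O%02d", 1:5),
    best_nb = c(1.0, 1.2, 1.4, 1.6, 1.8),
    label_group = "GenA", has_clone_member = FALSE)
  bs <- genus_nb_boxstats(calls)
  expect_equal(bs$median, 1.4)
  # type-7 interpolation on n = 5
  expect_equal(bs$q1, unname(quantile(calls$best_nb, 0.25, type = 7)))
  expect_equal(bs$q3, unname(quantile(calls$best_nb, 0.75, type = 7)))
  expect_equal(bs$whisker_low, 1.0)
  expect_equal(bs$whisker_high, 1.8)
  expect_length(bs$outliers[[1]], 0)

  # a single extreme low value is flagged as the only outlier
  calls2 <- data.table::data.table(
    otu_id = sprintf("O%02d", 1:8),
    best_nb = c(0.2, seq(1.5, 1.81, length.out = 7)),
    label_group = "GenB", has_clone_member = TRUE)
  bs2 <- genus_nb_boxstats(calls2)
  expect_equal(bs2$outliers[[1]], 0.2)
  expect_equal(bs2$whisker_low, 1.5)
  expect_true(bs2$has_mixed)

  # single-OTU set: median only
  one <- genus_nb_boxstats(data.table::data.table(
    otu_id = "O1", best_nb = 1.5, label_group = "GenC",
    has_clone_member = FALSE))
  expect_equal(one$median, 1.5)
  expect_true(is.na(one$q1) && is.na(one$whisker_low))
})

test_that("class composition counts distinct nonzero OTUs per class", {
  counts <- matrix(c(3L, 0L, 2L, 1L, 5L, 4L), nrow = 3,
                   dimnames = list(c("OTU_0001", "OTU_0002", "OTU_0003"),
                                   c("s1", "s2")))
  calls <- data.table::data.table(
    otu_id = rownames(counts),
    class = c("Trebouxiophyceae", "Chlorophyceae", "nonalgal"),
    target = c(TRUE, TRUE, FALSE))
  comp <- class_composition(calls, counts)
  pooled <- comp[sample == "pooled"]
  expect_equal(pooled$Trebouxiophyceae, 1L)
  expect_equal(pooled$Chlorophyceae, 1L)
  expect_equal(pooled$nonalgal_total, 1L)
  expect_equal(pooled$pct_Trebouxiophyceae, 50)
  s1 <- comp[sample == "s1"]
  expect_equal(s1$algal_total, 1L)        # OTU_0002 has zero reads in s1
  expect_equal(s1$pct_Trebouxiophyceae, 100)
  # single-class community -> 100%
  one <- class_composition(calls[1], counts[1, , drop = FALSE])
  expect_equal(one[sample == "pooled"]$pct_Trebouxiophyceae, 100)

  # random table vs a naive tally
  set.seed(55)
  m <- matrix(rpois(60, 2), nrow = 12,
              dimnames = list(sprintf("OTU_%04d", 1:12), paste0("s", 1:5)))
  cls <- sample(c(TARGET_CLASSES, "nonalgal"), 12, replace = TRUE)
  rcalls <- data.table::data.table(otu_id = rownames(m), class = cls,
                                   target = cls != "nonalgal")
  comp2 <- class_composition(rcalls, m)
  for (s in colnames(m)) {
    row <- comp2[sample == s]
    for (cl in TARGET_CLASSES) {
      expect_equal(row[[cl]], sum(m[, s] > 0 & cls == cl))
    }
  }
})

test_that("top_n_matrix selects by total reads with id tie-break", {
  set.seed(66)
  m <- matrix(rpois(40, 5), nrow = 8,
              dimnames = list(sprintf("OTU_%04d", 1:8), paste0("s", 1:5)))
  calls <- data.table::data.table(otu_id = rownames(m),
                                  class = rep(c("Chlorophyceae",
                                                "Ulvophyceae"), each = 4))
  gm <- data.table::data.table(sample = paste0("s", 1:5),
                               group = c(rep("groupA_north", 3),
                                         "groupA_south",
                                         "groupB_reference"))
  # n larger than the class size returns the whole class
  all5 <- top_n_matrix(m, calls, gm, n = 20)
  expect_equal(nrow(all5), 8L)
  # selection equals a sort-and-slice oracle
  top2 <- top_n_matrix(m, calls, gm, n = 2)
  for (cl in unique(calls$class)) {
    ids <- calls$otu_id[calls$class == cl]
    want <- ids[order(-rowSums(m)[ids], ids)][1:2]
    expect_equal(top2[class == cl]$otu_id, want)
  }
  # annotations
  expect_equal(all5$in_all_sites, unname(apply(m > 0, 1, all)))
})
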