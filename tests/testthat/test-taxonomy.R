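# Normalized bit scores, local alignment, consensus assignment, identity
# classes and overlap classification.

test_that("normalize_bitscore is plain division with validation", {
  expect_equal(round(normalize_bitscore(412.5, 228), 2), 1.81)
  expect_equal(normalize_bitscore(0, 100), 0)
  expect_equal(normalize_bitscore(200, 400), 0.5)
  expect_error(normalize_bitscore(100, 0), "positive")
})

test_that("a perfect full-length self-match reaches the NB ceiling", {
  set.seed(2)
  ref <- rand_dna(228)
  h <- align_local(ref, ref)
  # closed form: S = 2 * 228, S' = (0.625 * S - ln 0.41) / ln 2
  expect_equal(h$bitscore, (0.625 * 456 - log(0.41)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(normalize_bitscore(h$bitscore, h$slen), 2), 1.81)
  expect_equal(h$pident, 100)
  expect_equal(h$qcovs, 100)
  expect_equal(h$evalue, 228 * 228 * 2^(-h$bitscore), tolerance = 1e-12)
})

test_that("zero-similarity queries fall below the reporting floor", {
  expect_null(align_local(strrep("A", 60), strrep("C", 60)))
})

test_that("local alignment scores equal the textbook DP oracle", {
  set.seed(31)
  sc <- blast_scoring()
  for (case in 1:60) {
    L1 <- sample(30:120, 1); L2 <- sample(30:120, 1)
    if (case %% 3 == 0) {
      q <- rand_dna(L1); s <- rand_dna(L2)      # unrelated
    } else {
      s <- rand_dna(L2)
      q <- mutate_seq(substr(s, 1, min(L1, L2)), sample(0:8, 1))
    }
    want <- oracle_align_score(q, s, local = TRUE)
    got <- align_local(q, s, max_evalue = Inf)
    if (is.null(got)) {
      expect_lte(want, 0)
    } else {
      raw <- (got$bitscore * log(2) + log(sc$K)) / sc$lambda
      expect_equal(raw, want, tolerance = 1e-9)
    }
  }
})

test_that("clustering identity matches hand-computed cases", {
  a <- "ACGTACGTAC"
  expect_equal(seq_identity(a, a), 1)
  # one substitution in 10
  b <- "ACGTCCGTAC"
  expect_equal(seq_identity(a, b), 0.9)
  # prefix: 8 matched columns + 2 terminal gap columns count in the span
  expect_equal(seq_identity(substr(a, 1, 8), a), 0.8)
  # substitution-only divergence of equal-length random sequences equals
  # 1 - hamming/L whenever the substitution path is optimal
  set.seed(9)
  for (i in 1:20) {
    x <- rand_dna(150); y <- mutate_seq(x, sample(1:6, 1))
    hd <- sum(utf8ToInt(x) != utf8ToInt(y))
    expect_equal(seq_identity(x, y), 1 - hd / 150)
  }
})

make_hits <- function(bitscores, nbs, classes, orders, genera, species,
                      genotypes, titles = NULL) {
  n <- length(bitscores)
  data.table::data.table(
    qseqid = "OTU_X", sseqid = sprintf("S%03d", seq_len(n)),
    bitscore = bitscores, slen = 228, nb = nbs,
    stitle = titles %||% paste(genera, species, genotypes),
    class = classes, order = orders, genus = genera, species = species,
    genotype = genotypes)
}

test_that("consensus assignment reproduces the narrated mislabel case", {
  # 21 hits labeled "uncultured fungus" vs 29 on-target Ulvophyceae hits;
  # the target bit-score sum is larger, the genus with the largest
  # within-class sum has 10 hits, and its best NB is below 1.5:
  # expect a genus-rank "sp." call.
  set.seed(10)
  n_f <- 21; n_t <- 29
  fungi <- make_hits(runif(n_f, 100, 200), runif(n_f, 0.5, 1.0),
                     NA_character_, NA_character_, NA_character_,
                     NA_character_, NA_character_,
                     titles = rep("uncultured fungus", n_f))
  gen <- c(rep("Planophila", 10), sample(c("Ulvo_gen2", "Ulvo_gen3"),
                                         n_t - 10, replace = TRUE))
  bs <- c(runif(10, 280, 330), runif(n_t - 10, 150, 260))
  targ <- make_hits(bs, bs / 228, "Ulvophyceae", "Ulvo_order1", gen,
                    paste0(gen, "_spX"), paste0(gen, "_spX_gtY"))
  hits <- data.table::rbindlist(list(fungi, targ))
  call <- consensus_assign(hits)
  expect_equal(call$label, "Planophila sp.")
  expect_equal(call$assigned_rank, "genus")
  expect_lt(call$best_nb, 1.5)
  expect_equal(call$identity_class, "unidentified")
  expect_true(call$target)
})

test_that("all top hits on one species at NB 1.80 give a species call", {
  bs <- 1.80 * 228
  hits <- make_hits(rep(bs, 10), rep(1.80, 10), "Trebouxiophyceae",
                    "Treb_order1", "Treb_gen1", "Treb_gen1_sp1",
                    paste0("Treb_gen1_sp1_gt", 1:10))
  call <- consensus_assign(hits)
  expect_equal(call$assigned_rank, "species")
  expect_equal(call$label, "Treb_gen1_sp1")
  expect_equal(call$identity_class, "species")
})

test_that("an empty hit list yields a no_hit call", {
  call <- consensus_assign(make_hits(numeric(0), numeric(0), character(0),
                                     character(0), character(0),
                                     character(0), character(0)))
  expect_equal(call$label, "no_hit")
  expect_equal(call$identity_class, "unidentified")
})

test_that("when the non-target sum wins, the OTU is called non-algal", {
  fungi <- make_hits(rep(400, 10), rep(400 / 228, 10), NA_character_,
                     NA_character_, NA_character_, NA_character_,
                     NA_character_, titles = rep("uncultured fungus", 10))
  targ <- make_hits(rep(50, 5), rep(50 / 228, 5), "Ulvophyceae",
                    "Ulvo_order1", "Ulvo_gen1", "Ulvo_gen1_sp1",
                    paste0("Ulvo_gen1_sp1_gt", 1:5))
  call <- consensus_assign(data.table::rbindlist(list(fungi, targ)))
  expect_false(call$target)
  expect_equal(call$class, "nonalgal")
  expect_equal(call$label, "uncultured fungus")
})

test_that("consensus decisions equal brute-force enumeration", {
  set.seed(37)
  for (case in 1:200) {
    hits <- random_hit_table(sample(5:40, 1))
    got <- consensus_assign(data.table::as.data.table(hits))
    want <- oracle_consensus(hits)
    expect_equal(got$label, want$label)
    expect_equal(got$assigned_rank, want$rank)
  }
})

test_that("classify_identity applies the NB thresholds", {
  expect_equal(classify_identity(1.81), "genotype")
  expect_equal(classify_identity(1.806), "genotype")   # within tolerance
  expect_equal(classify_identity(1.80), "species")
  expect_equal(classify_identity(1.76), "species")
  expect_equal(classify_identity(1.75), "species")
  expect_equal(classify_identity(1.73), "unidentified")
  expect_equal(classify_identity(NA_real_), "unidentified")
  # partition: every NB maps to exactly one class
  nbs <- seq(0, 1.9, by = 0.01)
  cls <- classify_identity(nbs)
  expect_true(all(cls %in% c("genotype", "species", "unidentified")))
})

test_that("classify_overlap separates presence classes and breakdowns", {
  sc <- data.table::rbindlist(list(
    data.table::data.table(otu_id = "OTU_0001",
                           sample = c("AS-N1", "AS-S1", "REF-1"),
                           count = c(5L, 2L, 7L)),
    data.table::data.table(otu_id = "OTU_0002", sample = "AS-N1",
                           count = 3L),
    data.table::data.table(otu_id = "OTU_0003", sample = "REF-1",
                           count = 4L),
    data.table::data.table(otu_id = "OTU_0004",
                           sample = c("AS-N1", "REF-1"), count = c(1L, 1L))))
  calls <- data.table::data.table(
    otu_id = sprintf("OTU_%04d", 1:4),
    identity_class = c("genotype", "species", "unidentified", "species"),
    class = "Trebouxiophyceae", target = TRUE)
  gm <- data.table::data.table(
    sample = c("AS-N1", "AS-S1", "REF-1"),
    group = c("groupA_north", "groupA_south", "groupB_reference"))
  ov <- classify_overlap(sc, calls, gm)
  oc <- ov$calls[order(otu_id)]
  expect_equal(oc$presence,
               c("shared", "groupA_only", "groupB_only", "shared"))
  expect_equal(oc$shared_breakdown,
               c("genotype_identity", "none", "none", "species_level"))
  expect_equal(ov$summary$shared, 2L)
  expect_equal(ov$summary$shared_both_parts, 1L)
  expect_error(classify_overlap(sc, calls, gm[1:2]), "missing")
})
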