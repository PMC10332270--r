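# Synthetic data generator: determinism, divergence bands, community
# structure, read simulation statistics, ground-truth conservation.

test_that("reference DB generation is deterministic and well-formed", {
  db1 <- build_reference_db(seed = 7)
  db2 <- build_reference_db(seed = 7)
  expect_identical(db1$records, db2$records)

  f1 <- tempfile(fileext = ".fasta"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fasta"); t2 <- tempfile(fileext = ".tsv")
  write_refdb(db1, f1, t1); write_refdb(db2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))

  rec <- db1$records[is.na(mislabeled_as)]
  # 4 classes x 3 genera x 2 species x 2 genotypes
  expect_equal(nrow(rec), 48L)
  expect_setequal(unique(rec$class), TARGET_CLASSES)
  # names unique within rank; every record embeds the conserved flanks
  expect_equal(anyDuplicated(rec$genotype), 0L)
  expect_true(all(startsWith(rec$sequence, db1$motifs[["p5"]])))
  expect_true(all(endsWith(rec$sequence, db1$motifs[["p3"]])))
  expect_true(all(nchar(rec$core) >= 174 & nchar(rec$core) <= 295))
  # mislabeled duplicates never alter the sequence of their source genotype
  mis <- db1$records[!is.na(mislabeled_as)]
  expect_true(all(mis$core %in% rec$core))
})

test_that("realized pairwise divergences respect the requested bands", {
  rec <- build_reference_db(seed = 3)$records[is.na(mislabeled_as)]
  ham_frac <- function(a, b) {
    L <- min(nchar(a), nchar(b))
    sum(utf8ToInt(substr(a, 1, L)) != utf8ToInt(substr(b, 1, L))) / L
  }
  n <- nrow(rec)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- ham_frac(rec$core[i], rec$core[j])
      if (rec$species[i] == rec$species[j]) {
        expect_lte(d, 0.04)  # band 0.02 + tolerance
      } else if (rec$genus[i] == rec$genus[j]) {
        expect_gte(d, 0.02); expect_lte(d, 0.17)
      } else if (rec$class[i] == rec$class[j]) {
        expect_gte(d, 0.13); expect_lte(d, 0.42)
      }
    }
  }
})

test_that("degenerate and impossible divergence specs are handled", {
  db <- build_reference_db(n_genotypes_per_species = 1L,
                           divergence_spec = list(
                             genotype_max = 0,
                             species_band = c(0.04, 0.15),
                             genus_band = c(0.15, 0.40)),
                           seed = 5)
  rec <- db$records[is.na(mislabeled_as)]
  expect_equal(nrow(rec), 24L)          # all species singletons
  expect_equal(anyDuplicated(rec$core), 0L)

  expect_error(build_reference_db(divergence_spec = list(
    genotype_max = 0.10, species_band = c(0.04, 0.15),
    genus_band = c(0.15, 0.40))), "impossible")
  expect_error(build_reference_db(divergence_spec = list(
    genotype_max = 0.02, species_band = c(0.04, 0.30),
    genus_band = c(0.15, 0.40))), "impossible")
})

test_that("community simulation realizes the shared fraction", {
  db <- build_reference_db(seed = 11)
  # boundary cases
  c0 <- simulate_communities(db, shared_fraction = 0, frac_groupA = 0.5,
                             frac_groupB = 0.4, seed = 1)
  expect_length(intersect(c0$genotypes_groupA, c0$genotypes_groupB), 0)
  c1 <- simulate_communities(db, shared_fraction = 1, frac_groupB = 0.4,
                             seed = 1)
  expect_true(all(c1$genotypes_groupB %in% c1$genotypes_groupA))
  expect_error(simulate_communities(db, shared_fraction = 1.5),
               "shared_fraction")

  # 200 genotypes, group B draws all 200, shared_fraction 0.35:
  # realized shared count within +-1 of 70
  big <- build_reference_db(n_genera_per_class = 5L,
                            n_species_per_genus = 5L,
                            n_genotypes_per_species = 2L,
                            mislabeled_fraction = 0, seed = 13)
  cb <- simulate_communities(big, shared_fraction = 0.35,
                             frac_groupA = 0.35, frac_groupB = 1,
                             seed = 17)
  realized <- length(intersect(cb$genotypes_groupA, cb$genotypes_groupB))
  expect_lte(abs(realized - 70), 1)
  # profiles: every site total positive, abundances non-negative
  expect_true(all(cb$profiles$expected_reads >= 0))
  tot <- cb$profiles[, sum(expected_reads), by = site]$V1
  expect_true(all(tot > 0))
})

test_that("read simulation matches its stated error/chimera/offtarget model", {
  db <- build_reference_db(seed = 19)
  comm <- simulate_communities(db, n_sites_per_group = c(
    groupA_north = 1L, groupA_south = 0L, groupB_reference = 0L),
    reads_per_site = 10000L, seed = 19)
  sim <- simulate_reads(comm, db, error_rate = 0, chimera_rate = 0.05,
                        offtarget_fraction = 0.02, seed = 23)
  # conservation: one truth row per emitted read
  expect_identical(sort(sim$reads$id), sort(sim$truth$read_id))
  # chimera count within the binomial 99% CI around rate * n
  n <- nrow(sim$truth)
  n_chim <- sum(sim$truth$is_chimera)
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(n_chim, ci[1]); expect_lte(n_chim, ci[2])
  # chimeras have exactly two parents
  expect_true(all(lengths(strsplit(
    sim$truth$parent_ids[sim$truth$is_chimera], ";")) == 2))
  # off-target fraction within its 99% CI
  n_off <- sum(sim$truth$amplicon_group == "offtarget")
  cio <- qbinom(c(0.005, 0.995), n, 0.02)
  expect_gte(n_off, cio[1]); expect_lte(n_off, cio[2])

  # determinism: same seed, byte-identical FASTQ
  sim2 <- simulate_reads(comm, db, error_rate = 0, chimera_rate = 0.05,
                         offtarget_fraction = 0.02, seed = 23)
  d1 <- tempfile(); d2 <- tempfile()
  write_fastq_pairs(sim, d1); write_fastq_pairs(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # FASTQ round trip
  s <- unique(sim$reads$sample)[1]
  back <- read_fastq_pair(file.path(d1, paste0(s, "_R1.fastq")),
                          file.path(d1, paste0(s, "_R2.fastq")), s)
  expect_equal(back, sim$reads[sample == s], ignore_attr = TRUE)
})

test_that("zero-error reads reconstruct their source amplicons exactly", {
  w <- small_world(seed = 31, reads_per_site = 300, offtarget_fraction = 0)
  sim <- w$sim
  rec <- w$refdb$records[is.na(mislabeled_as)]
  amp <- setNames(rec$sequence, rec$genotype)
  pt <- primer_table()
  idx <- sample(nrow(sim$reads), 50)
  for (i in idx) {
    tr <- sim$truth[read_id == sim$reads$id[i]]
    p <- pt[group == tr$amplicon_group]
    f <- sub(paste0("^", p$fwd), "", sim$reads$fwd[i])
    r <- sub(paste0("^", p$rev), "", sim$reads$rev[i])
    mg <- merge_pairs(f, r,
                      substr(sim$reads$fwd_qual[i], 21,
                             nchar(sim$reads$fwd_qual[i])),
                      substr(sim$reads$rev_qual[i], 21,
                             nchar(sim$reads$rev_qual[i])))
    expect_identical(mg$sequence, unname(amp[tr$genotype]))
  }
  # quality strings encode the error model: error_rate 0 -> Q40 throughout
  expect_true(all(grepl("^I+$", sim$reads$fwd_qual)))
})

test_that("overlong amplicons are skipped with a warning", {
  db <- build_reference_db(seed = 37)
  comm <- simulate_communities(db, reads_per_site = 200, seed = 37)
  # read_len 120 -> insert 100, max mergeable amplicon 190; most cores are
  # longer, so many genotypes must be skipped
  expect_warning(
    sim <- simulate_reads(comm, db, read_len = 120L, seed = 37),
    "too long")
  expect_false(any(sim$truth$genotype %in% sim$skipped_genotypes))
})
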