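# Synthetic reference database: a four-class algal taxonomy with controlled
# pairwise ITS2 divergence bands, conserved 5.8S/28S proxy flanks, and an
# optional minority of records mislabeled as non-algal (emulating reference
# sequences from uncultured environmental material deposited under wrong
# names).

#' Target algal classes
#'
#' The four soil-algae classes the amplicon systems target. Three green algal
#' classes are amplified by the "green" primer system, the Xanthophyceae by
#' their own system.
#' @export
TARGET_CLASSES <- c("Chlorophyceae", "Trebouxiophyceae", "Ulvophyceae",
                    "Xanthophyceae")

# Conserved flank proxies embedded around every ITS2 core. The 5' motif
# stands in for the 3' end of the 5.8S gene, the 3' motif for the 5' end of
# the 28S gene. They are identical across all records, so a motif search
# recovers the exact core boundaries.
MOTIF_5P <- "GCATCGATGAAGAACGCAGC"
MOTIF_3P <- "GACCTCAGATCAGACGTGGC"

#' Default pairwise divergence bands
#'
#' Target bands for the fraction of differing sites between ITS2 cores:
#' genotypes within a species at most \code{genotype_max}; species within a
#' genus inside \code{species_band}; genera within a class inside
#' \code{genus_band}. Classes are unrelated random roots (about 75\%
#' divergent).
#' @export
default_divergence <- function() {
  list(genotype_max = 0.02,
       species_band = c(0.04, 0.15),
       genus_band   = c(0.15, 0.40))
}

# Derive per-level branch-length (substitution fraction) ranges so that sums
# along independent branches land inside the requested pairwise bands even
# after the deeper levels add their own substitutions. Mutated position sets
# are kept disjoint along lineages and between siblings, so pairwise
# divergence is (to first order) the sum of branch fractions.
derive_branches <- function(div) {
  gmax <- div$genotype_max
  sb <- div$species_band
  gb <- div$genus_band
  assert_that(gmax >= 0 && all(sb >= 0) && all(gb >= 0),
              "divergence fractions must be non-negative")
  assert_that(sb[1] <= sb[2] && gb[1] <= gb[2],
              "divergence bands must be ordered (min <= max)")
  assert_that(gmax <= sb[1],
              "impossible bands: genotype_max exceeds species band minimum")
  assert_that(sb[2] <= gb[1],
              "impossible bands: species band maximum exceeds genus band minimum")
  w <- c(0, gmax / 2)                      # genotype branch
  v <- c(sb[1] / 2, sb[2] / 2 - w[2])      # species branch
  u <- c(gb[1] / 2, (gb[2] - 2 * (v[2] + w[2])) / 2)  # genus branch
  assert_that(v[1] <= v[2], "impossible bands: species band too narrow")
  assert_that(u[1] <= u[2],
              "impossible bands: genus band too narrow for nested variation")
  list(genus = u, species = v, genotype = w)
}

#' Build a synthetic ITS2 reference database
#'
#' Generates a nested taxonomy (class > order > genus > species > genotype)
#' and one reference record per genotype. Cores evolve by i.i.d.
#' substitutions from per-class root sequences; mutated positions are kept
#' disjoint along lineages and between siblings so that realised pairwise
#' divergences respect the requested bands. A fraction of genotypes gains an
#' extra duplicate record carrying a foreign label (e.g. "uncultured fungus
#' clone"), emulating mislabeled database entries.
#'
#' @param n_genera_per_class,n_species_per_genus,n_genotypes_per_species
#'   taxonomy dimensions (defaults 3, 2, 2).
#' @param divergence_spec list with entries \code{genotype_max},
#'   \code{species_band}, \code{genus_band}; see [default_divergence()].
#' @param core_len_range allowed ITS2 core lengths (bp).
#' @param core_len_mean,core_len_sd normal draw (clamped to the range) for
#'   per-genus core length; defaults reproduce an average near 228 bp.
#' @param mislabeled_fraction fraction of genotypes that receive an extra
#'   mislabeled duplicate record.
#' @param classes class names (exactly these four by default).
#' @param n_orders_per_class number of order-rank labels genera are spread
#'   over within each class.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class \code{its2_refdb}: list with \code{records}
#'   (data.table: id, class, order, genus, species, genotype, core, sequence,
#'   mislabeled_as), \code{taxonomy} (the same minus sequences), and
#'   \code{motifs}.
#' @export
build_reference_db <- function(n_genera_per_class = 3L,
                               n_species_per_genus = 2L,
                               n_genotypes_per_species = 2L,
                               divergence_spec = default_divergence(),
                               core_len_range = c(174L, 295L),
                               core_len_mean = 228,
                               core_len_sd = 25,
                               mislabeled_fraction = 0.1,
                               classes = TARGET_CLASSES,
                               n_orders_per_class = 2L,
                               seed = 1L) {
  br <- derive_branches(divergence_spec)
  set.seed(seed)
  maxlen <- core_len_range[2]
  rows <- list()
  for (cl in classes) {
    root <- random_dna(maxlen)
    used_class <- integer(0)  # positions mutated by any genus of this class
    pre <- substr(cl, 1, 4)
    for (gi in seq_len(n_genera_per_class)) {
      ord <- paste0(pre, "_order", ((gi - 1L) %% n_orders_per_class) + 1L)
      genus <- paste0(pre, "_gen", gi)
      L <- round(rnorm(1, core_len_mean, core_len_sd))
      L <- max(core_len_range[1], min(core_len_range[2], L))
      u <- runif(1, br$genus[1], br$genus[2])
      avail_g <- setdiff(seq_len(L), used_class)
      n_mut <- round(u * L)
      assert_that(length(avail_g) >= n_mut,
                  "divergence bands too wide: ran out of disjoint positions")
      pos_g <- sample(avail_g, n_mut)
      used_class <- c(used_class, pos_g)
      genus_seq <- mutate_at(substr(root, 1, L), pos_g)
      used_genus <- integer(0)  # species-level positions within this genus
      for (si in seq_len(n_species_per_genus)) {
        species <- paste0(genus, "_sp", si)
        v <- runif(1, br$species[1], br$species[2])
        avail_s <- setdiff(seq_len(L), c(used_class, used_genus))
        n_mut <- round(v * L)
        assert_that(length(avail_s) >= n_mut,
                    "divergence bands too wide: ran out of disjoint positions")
        pos_s <- sample(avail_s, n_mut)
        used_genus <- c(used_genus, pos_s)
        species_seq <- mutate_at(genus_seq, pos_s)
        used_species <- integer(0)
        for (ti in seq_len(n_genotypes_per_species)) {
          genotype <- paste0(species, "_gt", ti)
          w <- runif(1, br$genotype[1], br$genotype[2])
          avail_t <- setdiff(seq_len(L),
                             c(used_class, used_genus, used_species))
          n_mut <- round(w * L)
          # keep sibling genotypes distinguishable: at least one private
          # substitution for every genotype after the first
          if (ti > 1L && n_mut == 0L) n_mut <- 1L
          pos_t <- if (n_mut > 0) sample(avail_t, n_mut) else integer(0)
          used_species <- c(used_species, pos_t)
          core <- mutate_at(species_seq, pos_t)
          rows[[length(rows) + 1L]] <- data.table::data.table(
            class = cl, order = ord, genus = genus, species = species,
            genotype = genotype, core = core)
        }
      }
    }
  }
  rec <- data.table::rbindlist(rows)
  rec[, mislabeled_as := NA_character_]
  n_mis <- round(mislabeled_fraction * nrow(rec))
  if (n_mis > 0) {
    mis <- rec[sample.int(nrow(rec), n_mis)]
    mis[, mislabeled_as := "uncultured fungus clone"]
    rec <- data.table::rbindlist(list(rec, mis))
  }
  rec[, id := sprintf("SYN%06d", seq_len(.N))]
  rec[, sequence := paste0(MOTIF_5P, core, MOTIF_3P)]
  data.table::setcolorder(rec, c("id", "class", "order", "genus", "species",
                                 "genotype", "core", "sequence",
                                 "mislabeled_as"))
  structure(list(records = rec,
                 taxonomy = rec[, .(id, class, order, genus, species,
                                    genotype, mislabeled_as)],
                 motifs = c(p5 = MOTIF_5P, p3 = MOTIF_3P),
                 divergence = divergence_spec,
                 seed = seed),
            class = "its2_refdb")
}

#' @export
print.its2_refdb <- function(x, ...) {
  cat("its2_refdb:", nrow(x$records), "records,",
      length(unique(x$records$genotype)), "genotypes,",
      sum(!is.na(x$records$mislabeled_as)), "mislabeled duplicates\n")
  invisible(x)
}

#' Write a reference database to FASTA plus a taxonomy TSV
#'
#' @param refdb an [build_reference_db()] result.
#' @param fasta,taxonomy_tsv output paths.
#' @export
write_refdb <- function(refdb, fasta, taxonomy_tsv) {
  rec <- refdb$records
  hdr <- ifelse(is.na(rec$mislabeled_as),
                paste0(">", rec$id, " ", rec$genotype),
                paste0(">", rec$id, " ", rec$mislabeled_as))
  writeLines(as.vector(rbind(hdr, rec$sequence)), fasta)
  write_tsv(refdb$taxonomy, taxonomy_tsv)
  invisible(c(fasta = fasta, taxonomy = taxonomy_tsv))
}

write_tsv <- function(dt, path) {
  utils::write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE)
}
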