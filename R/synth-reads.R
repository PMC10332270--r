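# Community profiles and error-bearing paired-end read simulation with a
# complete ground-truth table.

# Fixed 20-mer primer tags for the two amplicon systems plus a third tag used
# by off-target templates (whose reads are expected to fail primer screening).
PRIMER_TABLE <- data.table::data.table(
  group = c("green", "xantho", "offtarget"),
  fwd = c("GTGAACCTGCGGAAGGATCA", "GATTCTGCCTAGTAGCTGGT",
          "ACGGCTACCTTGTTACGACT"),
  rev = c("TCCTCCGCTTATTGATATGC", "CAATGTGTCCTGCAATTCAC",
          "TGTACACACCGCCCGTCGCT"))

#' Primer table of the two amplicon systems
#'
#' Returns the forward/reverse 20-mer tags of the green-algal and
#' Xanthophyceae amplicon systems (and the off-target tag pair, which the
#' screening stage is expected to discard).
#' @param include_offtarget keep the off-target row (default FALSE).
#' @return data.table with columns group, fwd, rev.
#' @export
primer_table <- function(include_offtarget = FALSE) {
  pt <- data.table::copy(PRIMER_TABLE)
  if (!include_offtarget) pt <- pt[group != "offtarget"]
  pt
}

# Amplicon system of a taxonomic class.
amplicon_group_of <- function(class) {
  ifelse(class == "Xanthophyceae", "xantho", "green")
}

#' Simulate site communities with a controlled shared-genotype fraction
#'
#' Two site groups are populated from the reference genotype pool: group A
#' (the multi-site group, split into a northern and a southern part) and
#' group B (a single-site reference). The fraction of group-B genotypes also
#' present in group A equals \code{shared_fraction} up to rounding. Expected
#' read counts are log-normal within each group, with mild per-site jitter.
#'
#' @param refdb reference database from [build_reference_db()].
#' @param n_sites_per_group named integer vector with entries
#'   \code{groupA_north}, \code{groupA_south}, \code{groupB_reference}.
#' @param shared_fraction fraction of group-B genotypes shared with group A.
#' @param reads_per_site expected total reads per site.
#' @param sigma log-normal sigma of genotype weights.
#' @param site_sigma log-normal sigma of per-site jitter around the group
#'   weight.
#' @param frac_groupA,frac_groupB fraction of all genotypes present in each
#'   group.
#' @param seed integer seed.
#' @return object of class \code{its2_communities}: list with
#'   \code{profiles} (data.table: site, group, genotype, expected_reads),
#'   genotype sets per group and the realised shared set.
#' @export
simulate_communities <- function(refdb,
                                 n_sites_per_group = c(groupA_north = 4L,
                                                       groupA_south = 3L,
                                                       groupB_reference = 1L),
                                 shared_fraction = 0.35,
                                 reads_per_site = 50000L,
                                 sigma = 1,
                                 site_sigma = 0.3,
                                 frac_groupA = 0.65,
                                 frac_groupB = 0.45,
                                 seed = 1L) {
  assert_that(shared_fraction >= 0 && shared_fraction <= 1,
              "shared_fraction must be in [0, 1]")
  set.seed(seed)
  gset <- unique(refdb$records[is.na(mislabeled_as),
                               .(genotype, class)])
  G <- nrow(gset)
  nA <- round(frac_groupA * G)
  nB <- round(frac_groupB * G)
  nshared <- round(shared_fraction * nB)
  assert_that(nshared <= min(nA, nB),
              "shared_fraction implies more shared genotypes than available")
  assert_that(nB - nshared <= G - nA,
              "not enough genotypes outside group A for the unshared part of group B")
  genotypesA <- sample(gset$genotype, nA)
  shared <- if (nshared > 0) sample(genotypesA, nshared) else character(0)
  pool <- setdiff(gset$genotype, genotypesA)
  genotypesB <- c(shared,
                  if (nB - nshared > 0) sample(pool, nB - nshared)
                  else character(0))
  wA <- stats::setNames(rlnorm(nA, 0, sigma), genotypesA)
  wB <- stats::setNames(rlnorm(nB, 0, sigma), genotypesB)
  site_names <- function(part, n, tag) paste0(tag, seq_len(n))
  sites <- data.table::data.table(
    site = c(site_names("n", n_sites_per_group[["groupA_north"]], "AS-N"),
             site_names("s", n_sites_per_group[["groupA_south"]], "AS-S"),
             site_names("b", n_sites_per_group[["groupB_reference"]], "REF-")),
    group = rep(c("groupA_north", "groupA_south", "groupB_reference"),
                times = c(n_sites_per_group[["groupA_north"]],
                          n_sites_per_group[["groupA_south"]],
                          n_sites_per_group[["groupB_reference"]])))
  profiles <- sites[, {
    w <- if (group %in% c("groupA_north", "groupA_south")) wA else wB
    jitter <- rlnorm(length(w), 0, site_sigma)
    ew <- w * jitter
    list(genotype = names(w),
         expected_reads = as.numeric(reads_per_site) * ew / sum(ew))
  }, by = .(site, group)]
  structure(list(profiles = profiles,
                 sites = sites,
                 genotypes_groupA = genotypesA,
                 genotypes_groupB = genotypesB,
                 shared = shared,
                 params = list(shared_fraction = shared_fraction,
                               reads_per_site = reads_per_site,
                               sigma = sigma, seed = seed)),
            class = "its2_communities")
}

#' @export
print.its2_communities <- function(x, ...) {
  cat("its2_communities:", nrow(x$sites), "sites;",
      length(x$genotypes_groupA), "group-A genotypes,",
      length(x$genotypes_groupB), "group-B genotypes,",
      length(x$shared), "shared\n")
  invisible(x)
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' Each emitted read pair carries a 20-mer primer tag plus a fragment of its
#' source amplicon (conserved 5.8S proxy + ITS2 core + conserved 28S proxy).
#' Sequencing errors are i.i.d. substitutions; quality strings carry the
#' constant Phred score implied by the error rate, so expected-error
#' filtering is analytically predictable. Chimeras are two-parent single
#' crossovers at a uniform breakpoint; off-target reads come from foreign
#' templates tagged with a non-matching primer pair. Amplicons too long to
#' merge at the given read length are skipped with a warning (the clone-only
#' long-sequence case).
#'
#' @param communities result of [simulate_communities()].
#' @param refdb result of [build_reference_db()].
#' @param error_rate per-base substitution probability (default 0.001).
#' @param chimera_rate fraction of target reads that are chimeric.
#' @param offtarget_fraction fraction of reads drawn from off-target
#'   templates.
#' @param read_len read length in bp including the 20-bp tag.
#' @param min_overlap minimum merger overlap the amplicon must allow.
#' @param seed integer seed.
#' @return object of class \code{its2_readsim}: list with \code{reads}
#'   (data.table: id, sample, fwd, rev, fwd_qual, rev_qual) and \code{truth}
#'   (data.table: read_id, genotype, site, amplicon_group, is_chimera,
#'   parent_ids).
#' @export
simulate_reads <- function(communities, refdb,
                           error_rate = 0.001,
                           chimera_rate = 0.01,
                           offtarget_fraction = 0.02,
                           read_len = 200L,
                           min_overlap = 10L,
                           seed = 1L) {
  set.seed(seed)
  insert_len <- read_len - 20L
  assert_that(insert_len > 0, "read_len must exceed the 20-bp tag")
  rec <- refdb$records[is.na(mislabeled_as)]
  amp <- stats::setNames(rec$sequence, rec$genotype)
  grp <- stats::setNames(amplicon_group_of(rec$class), rec$genotype)
  max_amp <- 2L * insert_len - min_overlap
  too_long <- names(amp)[nchar(amp) > max_amp]
  if (length(too_long) > 0) {
    warning("skipping ", length(too_long),
            " genotype(s) with amplicons too long to merge: ",
            paste(too_long, collapse = ", "))
  }
  # off-target templates: three foreign sequences near the typical amplicon
  # length, tagged with the off-target primer pair
  off_templates <- random_dna(c(240L, 268L, 300L))
  q <- if (error_rate > 0) {
    max(2L, min(40L, as.integer(round(-10 * log10(error_rate)))))
  } else 40L
  pt <- PRIMER_TABLE
  read_rows <- vector("list", 0L)
  truth_rows <- vector("list", 0L)
  prof <- communities$profiles
  for (s in unique(prof$site)) {
    p <- prof[site == s & !(genotype %in% too_long)]
    total <- as.integer(round(sum(p$expected_reads)))
    if (total == 0L) next
    n_off <- rbinom(1L, total, offtarget_fraction)
    n_target <- total - n_off
    n_chim <- rbinom(1L, n_target, chimera_rate)
    n_normal <- n_target - n_chim
    counts <- as.vector(rmultinom(1L, n_normal, p$expected_reads))
    src_gt <- rep(p$genotype, counts)
    src_amp <- unname(amp[src_gt])
    src_grp <- unname(grp[src_gt])
    is_chim <- rep(FALSE, n_normal)
    parents <- rep(NA_character_, n_normal)
    if (n_chim > 0L) {
      cg <- character(n_chim); ca <- character(n_chim); pp <- character(n_chim)
      for (i in seq_len(n_chim)) {
        g1 <- sample(p$genotype, 1L, prob = p$expected_reads)
        same <- p[grp[p$genotype] == grp[[g1]] & genotype != g1]
        if (nrow(same) == 0L) {  # lone genotype in its system: emit normal
          cg[i] <- g1; ca[i] <- amp[[g1]]; pp[i] <- NA_character_
          next
        }
        g2 <- sample(same$genotype, 1L, prob = same$expected_reads)
        a1 <- amp[[g1]]; a2 <- amp[[g2]]
        lo <- 21L; hi <- min(nchar(a1), nchar(a2)) - 20L
        k <- if (hi > lo) sample(lo:hi, 1L) else lo
        cg[i] <- NA_character_
        ca[i] <- paste0(substr(a1, 1L, k), substr(a2, k + 1L, nchar(a2)))
        pp[i] <- paste(g1, g2, sep = ";")
      }
      src_gt <- c(src_gt, cg)
      src_amp <- c(src_amp, ca)
      src_grp <- c(src_grp, unname(grp[vapply(strsplit(
        ifelse(is.na(pp), cg, pp), ";"), `[`, character(1), 1L)]))
      is_chim <- c(is_chim, !is.na(pp))
      parents <- c(parents, pp)
    }
    if (n_off > 0L) {
      oi <- sample.int(length(off_templates), n_off, replace = TRUE)
      src_gt <- c(src_gt, rep(NA_character_, n_off))
      src_amp <- c(src_amp, off_templates[oi])
      src_grp <- c(src_grp, rep("offtarget", n_off))
      is_chim <- c(is_chim, rep(FALSE, n_off))
      parents <- c(parents, rep(NA_character_, n_off))
    }
    n <- length(src_amp)
    ids <- sprintf("%s_r%06d", s, seq_len(n))
    L <- nchar(src_amp)
    f_ins <- substr(src_amp, 1L, pmin(L, insert_len))
    r_ins <- revcomp(substr(src_amp, pmax(1L, L - insert_len + 1L), L))
    tag_f <- pt$fwd[match(src_grp, pt$group)]
    tag_r <- pt$rev[match(src_grp, pt$group)]
    fwd <- paste0(tag_f, f_ins)
    rev <- paste0(tag_r, r_ins)
    if (error_rate > 0) {
      fwd <- mutate_strings(fwd, error_rate)
      rev <- mutate_strings(rev, error_rate)
    }
    read_rows[[length(read_rows) + 1L]] <- data.table::data.table(
      id = ids, sample = s, fwd = fwd, rev = rev,
      fwd_qual = phred_string(q, nchar(fwd)),
      rev_qual = phred_string(q, nchar(rev)))
    truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
      read_id = ids, genotype = src_gt, site = s, amplicon_group = src_grp,
      is_chimera = is_chim, parent_ids = parents)
  }
  structure(list(reads = data.table::rbindlist(read_rows),
                 truth = data.table::rbindlist(truth_rows),
                 skipped_genotypes = too_long,
                 params = list(error_rate = error_rate,
                               chimera_rate = chimera_rate,
                               offtarget_fraction = offtarget_fraction,
                               read_len = read_len, q = q, seed = seed)),
            class = "its2_readsim")
}

#' @export
print.its2_readsim <- function(x, ...) {
  cat("its2_readsim:", nrow(x$reads), "read pairs,",
      sum(x$truth$is_chimera), "chimeric,",
      sum(x$truth$amplicon_group == "offtarget"), "off-target\n")
  invisible(x)
}

#' Write simulated reads as paired FASTQ files (one pair per sample)
#'
#' @param sim result of [simulate_reads()].
#' @param dir output directory (created if absent).
#' @return invisible character vector of written paths.
#' @export
write_fastq_pairs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(sim$reads$sample)) {
    r <- sim$reads[sample == s]
    p1 <- file.path(dir, paste0(s, "_R1.fastq"))
    p2 <- file.path(dir, paste0(s, "_R2.fastq"))
    writeLines(as.vector(rbind(paste0("@", r$id), r$fwd, "+", r$fwd_qual)), p1)
    writeLines(as.vector(rbind(paste0("@", r$id), r$rev, "+", r$rev_qual)), p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

#' Read paired FASTQ files into the simulator's read-pair layout
#'
#' @param r1,r2 paths to the mate files (plain text or gzip).
#' @param sample sample label attached to every pair.
#' @return data.table with columns id, sample, fwd, rev, fwd_qual, rev_qual.
#' @export
read_fastq_pair <- function(r1, r2, sample) {
  f <- readLines(r1); r <- readLines(r2)
  assert_that(length(f) %% 4 == 0 && length(r) == length(f),
              "malformed FASTQ pair")
  i <- seq(1L, length(f), by = 4L)
  data.table::data.table(
    id = sub("^@", "", sub("\\s.*", "", f[i])),
    sample = sample,
    fwd = f[i + 1L], rev = r[i + 1L],
    fwd_qual = f[i + 3L], rev_qual = r[i + 3L])
}
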