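# End-to-end orchestration: validated config, staged execution with
# per-stage read-conservation logging, headline summary.

#' Build and validate a pipeline configuration
#'
#' All stage parameters with their defaults. In synthetic mode
#' (\code{simulate = TRUE}) the generator settings are used to build the
#' reference database, communities and reads in memory; otherwise
#' \code{reads}, \code{refdb} (and optionally \code{clones},
#' \code{hit_table}) must be supplied to [run_pipeline()] directly.
#'
#' @param simulate generate inputs synthetically (default TRUE).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param refdb_args,community_args,read_args lists of overrides for
#'   [build_reference_db()], [simulate_communities()], [simulate_reads()].
#' @param max_primer_mismatch,min_overlap,max_overlap_mismatch_frac,min_len,
#'   max_ee,identity_threshold,floor_fraction,n_consensus,n_recorded,
#'   genotype_threshold,species_threshold,nb_tolerance stage parameters; see
#'   the stage functions.
#' @param n_clones number of clone-library sequences simulated (synthetic
#'   mode; clones are drawn from reference genotypes).
#' @param out optional output directory for TSV/JSON artifacts.
#' @return validated config list of class \code{its2_config}.
#' @export
its2_config <- function(simulate = TRUE,
                        seed = 1L,
                        refdb_args = list(),
                        community_args = list(),
                        read_args = list(),
                        max_primer_mismatch = 1L,
                        min_overlap = 10L,
                        max_overlap_mismatch_frac = 0.1,
                        min_len = 200L,
                        max_ee = 1.0,
                        identity_threshold = 0.97,
                        floor_fraction = 5e-5,
                        n_consensus = 10L,
                        n_recorded = 50L,
                        genotype_threshold = 1.81,
                        species_threshold = 1.75,
                        nb_tolerance = 0.005,
                        n_clones = 20L,
                        hit_table_path = NULL,
                        out = NULL) {
  cfg <- as.list(environment())
  assert_that(max_primer_mismatch >= 0, "max_primer_mismatch must be >= 0")
  assert_that(min_overlap >= 1, "min_overlap must be >= 1")
  assert_that(max_overlap_mismatch_frac >= 0 &&
                max_overlap_mismatch_frac <= 1,
              "max_overlap_mismatch_frac must be in [0, 1]")
  assert_that(min_len >= 0 && max_ee > 0, "invalid filter parameters")
  assert_that(identity_threshold > 0 && identity_threshold <= 1,
              "identity_threshold must be in (0, 1]")
  assert_that(floor_fraction >= 0 && floor_fraction <= 1,
              "floor_fraction must be in [0, 1]")
  assert_that(n_consensus >= 1 && n_recorded >= n_consensus,
              "need n_recorded >= n_consensus >= 1")
  assert_that(species_threshold <= genotype_threshold,
              "species_threshold must not exceed genotype_threshold")
  structure(cfg, class = "its2_config")
}

#' Run the full pipeline
#'
#' Stage order: simulate (optional) -> primer screen/split -> merge ->
#' quality filter -> dereplicate -> chimera flagging -> ITS2 trimming ->
#' pooled OTU clustering -> per-group abundance floor -> clone co-clustering
#' -> hit-table taxonomy -> overlap classification -> community statistics.
#' Every stage's input/output counts are recorded in the processing log;
#' identical config and seed give identical results.
#'
#' @param config an [its2_config()] result.
#' @param reads,refdb,communities,clones,hit_table optional pre-built inputs
#'   overriding synthetic generation; \code{hit_table} skips the built-in
#'   aligner.
#' @return manifest list of class \code{its2_manifest} with all stage
#'   outputs, the processing log and a headline summary.
#' @export
run_pipeline <- function(config = its2_config(), reads = NULL, refdb = NULL,
                         communities = NULL, clones = NULL,
                         hit_table = NULL) {
  stopifnot(inherits(config, "its2_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- data.table::data.table(stage = stage, ...)
  }
  if (is.null(refdb)) {
    assert_that(config$simulate, "refdb required when simulate = FALSE")
    refdb <- do.call(build_reference_db, utils::modifyList(
      list(seed = stage_seed(config$seed, "refdb")), config$refdb_args))
  }
  sim <- NULL
  if (is.null(reads)) {
    assert_that(config$simulate, "reads required when simulate = FALSE")
    if (is.null(communities)) {
      communities <- do.call(simulate_communities, utils::modifyList(
        list(refdb = refdb, seed = stage_seed(config$seed, "communities")),
        config$community_args))
    }
    sim <- do.call(simulate_reads, utils::modifyList(
      list(communities = communities, refdb = refdb,
           seed = stage_seed(config$seed, "reads")), config$read_args))
    reads <- sim$reads
  }
  note("input", n = nrow(reads))
  raw_total <- nrow(reads)

  ## screen and split
  scr <- screen_and_split(reads, primer_table(), config$max_primer_mismatch)
  raw_by_pool <- vapply(scr$pools, nrow, integer(1))
  note("screen", n = sum(raw_by_pool), discarded = nrow(scr$discarded))
  assert_that(sum(raw_by_pool) + nrow(scr$discarded) == raw_total,
              "screen stage lost reads")

  ## per-pool: merge, filter, derep, chimera, trim
  pools <- list()
  for (g in names(scr$pools)) {
    pool <- scr$pools[[g]]
    if (nrow(pool) == 0L) next
    mg <- merge_pool(pool, config$min_overlap,
                     config$max_overlap_mismatch_frac)
    note(paste0("merge_", g), n = nrow(mg$merged),
         discarded = nrow(mg$rejected))
    assert_that(nrow(mg$merged) + nrow(mg$rejected) == nrow(pool),
                "merge stage lost reads")
    keep <- quality_filter(mg$merged$sequence, mg$merged$qual,
                           config$min_len, config$max_ee)
    filt <- mg$merged[keep]
    note(paste0("filter_", g), n = nrow(filt), discarded = sum(!keep))
    if (nrow(filt) == 0L) next
    der <- dereplicate(filt$sequence, filt$sample)
    note(paste0("derep_", g), n = nrow(der$derep),
         reads = sum(der$derep$abundance))
    chim <- detect_chimeras_denovo(der)
    flagged <- chim$seq_id[chim$is_chimera]
    keep_ids <- setdiff(der$derep$seq_id, flagged)
    note(paste0("chimera_", g), n = length(keep_ids),
         discarded = length(flagged))
    dd <- der$derep[seq_id %in% keep_ids]
    trimmed <- extract_its2(dd$sequence)
    ok <- trimmed$status == "ok"
    note(paste0("trim_", g), n = sum(ok), discarded = sum(!ok))
    dd <- dd[ok]
    dd[, core := trimmed$core[ok]]
    sc <- der$sample_counts[seq_id %in% dd$seq_id]
    pools[[g]] <- list(derep = dd, sample_counts = sc,
                       chimera = chim, raw = raw_by_pool[[g]])
  }
  assert_that(length(pools) > 0, "no reads survived processing")

  ## pool the trimmed cores and re-dereplicate across groups
  allseq <- data.table::rbindlist(lapply(names(pools), function(g) {
    sc <- merge(pools[[g]]$sample_counts,
                pools[[g]]$derep[, .(seq_id, core)], by = "seq_id")
    sc[, pool := g]
    sc[, .(core, sample, count, pool)]
  }))
  pooled <- dereplicate(allseq$core, allseq$sample, allseq$count)
  core_pool <- allseq[, .(count = sum(count)), by = .(core, pool)]
  core_group <- core_pool[order(-count),
                          .(pool = pool[1]), by = core]
  note("pool", n = nrow(pooled$derep), reads = sum(pooled$derep$abundance))

  ## cluster
  otus <- cluster_otus(pooled, config$identity_threshold)
  note("cluster", n = nrow(otus$otus), reads = sum(otus$otus$total_reads))
  assert_that(sum(otus$otus$total_reads) == sum(pooled$derep$abundance),
              "clustering lost reads")
  ## amplicon group of each OTU = group of its centroid
  otus$otus[, pool := core_group$pool[match(centroid, core_group$core)]]

  ## abundance floor, per amplicon group against that group's raw count
  kept_parts <- list(); removed_parts <- list()
  for (g in unique(otus$otus$pool)) {
    ids_g <- otus$otus$otu_id[otus$otus$pool == g]
    sub <- structure(list(otus = otus$otus[otu_id %in% ids_g],
                          members = otus$members[otu_id %in% ids_g],
                          sample_counts = otus$sample_counts[otu_id %in% ids_g]),
                     class = "its2_otus")
    fl <- filter_low_abundance(sub, pools[[g]]$raw, config$floor_fraction)
    kept_parts[[g]] <- fl$otus
    removed_parts[[g]] <- fl$removed
  }
  otus_f <- structure(list(
    otus = data.table::rbindlist(lapply(kept_parts, `[[`, "otus")),
    members = data.table::rbindlist(lapply(kept_parts, `[[`, "members")),
    sample_counts = data.table::rbindlist(lapply(kept_parts, `[[`,
                                                 "sample_counts"))),
    class = "its2_otus")
  data.table::setorder(otus_f$otus, otu_id)
  removed <- data.table::rbindlist(removed_parts)
  note("floor", n = nrow(otus_f$otus), discarded = nrow(removed))

  ## clone co-clustering
  if (is.null(clones) && config$simulate && config$n_clones > 0) {
    set.seed(stage_seed(config$seed, "clones"))
    rec <- refdb$records[is.na(mislabeled_as)]
    pick <- rec[sample.int(nrow(rec), min(config$n_clones, nrow(rec)))]
    clones <- stats::setNames(pick$core,
                              sprintf("clone_%s", pick$genotype))
  }
  cc <- cocluster_clones(otus_f, clones %||% character(0),
                         config$identity_threshold)
  otus_f <- cc$otus
  note("clones", n = nrow(cc$assignments),
       discarded = nrow(cc$clone_clusters))

  ## taxonomy (an externally supplied hit table skips the built-in aligner)
  if (is.null(hit_table) && !is.null(config$hit_table_path)) {
    hit_table <- read_hit_table(config$hit_table_path)
  }
  if (is.null(hit_table)) {
    queries <- stats::setNames(otus_f$otus$centroid, otus_f$otus$otu_id)
    hit_table <- blast_search(queries, refdb, config$n_recorded)
  }
  calls <- assign_taxonomy(hit_table, otu_ids = otus_f$otus$otu_id,
                           n_consensus = config$n_consensus,
                           n_recorded = config$n_recorded,
                           genotype_threshold = config$genotype_threshold,
                           species_threshold = config$species_threshold,
                           nb_tolerance = config$nb_tolerance)
  calls <- merge(calls,
                 otus_f$otus[, .(otu_id, total_reads, has_clone_member)],
                 by = "otu_id", sort = FALSE)
  calls[, label_group := data.table::fifelse(
    assigned_rank %in% c("genotype", "species"),
    sub("_sp[0-9]+.*$", "", label), label)]
  note("taxonomy", n = nrow(calls))

  ## overlap + stats
  group_map <- if (!is.null(communities)) {
    communities$sites[, .(sample = site, group)]
  } else {
    data.table::data.table(sample = unique(reads$sample),
                           group = "groupA_north")
  }
  overlap <- classify_overlap(otus_f$sample_counts, calls, group_map)
  counts <- otu_matrix(otus_f$sample_counts)
  composition <- class_composition(calls, counts)
  alpha <- alpha_diversity_table(counts)
  boxstats <- genus_nb_boxstats(calls[isTRUE_vec(target)])
  topn <- top_n_matrix(counts, calls[isTRUE_vec(target)], group_map)
  rare <- data.table::rbindlist(lapply(colnames(counts), function(s) {
    total <- sum(counts[, s])
    if (total == 0) return(NULL)
    depths <- unique(pmax(1, round(seq(1, total, length.out = 10))))
    r <- rarefaction_curve(counts[, s], depths, n_reps = 25,
                           seed = stage_seed(config$seed, paste0("rare_", s)))
    r[, sample := s]
    r
  }))
  note("stats", n = nrow(alpha))

  manifest <- structure(list(
    config = config,
    refdb = refdb,
    communities = communities,
    truth = if (!is.null(sim)) sim$truth else NULL,
    log = data.table::rbindlist(log, fill = TRUE),
    screen = scr$log,
    otus = otus_f,
    removed_otus = removed,
    clone_assignments = cc$assignments,
    clone_clusters = cc$clone_clusters,
    hit_table = hit_table,
    calls = calls,
    overlap = overlap,
    counts = counts,
    composition = composition,
    alpha = alpha,
    boxstats = boxstats,
    top_n = topn,
    rarefaction = rare), class = "its2_manifest")
  manifest$summary <- summarize_run(manifest)
  if (!is.null(config$out)) write_manifest(manifest, config$out)
  manifest
}

#' @export
print.its2_manifest <- function(x, ...) {
  cat("its2_manifest:", nrow(x$otus$otus), "OTUs,",
      nrow(x$calls), "taxonomy calls\n")
  invisible(x)
}

#' Headline percentages from raw counts
#'
#' Pure arithmetic on a named list of counts; every percentage reported by
#' [summarize_run()] is recomputable through this function. Expected names
#' (all optional): total_otus, algal_otus, class counts (named by class),
#' groupB_algal, shared, shared_genotype, shared_species,
#' shared_both_parts, identified, genotype_otus, species_otus, mixed_otus,
#' per-class shared counts as shared_<class>.
#'
#' @param counts named list/vector of counts.
#' @return named numeric vector of percentages (1 dp).
#' @export
headline_percentages <- function(counts) {
  counts <- as.list(counts)
  out <- c()
  grab <- function(n) counts[[n]] %||% NA_real_
  algal <- grab("algal_otus")
  out["pct_algal_of_total"] <- pct(algal, grab("total_otus"))
  for (cl in intersect(TARGET_CLASSES, names(counts))) {
    out[paste0("pct_", cl, "_of_algal")] <- pct(counts[[cl]], algal)
  }
  out["pct_shared_of_groupA"] <- pct(grab("shared"), algal)
  out["pct_shared_of_groupB"] <- pct(grab("shared"), grab("groupB_algal"))
  for (cl in TARGET_CLASSES) {
    sh <- counts[[paste0("shared_", cl)]]
    if (!is.null(sh)) {
      out[paste0("pct_shared_of_", cl)] <- pct(sh, counts[[cl]])
    }
  }
  out["pct_shared_genotype_of_shared"] <-
    pct(grab("shared_genotype"), grab("shared"))
  out["pct_shared_species_of_shared"] <-
    pct(grab("shared_species"), grab("shared"))
  out["pct_shared_both_parts_of_shared"] <-
    pct(grab("shared_both_parts"), grab("shared"))
  out["pct_identified_of_algal"] <- pct(grab("identified"), algal)
  out["pct_genotype_of_algal"] <- pct(grab("genotype_otus"), algal)
  out["pct_species_of_algal"] <- pct(grab("species_otus"), algal)
  out["pct_mixed_of_algal"] <- pct(grab("mixed_otus"), algal)
  out
}

#' Headline summary of a finished run
#'
#' Totals, per-class counts and percentages, overlap percentages and
#' identity-class fractions; every percentage is recomputable from the
#' manifest's tables via [headline_percentages()].
#'
#' @param manifest an [run_pipeline()] manifest.
#' @return named list.
#' @export
summarize_run <- function(manifest) {
  calls <- manifest$calls
  algal <- calls[isTRUE_vec(target)]
  ov <- manifest$overlap$summary
  class_counts <- as.list(table(algal$class))
  idc <- table(algal$identity_class)
  counts <- c(list(
    total_otus = nrow(calls),
    algal_otus = nrow(algal),
    groupB_algal = ov$algal_groupB,
    shared = ov$shared,
    shared_genotype = unname(ov$breakdown["genotype_identity"] %|NA|% 0),
    shared_species = unname(ov$breakdown["species_level"] %|NA|% 0),
    shared_both_parts = ov$shared_both_parts,
    identified = sum(algal$identity_class %in% c("genotype", "species")),
    genotype_otus = unname(idc["genotype"] %|NA|% 0),
    species_otus = unname(idc["species"] %|NA|% 0),
    mixed_otus = sum(isTRUE_vec(algal$has_clone_member))),
    class_counts)
  for (cl in TARGET_CLASSES) {
    pc <- ov$per_class[class == cl]
    if (nrow(pc) == 1) counts[[paste0("shared_", cl)]] <- pc$shared
  }
  list(counts = counts, percentages = headline_percentages(counts))
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Write manifest artifacts as plain-text files
#'
#' @param manifest an [run_pipeline()] manifest.
#' @param dir output directory.
#' @return invisible named vector of file paths with md5 hashes as names.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  w <- function(obj, name) {
    p <- file.path(dir, name)
    write_tsv(obj, p)
    paths <<- c(paths, p)
  }
  w(manifest$log, "processing_log.tsv")
  w(manifest$otus$otus[, .(otu_id, centroid, total_reads,
                           has_clone_member)], "otus.tsv")
  ot <- manifest$otus$otus
  p <- file.path(dir, "centroids.fasta")
  writeLines(as.vector(rbind(paste0(">", ot$otu_id, ";size=",
                                    ot$total_reads), ot$centroid)), p)
  paths <- c(paths, p)
  w(manifest$otus$sample_counts, "otu_table.tsv")
  w(manifest$otus$members[, .(otu_id, seq_id, identity, abundance)],
    "membership.tsv")
  if (nrow(manifest$clone_assignments) > 0 ||
        nrow(manifest$clone_clusters) > 0) {
    w(manifest$clone_assignments, "clone_assignments.tsv")
    w(manifest$clone_clusters, "clone_clusters.tsv")
  }
  w(manifest$calls[, .(otu_id, label, assigned_rank, class, best_nb,
                       identity_class, target)], "taxonomy_calls.tsv")
  w(manifest$overlap$calls, "overlap.tsv")
  w(manifest$composition, "class_composition.tsv")
  w(manifest$alpha, "alpha_diversity.tsv")
  bs <- data.table::copy(manifest$boxstats)
  bs[, outliers := vapply(outliers, paste, character(1), collapse = ";")]
  w(bs, "nb_boxstats.tsv")
  w(manifest$top_n, "top_n_matrix.tsv")
  if (nrow(manifest$rarefaction) > 0) w(manifest$rarefaction,
                                        "rarefaction.tsv")
  if (nrow(manifest$hit_table) > 0) w(manifest$hit_table, "hit_table.tsv")
  ov <- manifest$overlap$summary
  jsonlite::write_json(
    list(groupA = ov$algal_groupA, groupB = ov$algal_groupB,
         shared = ov$shared, breakdown = as.list(ov$breakdown),
         shared_both_parts = ov$shared_both_parts),
    file.path(dir, "venn_counts.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(dir, "venn_counts.json"))
  jsonlite::write_json(manifest$summary,
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(manifest$config)[
    !vapply(unclass(manifest$config), is.list, logical(1))],
    file.path(dir, "config_snapshot.yaml"))
  paths <- c(paths, file.path(dir, "summary.json"),
             file.path(dir, "config_snapshot.yaml"))
  hashes <- tools::md5sum(paths)
  invisible(hashes)
}
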