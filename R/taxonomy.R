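# Consensus taxonomy over recorded hits: bit-score-sum candidacy per rank,
# non-target suppression by summed bit scores, NB-threshold identity
# classes, and site-overlap classification.

RANK_LADDER <- c("genotype", "species", "genus", "order", "class")

#' Classify an NB value into an identity class
#'
#' Genotype identity means NB at the ceiling (full sequence identity with a
#' reference); the species band is 1.75 <= NB < ceiling; everything lower is
#' unidentified at species level. Because bit scores vary slightly with
#' length, equality with the ceiling is operationalised with a small
#' tolerance (ceiling - \code{nb_tolerance}).
#'
#' @param best_nb numeric NB value(s).
#' @param genotype_threshold NB ceiling (default 1.81).
#' @param species_threshold lower edge of the species band (default 1.75).
#' @param nb_tolerance tolerance on the ceiling (default 0.005).
#' @return character vector: "genotype", "species" or "unidentified".
#' @export
classify_identity <- function(best_nb, genotype_threshold = 1.81,
                              species_threshold = 1.75,
                              nb_tolerance = 0.005) {
  out <- rep("unidentified", length(best_nb))
  out[!is.na(best_nb) & best_nb >= species_threshold] <- "species"
  out[!is.na(best_nb) & best_nb >= genotype_threshold - nb_tolerance] <-
    "genotype"
  out[is.na(best_nb)] <- "unidentified"
  out
}

#' Consensus taxonomic assignment for one OTU
#'
#' Works on the recorded hits of a single query, sorted by decreasing bit
#' score. Non-target lineages (e.g. reference sequences labeled as fungi)
#' are out-competed by summing: when the summed bit score of target-class
#' hits over all recorded hits exceeds the non-target sum, non-target labels
#' are excluded from candidacy. Candidacy is then evaluated over the top
#' \code{n_consensus} remaining hits, rank by rank from genotype upward: the
#' label with the highest bit-score sum is the candidate, and the most
#' specific rank whose candidate is supported by a best hit with NB in the
#' species band (>= \code{species_threshold}; for genotype rank, at the
#' ceiling) is assigned. Failing both, the call falls back to "<genus> sp.",
#' then "unidentified <order>", then "unidentified <class>". Ties break by
#' best single bit score, then lexicographically.
#'
#' @param hits data.table of hits for one query as produced by
#'   [blast_search()] (needs bitscore, nb, and lineage columns; rows with NA
#'   lineage are treated as non-target).
#' @param n_consensus hits used for candidacy (default 10).
#' @param n_recorded hits used for non-target suppression (default 50).
#' @param target_classes lineage classes considered on-target.
#' @param genotype_threshold,species_threshold,nb_tolerance see
#'   [classify_identity()].
#' @return one-row data.table: otu_id, label, assigned_rank, class, best_nb,
#'   identity_class, target, support (list of named sums at the decision
#'   rank).
#' @export
consensus_assign <- function(hits, n_consensus = 10L, n_recorded = 50L,
                             target_classes = TARGET_CLASSES,
                             genotype_threshold = 1.81,
                             species_threshold = 1.75,
                             nb_tolerance = 0.005) {
  otu <- if (nrow(hits) > 0) hits$qseqid[1] else NA_character_
  no_call <- data.table::data.table(
    otu_id = otu, label = "no_hit", assigned_rank = NA_character_,
    class = NA_character_, best_nb = NA_real_,
    identity_class = "unidentified", target = NA, support = list(numeric(0)))
  if (nrow(hits) == 0L) return(no_call)
  hits <- utils::head(hits[order(-bitscore, sseqid)], n_recorded)
  is_target <- !is.na(hits$class) & hits$class %in% target_classes
  target_sum <- sum(hits$bitscore[is_target])
  nontarget_sum <- sum(hits$bitscore[!is_target])
  if (target_sum > nontarget_sum) {
    cand_hits <- hits[is_target]
  } else {
    # non-target wins: report the best-supported non-target label
    nt <- hits[!is_target]
    sums <- nt[, .(sum = sum(bitscore), best = max(bitscore)),
               by = .(label = stitle)]
    data.table::setorder(sums, -sum, -best, label)
    best_nb <- max(nt$nb[nt$stitle == sums$label[1]])
    return(data.table::data.table(
      otu_id = otu, label = sums$label[1], assigned_rank = NA_character_,
      class = "nonalgal", best_nb = best_nb,
      identity_class = classify_identity(best_nb, genotype_threshold,
                                         species_threshold, nb_tolerance),
      target = FALSE, support = list(stats::setNames(sums$sum, sums$label))))
  }
  top <- utils::head(cand_hits, n_consensus)
  pick_candidate <- function(rank) {
    sub <- top[!is.na(top[[rank]])]
    if (nrow(sub) == 0L) return(NULL)
    sums <- sub[, .(sum = sum(bitscore), best = max(bitscore)),
                by = c(rank)]
    data.table::setnames(sums, rank, "label")
    data.table::setorder(sums, -sum, -best, label)
    list(label = sums$label[1],
         support = stats::setNames(sums$sum, sums$label),
         best_nb = max(sub$nb[sub[[rank]] == sums$label[1]]))
  }
  finish <- function(label, rank, cand) {
    cls <- unique(top$class[!is.na(top$class)])[1]
    data.table::data.table(
      otu_id = otu, label = label, assigned_rank = rank, class = cls,
      best_nb = cand$best_nb,
      identity_class = classify_identity(cand$best_nb, genotype_threshold,
                                         species_threshold, nb_tolerance),
      target = TRUE, support = list(cand$support))
  }
  gt <- pick_candidate("genotype")
  if (!is.null(gt) && gt$best_nb >= genotype_threshold - nb_tolerance) {
    return(finish(gt$label, "genotype", gt))
  }
  sp <- pick_candidate("species")
  if (!is.null(sp) && sp$best_nb >= species_threshold) {
    return(finish(sp$label, "species", sp))
  }
  ge <- pick_candidate("genus")
  if (!is.null(ge)) {
    return(finish(paste(ge$label, "sp."), "genus", ge))
  }
  or <- pick_candidate("order")
  if (!is.null(or)) {
    return(finish(paste("unidentified", or$label), "order", or))
  }
  cl <- pick_candidate("class")
  if (!is.null(cl)) {
    return(finish(paste("unidentified", cl$label), "class", cl))
  }
  no_call
}

#' Consensus assignment for every query in a hit table
#'
#' @param hit_table data.table from [blast_search()] (multiple queries).
#' @param otu_ids all query ids expected (queries without hits get a
#'   "no_hit" call).
#' @inheritParams consensus_assign
#' @return data.table of calls, one row per OTU.
#' @export
assign_taxonomy <- function(hit_table, otu_ids = NULL, ...) {
  groups <- if (nrow(hit_table) > 0) split(hit_table, by = "qseqid") else list()
  calls <- data.table::rbindlist(lapply(groups, consensus_assign, ...))
  if (!is.null(otu_ids)) {
    missing <- setdiff(otu_ids, calls$otu_id)
    if (length(missing) > 0) {
      empty <- data.table::rbindlist(lapply(missing, function(id) {
        no <- consensus_assign(hit_table[0L], ...)
        no$otu_id <- id
        no
      }))
      calls <- data.table::rbindlist(list(calls, empty))
    }
    calls <- calls[match(otu_ids, otu_id)]
  }
  calls[]
}

#' Classify OTU presence across the two site groups
#'
#' Presence comes from nonzero read counts. Shared OTUs (present in both the
#' multi-site group A and the reference group B) are subdivided by their
#' identity class: genotype identity, species level, or reference-independent
#' (unidentified, their shared distribution deduced purely from co-clustered
#' reads). Also reports per-class overlap counts and the subset of shared
#' OTUs present in both sub-parts of group A.
#'
#' @param sample_counts data.table: otu_id, sample, count.
#' @param calls taxonomy calls from [assign_taxonomy()].
#' @param group_map data.table: sample, group (groups starting "groupA" /
#'   "groupB").
#' @return list with \code{calls} (data.table: otu_id, presence,
#'   shared_breakdown) and \code{summary} (counts and percentages).
#' @export
classify_overlap <- function(sample_counts, calls, group_map) {
  missing <- setdiff(unique(sample_counts$sample), group_map$sample)
  assert_that(length(missing) == 0,
              paste("samples missing from group map:",
                    paste(missing, collapse = ", ")))
  sc <- merge(sample_counts, group_map, by = "sample")
  sc <- sc[count > 0]
  pres <- sc[, .(
    inA = any(startsWith(group, "groupA")),
    inB = any(startsWith(group, "groupB")),
    in_north = any(group == "groupA_north"),
    in_south = any(group == "groupA_south")), by = otu_id]
  pres[, presence := data.table::fcase(
    inA & inB, "shared", inA, "groupA_only", inB, "groupB_only")]
  pres <- merge(pres,
                calls[, .(otu_id, identity_class, class, target)],
                by = "otu_id", all.x = TRUE)
  pres[, shared_breakdown := "none"]
  pres[presence == "shared" & identity_class == "genotype",
       shared_breakdown := "genotype_identity"]
  pres[presence == "shared" & identity_class == "species",
       shared_breakdown := "species_level"]
  pres[presence == "shared" & identity_class == "unidentified",
       shared_breakdown := "reference_independent"]
  alg <- pres[isTRUE_vec(target)]
  n_shared <- sum(alg$presence == "shared")
  n_A <- sum(alg$inA)
  n_B <- sum(alg$inB)
  per_class <- alg[, .(
    groupA = sum(inA), shared = sum(presence == "shared")), by = class]
  per_class[, pct_shared_of_groupA := pct(shared, groupA)]
  summary <- list(
    algal_groupA = n_A,
    algal_groupB = n_B,
    shared = n_shared,
    pct_shared_of_groupA = pct(n_shared, n_A),
    pct_shared_of_groupB = pct(n_shared, n_B),
    breakdown = table(alg$shared_breakdown[alg$presence == "shared"]),
    shared_both_parts = sum(alg$presence == "shared" & alg$in_north &
                              alg$in_south),
    per_class = per_class)
  list(calls = pres[, .(otu_id, presence, shared_breakdown, inA, inB,
                        in_north, in_south)],
       summary = summary)
}

isTRUE_vec <- function(x) !is.na(x) & x

# Percentage rounded to 1 dp (presentation convention used throughout).
pct <- function(x, total, digits = 1) {
  ifelse(total > 0, round(100 * x / total, digits), NA_real_)
}
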