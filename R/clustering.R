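# ITS2 core extraction (motif proxy for the HMM-based extractor), greedy
# abundance-sorted centroid clustering at 97% identity, relative-abundance
# floor, and co-clustering of long clone-library sequences.

# Best match of a short motif in a sequence: slide over every offset and
# count mismatches. Returns list(start, mismatches) of the best offset or
# NULL when nothing is within tolerance.
find_motif <- function(seq_int, motif_int, max_mm, from = 1L) {
  L <- length(seq_int); k <- length(motif_int)
  last <- L - k + 1L
  if (last < from) return(NULL)
  best <- NULL; best_mm <- max_mm + 1L
  for (s in from:last) {
    mm <- sum(seq_int[s:(s + k - 1L)] != motif_int)
    if (mm < best_mm) {
      best_mm <- mm; best <- s
      if (mm == 0L) break
    }
  }
  if (is.null(best) || best_mm > max_mm) return(NULL)
  list(start = best, mismatches = best_mm)
}

#' Extract the ITS2 core between conserved flanking motifs
#'
#' Motif-proxy stand-in for HMM-based ITS2 extraction: returns the
#' subsequence strictly between the best match of the 5' flank motif and the
#' best match of the 3' flank motif downstream of it, each within
#' \code{max_motif_mismatch} substitutions. Sequences missing either motif,
#' or whose motif hits overlap (empty core), are rejected with a reason.
#'
#' @param sequences character vector.
#' @param motif_5p,motif_3p flanking motifs (defaults are the motifs the
#'   generator embeds).
#' @param max_motif_mismatch tolerance per motif (default 1).
#' @return data.table: sequence, core (NA on rejection), status
#'   ("ok"/"rejected"), reason.
#' @export
extract_its2 <- function(sequences, motif_5p = MOTIF_5P, motif_3p = MOTIF_3P,
                         max_motif_mismatch = 1L) {
  m5 <- utf8ToInt(motif_5p); m3 <- utf8ToInt(motif_3p)
  useq <- unique(sequences)
  res <- lapply(useq, function(s) {
    si <- utf8ToInt(s)
    h5 <- find_motif(si, m5, max_motif_mismatch)
    if (is.null(h5)) return(list(NA_character_, "no_5p_motif"))
    end5 <- h5$start + length(m5) - 1L
    h3 <- find_motif(si, m3, max_motif_mismatch, from = h5$start + 1L)
    if (is.null(h3)) return(list(NA_character_, "no_3p_motif"))
    if (h3$start <= end5) return(list(NA_character_, "overlapping_motifs"))
    if (h3$start == end5 + 1L) return(list(NA_character_, "empty_core"))
    list(substr(s, end5 + 1L, h3$start - 1L), NA_character_)
  })
  cores <- vapply(res, `[[`, character(1), 1L)
  reasons <- vapply(res, `[[`, character(1), 2L)
  idx <- match(sequences, useq)
  data.table::data.table(
    sequence = sequences, core = cores[idx],
    status = ifelse(is.na(cores[idx]), "rejected", "ok"),
    reason = reasons[idx])
}

#' Greedy abundance-sorted centroid OTU clustering
#'
#' Sequences are visited in decreasing abundance (ties lexicographic). Each
#' sequence is compared against every existing centroid (exhaustive search;
#' the equivalent of maxaccepts = maxrejects = 0) and joins the centroid of
#' highest identity when that identity reaches the threshold, otherwise it
#' founds a new OTU. Identity is matching columns over alignment length in
#' an end-gap-free global alignment. Equally similar centroids resolve to
#' the earlier-founded (more abundant) one. OTU ids rank OTUs by decreasing
#' total reads.
#'
#' @param derep an [dereplicate()] result.
#' @param identity_threshold clustering threshold (default 0.97).
#' @return object of class \code{its2_otus}: list with \code{otus}
#'   (data.table: otu_id, centroid, total_reads, has_clone_member),
#'   \code{members} (data.table: otu_id, seq_id, sequence, identity,
#'   abundance) and \code{sample_counts} (data.table: otu_id, sample,
#'   count).
#' @export
cluster_otus <- function(derep, identity_threshold = 0.97) {
  dd <- derep$derep
  empty <- list(
    otus = data.table::data.table(otu_id = character(0),
                                  centroid = character(0),
                                  total_reads = integer(0),
                                  has_clone_member = logical(0)),
    members = data.table::data.table(otu_id = character(0),
                                     seq_id = integer(0),
                                     sequence = character(0),
                                     identity = numeric(0),
                                     abundance = integer(0)),
    sample_counts = data.table::data.table(otu_id = character(0),
                                           sample = character(0),
                                           count = integer(0)))
  if (nrow(dd) == 0L) return(structure(empty, class = "its2_otus"))
  centroids <- character(0)
  assign_to <- integer(nrow(dd))
  identity <- numeric(nrow(dd))
  for (i in seq_len(nrow(dd))) {
    ids <- identity_to_set(dd$sequence[i], centroids)
    j <- if (length(ids) > 0) which.max(ids) else NA_integer_
    if (!is.na(j) && ids[j] >= identity_threshold) {
      assign_to[i] <- j
      identity[i] <- ids[j]
    } else {
      centroids <- c(centroids, dd$sequence[i])
      assign_to[i] <- length(centroids)
      identity[i] <- 1
    }
  }
  members <- data.table::data.table(
    cluster = assign_to, seq_id = dd$seq_id, sequence = dd$sequence,
    identity = identity, abundance = dd$abundance)
  totals <- members[, .(total_reads = sum(abundance)), by = cluster]
  data.table::setorder(totals, -total_reads, cluster)
  totals[, otu_id := sprintf("OTU_%04d", seq_len(.N))]
  members[, otu_id := totals$otu_id[match(cluster, totals$cluster)]]
  sc <- merge(derep$sample_counts,
              members[, .(seq_id, otu_id)], by = "seq_id")
  sample_counts <- sc[, .(count = sum(count)), by = .(otu_id, sample)]
  otus <- totals[, .(otu_id,
                     centroid = centroids[cluster],
                     total_reads,
                     has_clone_member = FALSE)]
  structure(list(otus = otus,
                 members = members[, .(otu_id, seq_id, sequence, identity,
                                       abundance)],
                 sample_counts = sample_counts),
            class = "its2_otus")
}

#' @export
print.its2_otus <- function(x, ...) {
  cat("its2_otus:", nrow(x$otus), "OTUs,", sum(x$otus$total_reads),
      "reads\n")
  invisible(x)
}

#' Remove OTUs below the relative-abundance floor
#'
#' An OTU is kept iff its total reads reach \code{floor_fraction} of the
#' initial (raw, pre-filtering) read count. Removed reads are logged, not
#' reassigned.
#'
#' @param otus an [cluster_otus()] result.
#' @param initial_read_total raw read count of the run.
#' @param floor_fraction default 0.00005 (0.005\%).
#' @return list(otus = filtered its2_otus, removed = data.table of dropped
#'   OTUs).
#' @export
filter_low_abundance <- function(otus, initial_read_total,
                                 floor_fraction = 5e-5) {
  assert_that(floor_fraction >= 0 && floor_fraction <= 1,
              "floor_fraction must be in [0, 1]")
  floor_reads <- floor_fraction * initial_read_total
  keep <- otus$otus$total_reads >= floor_reads
  kept_ids <- otus$otus$otu_id[keep]
  res <- structure(list(
    otus = otus$otus[keep],
    members = otus$members[otu_id %in% kept_ids],
    sample_counts = otus$sample_counts[otu_id %in% kept_ids]),
    class = "its2_otus")
  list(otus = res, removed = otus$otus[!keep],
       floor_reads = floor_reads)
}

#' Co-cluster clone-library sequences with existing OTUs
#'
#' Each ITS2-trimmed clone sequence is assigned to the centroid of highest
#' identity when that identity reaches the threshold; such OTUs become
#' "mixed" (\code{has_clone_member}). Clones matching no centroid are
#' clustered greedily among themselves into clone-only clusters. OTU read
#' counts never change (clones carry no abundance).
#'
#' @param otus an [cluster_otus()] result.
#' @param clones named character vector of ITS2-trimmed clone sequences.
#' @param identity_threshold default 0.97.
#' @return list(otus = updated its2_otus, assignments = data.table
#'   (clone_id, otu_id, identity), clone_clusters = data.table (cluster_id,
#'   clone_id, centroid_clone)).
#' @export
cocluster_clones <- function(otus, clones, identity_threshold = 0.97) {
  assignments <- data.table::data.table(
    clone_id = character(0), otu_id = character(0), identity = numeric(0))
  clone_clusters <- data.table::data.table(
    cluster_id = character(0), clone_id = character(0),
    centroid_clone = character(0))
  upd <- structure(list(otus = data.table::copy(otus$otus),
                        members = otus$members,
                        sample_counts = otus$sample_counts),
                   class = "its2_otus")
  if (length(clones) == 0L) {
    return(list(otus = upd, assignments = assignments,
                clone_clusters = clone_clusters))
  }
  if (is.null(names(clones))) {
    names(clones) <- sprintf("clone_%03d", seq_along(clones))
  }
  cents <- upd$otus$centroid
  unassigned <- character(0)
  for (ci in seq_along(clones)) {
    ids <- identity_to_set(clones[[ci]], cents)
    j <- if (length(ids) > 0) which.max(ids) else NA_integer_
    if (!is.na(j) && ids[j] >= identity_threshold) {
      assignments <- data.table::rbindlist(list(
        assignments,
        data.table::data.table(clone_id = names(clones)[ci],
                               otu_id = upd$otus$otu_id[j],
                               identity = ids[j])))
      upd$otus$has_clone_member[j] <- TRUE
    } else {
      unassigned <- c(unassigned, names(clones)[ci])
    }
  }
  if (length(unassigned) > 0) {
    ccent <- character(0); cids <- character(0)
    rows <- list()
    for (cid in unassigned) {
      ids <- identity_to_set(clones[[cid]], ccent)
      j <- if (length(ids) > 0) which.max(ids) else NA_integer_
      if (!is.na(j) && ids[j] >= identity_threshold) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          cluster_id = cids[j], clone_id = cid, centroid_clone = cids[j])
      } else {
        ccent <- c(ccent, clones[[cid]])
        cids <- c(cids, cid)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          cluster_id = cid, clone_id = cid, centroid_clone = cid)
      }
    }
    clone_clusters <- data.table::rbindlist(rows)
  }
  list(otus = upd, assignments = assignments,
       clone_clusters = clone_clusters)
}
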