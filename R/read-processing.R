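# Paired-end read processing: primer screening and pool splitting,
# quality-aware ungapped merging, expected-error filtering, dereplication.

#' Screen primers and split read pairs into amplicon pools
#'
#' Each pair is tested against every primer system: the forward mate must
#' start with the system's forward primer and the reverse mate with the
#' reverse primer, each within \code{max_primer_mismatch} substitutions.
#' Pairs matching with swapped mates are re-oriented 5'->3'. Retained reads
#' have their primers stripped; everything else is discarded with a reason.
#'
#' @param pairs data.table with columns id, sample, fwd, rev, fwd_qual,
#'   rev_qual (as produced by [simulate_reads()] or [read_fastq_pair()]).
#' @param primers data.table with columns group, fwd, rev; see
#'   [primer_table()].
#' @param max_primer_mismatch maximum substitutions tolerated per primer.
#' @return list with \code{pools} (named list of data.tables, primers
#'   stripped), \code{discarded} (data.table with a reason column) and
#'   \code{log} (per-sample counts).
#' @export
screen_and_split <- function(pairs, primers, max_primer_mismatch = 1L) {
  assert_that(nrow(primers) > 0, "primer table is empty")
  n <- nrow(pairs)
  assigned <- rep(NA_character_, n)
  swapped <- rep(FALSE, n)
  nhits <- integer(n)
  for (g in seq_len(nrow(primers))) {
    fp <- primers$fwd[g]; rp <- primers$rev[g]
    ok_fw <- prefix_mismatch(pairs$fwd, fp) <= max_primer_mismatch &
      prefix_mismatch(pairs$rev, rp) <= max_primer_mismatch
    ok_sw <- prefix_mismatch(pairs$rev, fp) <= max_primer_mismatch &
      prefix_mismatch(pairs$fwd, rp) <= max_primer_mismatch
    hit <- ok_fw | ok_sw
    assigned[hit] <- primers$group[g]
    swapped[ok_sw & !ok_fw] <- TRUE
    nhits <- nhits + hit
  }
  assigned[nhits > 1L] <- NA_character_  # ambiguous across systems
  pools <- list()
  for (g in primers$group) {
    sel <- which(!is.na(assigned) & assigned == g)
    if (length(sel) == 0L) {
      pools[[g]] <- pairs[0L]
      next
    }
    sub <- pairs[sel]
    sw <- swapped[sel]
    if (any(sw)) {
      tmp <- sub$fwd[sw]; sub$fwd[sw] <- sub$rev[sw]; sub$rev[sw] <- tmp
      tmp <- sub$fwd_qual[sw]
      sub$fwd_qual[sw] <- sub$rev_qual[sw]; sub$rev_qual[sw] <- tmp
    }
    kf <- nchar(primers$fwd[primers$group == g])
    kr <- nchar(primers$rev[primers$group == g])
    sub[, `:=`(fwd = substr(fwd, kf + 1L, nchar(fwd)),
               rev = substr(rev, kr + 1L, nchar(rev)),
               fwd_qual = substr(fwd_qual, kf + 1L, nchar(fwd_qual)),
               rev_qual = substr(rev_qual, kr + 1L, nchar(rev_qual)))]
    pools[[g]] <- sub
  }
  disc <- pairs[is.na(assigned)]
  disc[, reason := ifelse(nhits[is.na(assigned)] > 1L,
                          "ambiguous_primer", "primer_mismatch")]
  log <- pairs[, .(input = .N), by = sample]
  kept <- data.table::rbindlist(
    lapply(names(pools), function(g) {
      if (nrow(pools[[g]]) == 0) return(NULL)
      pools[[g]][, .(n = .N, pool = g), by = sample]
    }))
  list(pools = pools, discarded = disc,
       log = list(per_sample = log, per_pool = kept))
}

#' Merge one read pair by best ungapped overlap
#'
#' All overlap offsets between \code{min_overlap} and the shorter mate's
#' length are scanned; the offset with the most matching bases wins (ties go
#' to the longer overlap), provided its mismatch fraction does not exceed
#' \code{max_overlap_mismatch_frac}. At overlap mismatches the base with the
#' higher Phred score is kept together with its quality; at matches the
#' higher of the two qualities is kept. Returns NULL when no admissible
#' overlap exists.
#'
#' @param fwd,rev mate sequences (rev as sequenced, i.e. reverse-complement
#'   of the template tail).
#' @param fwd_qual,rev_qual quality strings.
#' @param min_overlap smallest admissible overlap (bp).
#' @param max_overlap_mismatch_frac maximum mismatch fraction in the overlap.
#' @return list(sequence, qual, overlap) or NULL on rejection.
#' @export
merge_pairs <- function(fwd, rev, fwd_qual, rev_qual,
                        min_overlap = 10L, max_overlap_mismatch_frac = 0.1) {
  f <- utf8ToInt(fwd)
  r <- utf8ToInt(revcomp(rev))
  fq <- phred_scores(fwd_qual)
  rq <- base::rev(phred_scores(rev_qual))
  nf <- length(f); nr <- length(r)
  omax <- min(nf, nr)
  if (omax < min_overlap) return(NULL)
  best_o <- NA_integer_; best_m <- -1L
  for (o in min_overlap:omax) {
    m <- sum(f[(nf - o + 1L):nf] == r[1:o])
    if ((o - m) / o <= max_overlap_mismatch_frac &&
        (m > best_m || (m == best_m && !is.na(best_o) && o > best_o))) {
      best_m <- m; best_o <- o
    }
  }
  if (is.na(best_o)) return(NULL)
  o <- best_o
  fi <- (nf - o + 1L):nf; ri <- 1:o
  ov_seq <- f[fi]; ov_q <- pmax(fq[fi], rq[ri])
  take_r <- f[fi] != r[ri] & rq[ri] > fq[fi]
  ov_seq[take_r] <- r[ri][take_r]
  ov_q[take_r] <- rq[ri][take_r]
  merged <- c(f[seq_len(nf - o)], ov_seq, r[seq_len(nr - o) + o])
  qual <- c(fq[seq_len(nf - o)], ov_q, rq[seq_len(nr - o) + o])
  list(sequence = intToUtf8(merged),
       qual = phredv_string(qual),
       overlap = o)
}

phredv_string <- function(q) intToUtf8(q + 33L)

#' Merge a pool of read pairs
#'
#' Batch wrapper around [merge_pairs()]. Identical (fwd, rev, quality)
#' tuples are merged once and the result reused, which makes low-error runs
#' fast without changing any per-read outcome.
#'
#' @param pool data.table with id, sample, fwd, rev, fwd_qual, rev_qual.
#' @inheritParams merge_pairs
#' @return list with \code{merged} (data.table: id, sample, sequence, qual)
#'   and \code{rejected} (data.table of unmergeable pairs).
#' @export
merge_pool <- function(pool, min_overlap = 10L,
                       max_overlap_mismatch_frac = 0.1) {
  if (nrow(pool) == 0L) {
    return(list(merged = data.table::data.table(
      id = character(0), sample = character(0),
      sequence = character(0), qual = character(0)),
      rejected = pool))
  }
  key <- paste(pool$fwd, pool$rev, pool$fwd_qual, pool$rev_qual, sep = "\r")
  uk <- unique(key)
  ui <- match(uk, key)
  res <- lapply(ui, function(i) {
    merge_pairs(pool$fwd[i], pool$rev[i], pool$fwd_qual[i], pool$rev_qual[i],
                min_overlap, max_overlap_mismatch_frac)
  })
  idx <- match(key, uk)
  ok <- !vapply(res, is.null, logical(1))[idx]
  merged <- data.table::data.table(
    id = pool$id[ok], sample = pool$sample[ok],
    sequence = vapply(res[idx[ok]], `[[`, character(1), "sequence"),
    qual = vapply(res[idx[ok]], `[[`, character(1), "qual"))
  list(merged = merged, rejected = pool[!ok])
}

#' Expected-error quality filter
#'
#' Keeps a merged read iff its length strictly exceeds \code{min_len} and
#' its expected number of errors (sum of per-base error probabilities) is
#' strictly below \code{max_ee}.
#'
#' @param sequence,qual character vectors (parallel).
#' @param min_len minimum length (exclusive), default 200 bp.
#' @param max_ee maximum expected errors (exclusive), default 1.0.
#' @return logical keep vector.
#' @export
quality_filter <- function(sequence, qual, min_len = 200L, max_ee = 1.0) {
  nchar(sequence) > min_len & expected_errors(qual) < max_ee
}

#' Dereplicate identical sequences
#'
#' Groups exact duplicate strings, sums their abundances, and tracks
#' per-sample counts. Output is sorted by decreasing abundance with ties
#' broken lexicographically by sequence.
#'
#' @param sequence character vector of sequences.
#' @param sample parallel sample labels.
#' @param weight parallel copy counts (default 1 per entry).
#' @param ids optional read ids to record as members.
#' @return object of class \code{its2_derep}: list with \code{derep}
#'   (data.table: seq_id, sequence, abundance), \code{sample_counts}
#'   (data.table: seq_id, sample, count) and optional \code{member_ids}.
#' @export
dereplicate <- function(sequence, sample = rep("S1", length(sequence)),
                        weight = rep(1L, length(sequence)), ids = NULL) {
  dt <- data.table::data.table(sequence = sequence, sample = sample,
                               weight = as.integer(weight))
  ab <- dt[, .(abundance = sum(weight)), by = sequence]
  data.table::setorder(ab, -abundance, sequence)
  ab[, seq_id := seq_len(.N)]
  sc <- dt[, .(count = sum(weight)), by = .(sequence, sample)]
  sc[, seq_id := ab$seq_id[match(sequence, ab$sequence)]]
  out <- list(derep = ab[, .(seq_id, sequence, abundance)],
              sample_counts = sc[, .(seq_id, sample, count)])
  if (!is.null(ids)) {
    m <- data.table::data.table(
      seq_id = ab$seq_id[match(sequence, ab$sequence)], id = ids)
    out$member_ids <- split(m$id, m$seq_id)
  }
  structure(out, class = "its2_derep")
}

#' Write dereplicated sequences as FASTA with size annotations
#'
#' Headers follow the \code{;size=N} dialect of common amplicon tools.
#'
#' @param derep an [dereplicate()] result.
#' @param path output FASTA path.
#' @export
write_derep_fasta <- function(derep, path) {
  dd <- derep$derep
  writeLines(as.vector(rbind(
    sprintf(">seq%06d;size=%d", dd$seq_id, dd$abundance), dd$sequence)),
    path)
  invisible(path)
}

#' @export
print.its2_derep <- function(x, ...) {
  cat("its2_derep:", nrow(x$derep), "unique sequences,",
      sum(x$derep$abundance), "reads\n")
  invisible(x)
}
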