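# Pairwise alignment layer. Local (Smith-Waterman, blastn default scoring)
# alignments produce BLAST-outfmt-6-compatible hit tables against the
# synthetic reference database; end-gap-free global ("overlap") alignments
# supply the identity used by OTU clustering and the match profiles used by
# chimera detection. The dynamic programming lives in compiled code
# (src/alignment.cpp); its affine gap model (a gap of length k costs
# open + k * extend) matches BLAST's convention.

#' @useDynLib its2pipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default blastn-like scoring parameters
#'
#' Match reward +2, mismatch penalty -3, gap open 5, gap extend 2, with the
#' gapped Karlin-Altschul parameters lambda = 0.625 and K = 0.41 used to
#' convert raw scores into bit scores.
#' @export
blast_scoring <- function() {
  list(reward = 2, penalty = -3, gap_open = 5, gap_extend = 2,
       lambda = 0.625, K = 0.41)
}

# Bit score from a raw alignment score: S' = (lambda * S - ln K) / ln 2.
bit_score <- function(raw, scoring = blast_scoring()) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

#' Normalize a bit score by the reference sequence length
#'
#' NB = S' / subject_length. The ceiling under default blastn scoring for a
#' full-length perfect match is about 1.81; NB is the similarity currency of
#' the whole taxonomy stage.
#'
#' @param bit_score bit score(s) S'.
#' @param subject_length reference (subject) length(s), bp.
#' @return numeric NB value(s).
#' @export
normalize_bitscore <- function(bit_score, subject_length) {
  assert_that(all(subject_length > 0), "subject_length must be positive")
  bit_score / subject_length
}

#' Local alignment producing one BLAST-style hit record
#'
#' Smith-Waterman alignment under blastn default scoring; the raw score is
#' converted to a bit score via the gapped Karlin-Altschul parameters, and
#' the E value via E = m * n * 2^-S'. Hits with non-positive raw score or E
#' value above \code{max_evalue} are reported as NULL (below the reporting
#' floor).
#'
#' @param query,reference nucleotide strings.
#' @param scoring list as returned by [blast_scoring()].
#' @param max_evalue reporting floor (default 10, the blastn default).
#' @return one-row data.table with qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore slen qcovs stitle (ids
#'   and title left NA for the caller to fill), or NULL.
#' @export
align_local <- function(query, reference, scoring = blast_scoring(),
                        max_evalue = 10) {
  assert_that(nchar(query) > 0 && nchar(reference) > 0,
              "sequences must be non-empty")
  r <- .cpp_align_pair(query, reference, scoring$reward, scoring$penalty,
                       scoring$gap_open, scoring$gap_extend, TRUE, FALSE)
  if (r$score <= 0) return(NULL)
  bs <- bit_score(r$score, scoring)
  ev <- nchar(query) * nchar(reference) * 2^(-bs)
  if (ev > max_evalue) return(NULL)
  data.table::data.table(
    qseqid = NA_character_, sseqid = NA_character_,
    pident = 100 * r$matches / r$alen, length = r$alen,
    mismatch = r$mismatches, gapopen = r$gapopens,
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
    evalue = ev, bitscore = bs, slen = nchar(reference),
    qcovs = 100 * (r$qend - r$qstart + 1L) / nchar(query),
    stitle = NA_character_)
}

#' Clustering identity between two sequences
#'
#' Matching columns divided by alignment length in a global alignment with
#' free terminal gaps ("overlap" alignment), the identity definition used by
#' the greedy centroid clusterer.
#'
#' @param a,b nucleotide strings.
#' @param scoring alignment scoring, [blast_scoring()] by default.
#' @return identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b, scoring = blast_scoring()) {
  identity_to_set(a, b, scoring)
}

#' Identity of one query against a set of sequences
#'
#' Overlap alignment of \code{query} against every element of \code{set} in
#' compiled code; one call per query keeps the greedy clusterer fast.
#'
#' @param query nucleotide string.
#' @param set character vector of sequences.
#' @param scoring alignment scoring.
#' @return numeric vector of identity fractions.
#' @export
identity_to_set <- function(query, set, scoring = blast_scoring()) {
  if (length(set) == 0L) return(numeric(0))
  .cpp_identity_to_set(query, set, scoring$reward, scoring$penalty,
                       scoring$gap_open, scoring$gap_extend)
}

# Per-position match profiles of `candidate` against each parent: logical
# matrix (parents x nchar(candidate)); TRUE where the aligned parent base
# equals the candidate base. Used by the chimera crossover model.
match_profiles <- function(candidate, parents, scoring = blast_scoring()) {
  .cpp_match_profiles(candidate, parents, scoring$reward, scoring$penalty,
                      scoring$gap_open, scoring$gap_extend)
}

#' Search queries against a reference database, producing a hit table
#'
#' Emulates a blastn run against the synthetic reference set: every query is
#' locally aligned to every ITS2-trimmed reference, hits below the reporting
#' floor are dropped, and the best \code{n_recorded} hits per query (by bit
#' score) are recorded in a 15-column outfmt-6-style table, joined with the
#' reference lineage. Records carrying a \code{mislabeled_as} label expose
#' that label instead of their lineage, as mislabeled database entries do.
#'
#' The subject sequences are the ITS2 cores of the reference records (the
#' trimmed region is what the hit table normalizes against), so
#' \code{slen} is the core length.
#'
#' @param queries named character vector of query sequences (names become
#'   qseqid).
#' @param refdb [build_reference_db()] result.
#' @param n_recorded hits recorded per query (default 50).
#' @param scoring,max_evalue see [align_local()].
#' @return data.table of hits with lineage columns class, order, genus,
#'   species, genotype (NA for mislabeled subjects) plus nb, sorted by
#'   query and decreasing bit score.
#' @export
blast_search <- function(queries, refdb, n_recorded = 50L,
                         scoring = blast_scoring(), max_evalue = 10) {
  refs <- refdb$records
  out <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    # cheap vectorised score pass first, full stats only for recordable hits
    raw <- .cpp_score_to_set(queries[[qi]], refs$core, scoring$reward,
                             scoring$penalty, scoring$gap_open,
                             scoring$gap_extend, TRUE)
    bs <- bit_score(raw, scoring)
    ev <- nchar(queries[[qi]]) * nchar(refs$core) * 2^(-bs)
    cand <- which(raw > 0 & ev <= max_evalue)
    if (length(cand) == 0L) next
    cand <- cand[order(-bs[cand], refs$id[cand])]
    cand <- utils::head(cand, n_recorded)
    hits <- lapply(cand, function(ri) {
      h <- align_local(queries[[qi]], refs$core[ri], scoring, max_evalue)
      h[, `:=`(qseqid = names(queries)[qi], sseqid = refs$id[ri],
               stitle = ifelse(is.na(refs$mislabeled_as[ri]),
                               paste(refs$genus[ri], refs$species[ri],
                                     refs$genotype[ri]),
                               refs$mislabeled_as[ri]))]
      h
    })
    ht <- data.table::rbindlist(hits)
    data.table::setorder(ht, -bitscore, sseqid)
    out[[qi]] <- ht
  }
  ht <- data.table::rbindlist(out)
  if (nrow(ht) == 0L) return(ht)
  tax <- refdb$taxonomy
  lin <- tax[match(ht$sseqid, tax$id)]
  mis <- !is.na(lin$mislabeled_as)
  for (col in c("class", "order", "genus", "species", "genotype")) {
    v <- lin[[col]]
    v[mis] <- NA_character_
    ht[, (col) := v]
  }
  ht[, nb := normalize_bitscore(bitscore, slen)]
  ht[]
}

#' Read or write a BLAST tabular hit table (15 columns + lineage)
#'
#' @param path TSV path.
#' @return data.table of hits.
#' @export
read_hit_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
}

#' @rdname read_hit_table
#' @param hits data.table as produced by [blast_search()].
#' @export
write_hit_table <- function(hits, path) {
  write_tsv(hits, path)
  invisible(path)
}
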