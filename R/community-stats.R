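# Community summaries: per-class OTU composition, alpha diversity,
# rarefaction, Kruskal-Wallis group tests, per-genus NB box statistics and
# top-N abundance matrices.

#' OTU-by-sample count matrix from clustering results
#'
#' @param sample_counts data.table: otu_id, sample, count.
#' @return integer matrix, OTUs in rows, samples in columns.
#' @export
otu_matrix <- function(sample_counts) {
  otus <- sort(unique(sample_counts$otu_id))
  samples <- sort(unique(sample_counts$sample))
  m <- matrix(0L, length(otus), length(samples),
              dimnames = list(otus, samples))
  m[cbind(match(sample_counts$otu_id, otus),
          match(sample_counts$sample, samples))] <- sample_counts$count
  m
}

#' Per-sample class composition of OTU counts
#'
#' Counts distinct OTUs with nonzero reads per taxonomic class in every
#' sample and pooled (union over samples). Percentages are computed on the
#' algal total (OTUs assigned to a target class); non-algal/unassigned OTUs
#' are tallied separately.
#'
#' @param calls taxonomy calls (need otu_id, class, target).
#' @param counts OTU-by-sample matrix from [otu_matrix()].
#' @param target_classes class labels considered algal.
#' @return data.table with one row per sample plus a "pooled" row: sample,
#'   one column per class, algal_total, nonalgal_total, pct_<class>.
#' @export
class_composition <- function(calls, counts,
                              target_classes = TARGET_CLASSES) {
  cls <- calls$class[match(rownames(counts), calls$otu_id)]
  cls[is.na(cls) | !(cls %in% target_classes)] <- "nonalgal"
  one_row <- function(present, label) {
    tab <- table(factor(cls[present], levels = c(target_classes, "nonalgal")))
    algal <- sum(tab[target_classes])
    row <- data.table::as.data.table(as.list(tab))
    row[, `:=`(sample = label, algal_total = algal,
               nonalgal_total = as.integer(tab[["nonalgal"]]))]
    for (tc in target_classes) {
      row[[paste0("pct_", tc)]] <- pct(tab[[tc]], algal)
    }
    row
  }
  rows <- lapply(colnames(counts), function(s) one_row(counts[, s] > 0, s))
  rows[[length(rows) + 1L]] <- one_row(rowSums(counts) > 0, "pooled")
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, "sample")
  out[]
}

#' Alpha diversity indices
#'
#' Observed richness, Shannon entropy (natural log) and inverse Simpson for
#' one vector of counts; empty samples report NA.
#'
#' @param counts non-negative integer vector.
#' @return named numeric vector: observed, shannon, invsimpson.
#' @export
alpha_diversity <- function(counts) {
  assert_that(all(counts >= 0), "counts must be non-negative")
  total <- sum(counts)
  if (total == 0) {
    return(c(observed = NA_real_, shannon = NA_real_,
             invsimpson = NA_real_))
  }
  p <- counts[counts > 0] / total
  c(observed = sum(counts > 0),
    shannon = -sum(p * log(p)),
    invsimpson = 1 / sum(p^2))
}

#' Alpha diversity per sample
#'
#' @param counts OTU-by-sample matrix.
#' @return data.table: sample, observed, shannon, invsimpson.
#' @export
alpha_diversity_table <- function(counts) {
  res <- t(apply(counts, 2, alpha_diversity))
  data.table::data.table(sample = rownames(res),
                         observed = res[, "observed"],
                         shannon = res[, "shannon"],
                         invsimpson = res[, "invsimpson"])
}

#' Rarefaction curve by repeated subsampling without replacement
#'
#' Mean observed richness over \code{n_reps} random subsamples at each
#' depth. At depth equal to the sample total the curve equals the full
#' richness exactly.
#'
#' @param counts non-negative integer vector for one sample.
#' @param depths subsampling depths (each <= sum(counts)).
#' @param n_reps subsamples per depth (default 100).
#' @param seed integer seed.
#' @return data.table: depth, mean_observed, sd_observed.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 100L, seed = 1L) {
  total <- sum(counts)
  assert_that(all(depths <= total), "depth exceeds sample total")
  assert_that(all(depths >= 1), "depths must be >= 1")
  set.seed(seed)
  pool <- rep.int(seq_along(counts), counts)
  rows <- lapply(depths, function(d) {
    if (d == total) {
      obs <- rep(sum(counts > 0), n_reps)
    } else {
      obs <- vapply(seq_len(n_reps), function(r) {
        length(unique(pool[sample.int(total, d)]))
      }, numeric(1))
    }
    data.table::data.table(depth = d, mean_observed = mean(obs),
                           sd_observed = stats::sd(obs))
  })
  data.table::rbindlist(rows)
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-rank H statistic with tie correction; p value from the chi-square
#' approximation with k - 1 degrees of freedom. All-identical values give
#' H = 0, p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   non-empty).
#' @return list(H, df, p_value).
#' @export
kruskal_wallis <- function(groups) {
  assert_that(length(groups) >= 2, "need at least two groups")
  assert_that(all(lengths(groups) >= 1), "each group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) H <- H / tie_corr else H <- 0
  df <- length(groups) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  list(H = H, df = df, p_value = p)
}

#' Per-genus NB box statistics
#'
#' Quartiles by linear interpolation (quantile type 7); whiskers extend to
#' the most extreme values within 1.5 IQR of the quartiles; values beyond
#' are listed as outliers. Single-OTU sets report the median only.
#'
#' @param calls taxonomy calls with columns best_nb and a grouping label
#'   (genus by default: the label for genus-or-better calls, the
#'   "unidentified ..." group label otherwise).
#' @param group_col column to group by (default "label_group").
#' @return data.table: group, n_otus, median, q1, q3, whisker_low,
#'   whisker_high, outliers (list), has_mixed.
#' @export
genus_nb_boxstats <- function(calls, group_col = "label_group") {
  assert_that(group_col %in% names(calls),
              paste("missing column", group_col))
  dt <- data.table::copy(calls[!is.na(best_nb)])
  if (!"has_clone_member" %in% names(dt)) dt[, has_clone_member := FALSE]
  dt[, .grp := dt[[group_col]]]
  out <- dt[, {
    v <- sort(best_nb)
    n <- length(v)
    med <- stats::median(v)
    if (n == 1L) {
      list(n_otus = 1L, median = med, q1 = NA_real_, q3 = NA_real_,
           whisker_low = NA_real_, whisker_high = NA_real_,
           outliers = list(numeric(0)),
           has_mixed = any(isTRUE_vec(has_clone_member)))
    } else {
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[2] + 1.5 * iqr
      inside <- v[v >= lo_fence & v <= hi_fence]
      list(n_otus = n, median = med, q1 = q[1], q3 = q[2],
           whisker_low = min(inside), whisker_high = max(inside),
           outliers = list(v[v < lo_fence | v > hi_fence]),
           has_mixed = any(isTRUE_vec(has_clone_member)))
    }
  }, by = .grp]
  data.table::setnames(out, ".grp", "group")
  out[]
}

#' Top-N abundance matrix per class
#'
#' For each taxonomic class, selects the \code{n} OTUs with the highest
#' total reads (ties broken by OTU id) and returns their counts across all
#' samples, annotated with whether each OTU occurs at every group-A site and
#' at every site.
#'
#' @param counts OTU-by-sample matrix.
#' @param calls taxonomy calls (otu_id, class).
#' @param group_map data.table: sample, group.
#' @param n OTUs per class (default 20).
#' @return data.table: class, otu_id, total_reads, one column per sample,
#'   in_all_groupA_sites, in_all_sites.
#' @export
top_n_matrix <- function(counts, calls, group_map, n = 20L) {
  assert_that(n >= 1, "n must be >= 1")
  totals <- rowSums(counts)
  cls <- calls$class[match(rownames(counts), calls$otu_id)]
  gA <- group_map$sample[startsWith(group_map$group, "groupA")]
  gA <- intersect(gA, colnames(counts))
  rows <- list()
  for (cc in sort(unique(cls[!is.na(cls)]))) {
    ids <- rownames(counts)[!is.na(cls) & cls == cc]
    ids <- ids[order(-totals[ids], ids)]
    ids <- utils::head(ids, n)
    sub <- counts[ids, , drop = FALSE]
    dt <- data.table::data.table(class = cc, otu_id = ids,
                                 total_reads = unname(totals[ids]))
    for (s in colnames(counts)) data.table::set(dt, j = s,
                                                value = unname(sub[, s]))
    data.table::set(dt, j = "in_all_groupA_sites",
                    value = apply(sub[, gA, drop = FALSE] > 0, 1, all))
    data.table::set(dt, j = "in_all_sites", value = apply(sub > 0, 1, all))
    rows[[length(rows) + 1L]] <- dt
  }
  data.table::rbindlist(rows)
}
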