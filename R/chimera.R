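# De novo chimera flagging on dereplicated sequences: a candidate is
# chimeric when a single crossover between two sufficiently more abundant
# parents explains it clearly better than any single parent does.

#' Flag chimeric sequences de novo
#'
#' For each dereplicated sequence (candidates are visited in decreasing
#' abundance order), all sequences at least \code{min_parent_fold} times
#' more abundant are considered potential parents (capped at the
#' \code{k_top_parents} most abundant). For every parent pair (A, B) a
#' single-crossover model is scanned exhaustively over breakpoints: the
#' model's identity to the candidate is the best achievable fraction of
#' candidate positions matched by A up to the breakpoint and by B after it.
#' The candidate is flagged iff some model's identity exceeds the best
#' single-parent identity by at least \code{min_improvement}. Flags only;
#' removal is a separate decision.
#'
#' @param derep an [dereplicate()] result (sorted by decreasing abundance).
#' @param min_parent_fold minimum parent/candidate abundance ratio
#'   (default 2).
#' @param min_improvement minimum identity-gain of the crossover model over
#'   the best single parent (default 0.02).
#' @param k_top_parents parents examined per candidate (default 20).
#' @param min_model_identity minimum identity of the crossover model itself
#'   (default 0.99): a true PCR chimera is its crossover model up to
#'   sequencing error, so models that explain the candidate only partially
#'   are rejected. This guards against false positives among genuine
#'   relatives whose substitution patterns happen to be separable by a
#'   breakpoint.
#' @return data.table: seq_id, is_chimera, best_parents, best_single_identity,
#'   best_model_identity.
#' @export
detect_chimeras_denovo <- function(derep, min_parent_fold = 2,
                                   min_improvement = 0.02,
                                   k_top_parents = 20L,
                                   min_model_identity = 0.99) {
  dd <- derep$derep
  n <- nrow(dd)
  out <- data.table::data.table(
    seq_id = dd$seq_id, is_chimera = FALSE, best_parents = NA_character_,
    best_single_identity = NA_real_, best_model_identity = NA_real_)
  if (n < 3L) return(out)
  for (i in seq_len(n)) {
    cand <- dd$sequence[i]
    L <- nchar(cand)
    par_idx <- which(dd$abundance >= min_parent_fold * dd$abundance[i] &
                       seq_len(n) != i)
    if (length(par_idx) < 2L) next
    par_idx <- utils::head(par_idx, k_top_parents)
    profs_m <- match_profiles(cand, dd$sequence[par_idx])
    profs <- lapply(seq_along(par_idx), function(k) profs_m[k, ])
    singles <- vapply(profs, function(p) sum(p) / L, numeric(1))
    best_single <- max(singles)
    cums <- lapply(profs, cumsum)
    totals <- vapply(cums, function(cm) cm[L], numeric(1))
    best_model <- -Inf; best_pair <- NA_character_
    for (a in seq_along(par_idx)) {
      for (b in seq_along(par_idx)) {
        if (a == b) next
        # breakpoint k: positions 1..k from parent a, k+1..L from parent b
        model <- max(c(0, cums[[a]][-L]) + totals[b] -
                       c(0, cums[[b]][-L])) / L
        if (model > best_model) {
          best_model <- model
          best_pair <- paste(dd$seq_id[par_idx[a]], dd$seq_id[par_idx[b]],
                             sep = ";")
        }
      }
    }
    out$best_single_identity[i] <- best_single
    out$best_model_identity[i] <- best_model
    if (is.finite(best_model) &&
        best_model >= min_model_identity &&
        best_model - best_single >= min_improvement) {
      out$is_chimera[i] <- TRUE
      out$best_parents[i] <- best_pair
    }
  }
  out
}
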