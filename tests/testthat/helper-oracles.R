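# Independent reference implementations used as oracles. These deliberately
# re-derive results from first principles (textbook dynamic programming,
# naive enumeration) and share no code with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# Affine-gap alignment score by row-wise dynamic programming.
# local = TRUE: Smith-Waterman best-cell score.
# local = FALSE: ends-free global (free terminal gaps), best over last
# row/column across all three states.
oracle_align_score <- function(q, s, reward = 2, penalty = -3,
                               gap_open = 5, gap_ext = 2, local = TRUE) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  m <- length(qv); n <- length(sv)
  open <- gap_open + gap_ext
  NEG <- -1e30
  Mp <- rep(0, n + 1)           # M[i-1, ], boundary row = 0 (free start)
  Xp <- rep(NEG, n + 1)
  Yp <- rep(NEG, n + 1)
  best <- if (local) 0 else NEG
  lastcol <- c(M = NEG, X = NEG, Y = NEG)
  Mrow <- Xrow <- Yrow <- NULL
  for (i in 1:m) {
    sub <- ifelse(qv[i] == sv, reward, penalty)
    prev_best <- pmax(Mp, Xp, Yp)
    if (local) prev_best <- pmax(prev_best, 0)
    Mi <- c(0, sub + prev_best[1:n])       # M[i, 0] = 0 (free start col)
    Xi <- c(NEG, pmax(Mp[-1] - open, Xp[-1] - gap_ext))
    # Y[i, j] = max_{k < j} (M[i, k] - open - gap_ext * (j - 1 - k))
    B <- Mi + gap_ext * (0:n)
    Yi <- c(NEG, cummax(B[1:n]) - open - gap_ext * (0:(n - 1)))
    if (local) best <- max(best, Mi)
    if (!local) {
      best <- max(best, Mi[n + 1], Xi[n + 1], Yi[n + 1])
    }
    Mp <- Mi; Xp <- Xi; Yp <- Yi
  }
  if (!local) best <- max(best, Mp[-1], Xp[-1], Yp[-1])
  best
}

# Exhaustive-offset read merger: enumerate every overlap length, count
# matches with character vectors, apply the mismatch-fraction filter, pick
# max matches (ties: longer overlap), resolve overlap bases by quality.
oracle_merge <- function(fwd, rev, fwd_qual, rev_qual, min_overlap = 10,
                         max_frac = 0.1) {
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rc(rev), "")[[1]]
  fq <- utf8ToInt(fwd_qual) - 33L
  rq <- rev(utf8ToInt(rev_qual) - 33L)
  nf <- length(f); nr <- length(r)
  best <- NULL
  for (o in seq_len(min(nf, nr))) {
    if (o < min_overlap) next
    fi <- f[(nf - o + 1):nf]; ri <- r[1:o]
    mm <- sum(fi != ri)
    if (mm / o > max_frac) next
    matches <- o - mm
    if (is.null(best) || matches > best$matches ||
        (matches == best$matches && o > best$o)) {
      best <- list(o = o, matches = matches)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  fi <- (nf - o + 1):nf; ri <- 1:o
  seq_ov <- f[fi]; q_ov <- pmax(fq[fi], rq[ri])
  swap <- f[fi] != r[ri] & rq[ri] > fq[fi]
  seq_ov[swap] <- r[ri][swap]
  q_ov[swap] <- rq[ri][swap]
  list(sequence = paste(c(f[seq_len(nf - o)], seq_ov, r[-(1:o)]),
                        collapse = ""),
       qual = intToUtf8(c(fq[seq_len(nf - o)], q_ov, rq[-(1:o)]) + 33L),
       overlap = o)
}

# Naive greedy clusterer: same contract as cluster_otus but written as a
# direct loop that recomputes every identity one pair at a time.
oracle_greedy <- function(seqs_sorted, threshold, identity_fun) {
  centroids <- character(0)
  assign <- integer(length(seqs_sorted))
  for (i in seq_along(seqs_sorted)) {
    best_j <- NA; best_id <- -1
    for (j in seq_along(centroids)) {
      id <- identity_fun(seqs_sorted[i], centroids[j])
      if (id > best_id) { best_id <- id; best_j <- j }
    }
    if (!is.na(best_j) && best_id >= threshold) {
      assign[i] <- best_j
    } else {
      centroids <- c(centroids, seqs_sorted[i])
      assign[i] <- length(centroids)
    }
  }
  assign
}

# Brute-force consensus decision: enumerate every rank and label sum
# explicitly over plain data frames.
oracle_consensus <- function(hits, n_consensus = 10, n_recorded = 50,
                             target_classes = its2pipe::TARGET_CLASSES,
                             genotype_threshold = 1.81,
                             species_threshold = 1.75,
                             nb_tolerance = 0.005) {
  hits <- as.data.frame(hits)
  hits <- hits[order(-hits$bitscore, hits$sseqid), ]
  hits <- head(hits, n_recorded)
  is_t <- !is.na(hits$class) & hits$class %in% target_classes
  if (sum(hits$bitscore[is_t]) <= sum(hits$bitscore[!is_t])) {
    nt <- hits[!is_t, ]
    sums <- aggregate(bitscore ~ stitle, nt, sum)
    bests <- aggregate(bitscore ~ stitle, nt, max)
    ord <- order(-sums$bitscore, -bests$bitscore[match(sums$stitle,
                                                       bests$stitle)],
                 sums$stitle)
    return(list(label = sums$stitle[ord[1]], rank = NA_character_,
                target = FALSE))
  }
  top <- head(hits[is_t, ], n_consensus)
  cand <- function(rank) {
    sub <- top[!is.na(top[[rank]]), ]
    if (nrow(sub) == 0) return(NULL)
    labs <- unique(sub[[rank]])
    sums <- sapply(labs, function(l) sum(sub$bitscore[sub[[rank]] == l]))
    bests <- sapply(labs, function(l) max(sub$bitscore[sub[[rank]] == l]))
    ord <- order(-sums, -bests, labs)
    lab <- labs[ord[1]]
    list(label = lab, best_nb = max(sub$nb[sub[[rank]] == lab]))
  }
  g <- cand("genotype")
  if (!is.null(g) && g$best_nb >= genotype_threshold - nb_tolerance) {
    return(list(label = g$label, rank = "genotype", target = TRUE))
  }
  s <- cand("species")
  if (!is.null(s) && s$best_nb >= species_threshold) {
    return(list(label = s$label, rank = "species", target = TRUE))
  }
  ge <- cand("genus")
  if (!is.null(ge)) {
    return(list(label = paste(ge$label, "sp."), rank = "genus",
                target = TRUE))
  }
  o <- cand("order")
  if (!is.null(o)) {
    return(list(label = paste("unidentified", o$label), rank = "order",
                target = TRUE))
  }
  cl <- cand("class")
  if (!is.null(cl)) {
    return(list(label = paste("unidentified", cl$label), rank = "class",
                target = TRUE))
  }
  list(label = "no_hit", rank = NA_character_, target = NA)
}

# Random hit table for consensus fuzzing: a mix of target lineages (drawn
# from a small synthetic taxonomy) and non-target entries.
random_hit_table <- function(n_hits = 30) {
  classes <- its2pipe::TARGET_CLASSES
  rows <- lapply(seq_len(n_hits), function(i) {
    nontarget <- runif(1) < 0.25
    bs <- runif(1, 50, 450)
    slen <- sample(174:295, 1)
    if (nontarget) {
      data.frame(qseqid = "Q1", sseqid = sprintf("S%03d", i),
                 bitscore = bs, slen = slen, nb = bs / slen,
                 stitle = sample(c("uncultured fungus clone",
                                   "uncultured eukaryote"), 1),
                 class = NA_character_, order = NA_character_,
                 genus = NA_character_, species = NA_character_,
                 genotype = NA_character_)
    } else {
      cl <- sample(classes, 1)
      gen <- paste0(substr(cl, 1, 4), "_gen", sample(1:3, 1))
      sp <- paste0(gen, "_sp", sample(1:2, 1))
      gt <- paste0(sp, "_gt", sample(1:2, 1))
      data.frame(qseqid = "Q1", sseqid = sprintf("S%03d", i),
                 bitscore = bs, slen = slen, nb = bs / slen,
                 stitle = paste(gen, sp, gt), class = cl,
                 order = paste0(substr(cl, 1, 4), "_order1"),
                 genus = gen, species = sp, genotype = gt)
    }
  })
  data.table::rbindlist(rows)
}

# Closed-form expected rarefaction richness (hypergeometric expectation).
oracle_rarefaction_expectation <- function(counts, depth) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}
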