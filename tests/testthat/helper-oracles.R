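# Independent oracles the test suite checks the implementation against.
# Each is deliberately coded from the definition (or delegates to an
# unrelated established implementation), not by calling the package's own
# code path.

suppressPackageStartupMessages({
  library(data.table)
  library(Biostrings)
})

# --- alignment score oracle: exhaustive local alignment via Biostrings ----
# Same scoring scheme (match +10, mismatch -20, gap of length L costs
# 20 + 5L), full dynamic program over every transcript and both strands.
oracle_best_local_score <- function(read, ref_seqs,
                                    match = 10, mismatch = -20,
                                    gap_open = 20, gap_extend = 5) {
  submat <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                   c("A", "C", "G", "T")))
  diag(submat) <- match
  rc <- as.character(reverseComplement(DNAString(read)))
  best <- 0
  for (s in ref_seqs) {
    for (q in c(read, rc)) {
      sc <- pairwiseAlignment(q, s, type = "local",
                              substitutionMatrix = submat,
                              gapOpening = gap_open,
                              gapExtension = gap_extend, scoreOnly = TRUE)
      best <- max(best, sc)
    }
  }
  best
}

# --- pileup recount oracle: naive per-position walk of alignment ops ------
oracle_pileup_recount <- function(alignments) {
  aln <- alignments$alignments
  rows <- list()
  for (i in seq_len(nrow(aln))) {
    qseq <- substr(aln$oriented_seq[i], aln$clip5[i] + 1L,
                   nchar(aln$oriented_seq[i]) - aln$clip3[i])
    lens <- as.integer(regmatches(aln$cigar[i],
                                  gregexpr("\\d+", aln$cigar[i]))[[1]])
    ops <- regmatches(aln$cigar[i], gregexpr("[A-Z]", aln$cigar[i]))[[1]]
    rpos <- aln$start[i]
    qi <- 0L
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "X")) {
        for (t in seq_len(lens[k])) {
          rows[[length(rows) + 1L]] <- data.table(
            tx = aln$tx[i], pos = rpos + t - 1L,
            sample_id = aln$sample_id[i],
            allele = substr(qseq, qi + t, qi + t))
        }
        rpos <- rpos + lens[k]; qi <- qi + lens[k]
      } else if (ops[k] == "D") {
        for (t in seq_len(lens[k])) {
          rows[[length(rows) + 1L]] <- data.table(
            tx = aln$tx[i], pos = rpos + t - 1L,
            sample_id = aln$sample_id[i], allele = "-")
        }
        rpos <- rpos + lens[k]
      } else if (ops[k] == "I") {
        qi <- qi + lens[k]
      }
    }
  }
  if (!length(rows)) return(data.table())
  long <- rbindlist(rows)
  out <- dcast(long[, .N, by = .(tx, pos, sample_id, allele)],
               tx + pos + sample_id ~ allele, value.var = "N", fill = 0L)
  for (col in c("A", "C", "G", "T", "-"))
    if (!col %in% names(out)) out[, (col) := 0L]
  setnames(out, "-", "gap")
  setorder(out, tx, pos, sample_id)
  out[, .(tx, pos, sample_id, A, C, G, T, gap)]
}

# --- Fisher two-sided oracle: hypergeometric enumeration ------------------
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- group-specificity set-logic oracle -----------------------------------
# Direct restatement: allele exclusive iff present in one group and with
# zero reads in the other; subtype from present-set sizes.
oracle_classify <- function(ao, lm, min_present = 2L) {
  alleles <- c("A", "C", "G", "T", "-")
  av <- setNames(rep(0L, 5), alleles); av[names(ao)] <- ao
  lv <- setNames(rep(0L, 5), alleles); lv[names(lm)] <- lm
  if (sum(av) == 0 || sum(lv) == 0) return("uncallable")
  pa <- alleles[av >= min_present]
  pl <- alleles[lv >= min_present]
  if (!length(pa) || !length(pl)) return("uncallable")
  excl <- any(lv[pa] == 0) || any(av[pl] == 0)
  if (!excl) return("not_group_specific")
  if (length(pa) >= 2 && length(pl) >= 2) return("polymorphic_in_both")
  if (length(pa) >= 2) return("polymorphic_in_AO")
  if (length(pl) >= 2) return("polymorphic_in_LM")
  "fixed_divergent"
}

# --- moderated-t re-derivation oracle -------------------------------------
# Recomputes the statistic from the closed-form definition, independent of
# the package's vectorized implementation.
oracle_moderated_t <- function(log_expr, groups, d0, s0_sq) {
  groups <- as.character(groups)
  g <- sort(unique(groups))
  i1 <- which(groups == g[1]); i2 <- which(groups == g[2])
  n1 <- length(i1); n2 <- length(i2); dg <- n1 + n2 - 2
  t(apply(log_expr, 1, function(x) {
    m1 <- mean(x[i1]); m2 <- mean(x[i2])
    s2 <- (sum((x[i1] - m1)^2) + sum((x[i2] - m2)^2)) / dg
    s2t <- if (is.infinite(d0)) s0_sq else
      if (d0 == 0) s2 else (d0 * s0_sq + dg * s2) / (d0 + dg)
    tt <- (m1 - m2) / sqrt(s2t * (1 / n1 + 1 / n2))
    df <- min(d0 + dg, 1e6)
    c(t = tt, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
  }))
}

# --- BH step-up oracle ----------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# --- centroid-linkage brute force -----------------------------------------
# Greedy agglomeration recomputing cluster centroids after every merge;
# returns merge heights (Euclidean centroid distances) and the member sets
# merged at each step.
oracle_centroid_cluster <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), function(i) i)
  centroids <- lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- sqrt(sum((centroids[[i]] - centroids[[j]])^2))
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    merges[[length(merges) + 1L]] <- sort(c(clusters[[i]], clusters[[j]]))
    newc <- sort(c(clusters[[i]], clusters[[j]]))
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newcent <- (centroids[[i]] * ni + centroids[[j]] * nj) / (ni + nj)
    clusters <- c(clusters[-c(i, j)], list(newc))
    centroids <- c(centroids[-c(i, j)], list(newcent))
  }
  list(heights = heights, merges = merges)
}

# member sets merged at each step of an hclust tree
hclust_merge_sets <- function(h) {
  sets <- list()
  out <- list()
  for (i in seq_len(nrow(h$merge))) {
    members <- unlist(lapply(h$merge[i, ], function(m)
      if (m < 0) -m else sets[[m]]))
    sets[[i]] <- sort(members)
    out[[i]] <- sets[[i]]
  }
  out
}
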