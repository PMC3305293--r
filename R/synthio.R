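#' Generate a synthetic reference transcript set
#'
#' Transcripts emulate a de novo transcriptome assembly: a few hundred
#' contigs of a few hundred bp, a fraction of which carry an annotated CDS
#' (start codon `ATG`, internal frame free of stop codons, terminal stop,
#' length divisible by 3).  Lengths are drawn from a truncated normal.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_mean,length_sd,length_min transcript length distribution (bp).
#' @param cds_fraction proportion of transcripts that carry a CDS.
#' @param gc target GC content in `[0, 1]`.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return a `reference_set`: list with `seq` (named character vector of
#'   sequences) and `info` (data.table with `id`, `length`, `cds_start`,
#'   `cds_end` 0-based half-open, `is_coding`).
#' @export
generate_reference <- function(n_transcripts, length_mean = 350,
                               length_sd = 120, length_min = 120,
                               cds_fraction = 0.7, gc = 0.45, seed = 1L) {
  stopifnot(n_transcripts >= 1, cds_fraction >= 0, cds_fraction <= 1,
            gc >= 0, gc <= 1)
  if (length_mean <= 0 || length_min <= 0)
    stop("transcript lengths must be positive")
  set.seed(derive_seed(seed, "reference"))
  lens <- rtrunc_norm_int(n_transcripts, length_mean, length_sd, length_min)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ids <- sprintf("tx%04d", seq_len(n_transcripts))
  coding <- seq_len(n_transcripts) <= round(cds_fraction * n_transcripts)
  coding <- sample(coding)  # don't tie coding status to id order
  seqs <- character(n_transcripts)
  cds_start <- rep(NA_integer_, n_transcripts)
  cds_end <- rep(NA_integer_, n_transcripts)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n_transcripts)) {
    b <- sample(BASES, lens[i], replace = TRUE, prob = probs)
    if (coding[i]) {
      u5 <- sample.int(min(31L, lens[i] - 60L), 1L) - 1L
      u3 <- sample.int(min(31L, lens[i] - 60L - u5), 1L) - 1L
      clen <- ((lens[i] - u5 - u3) %/% 3L) * 3L
      s <- u5 + 1L
      b[s:(s + 2L)] <- c("A", "T", "G")
      # clear internal stop codons; terminal codon becomes a stop
      for (cs in seq(s + 3L, s + clen - 6L, by = 3L)) {
        if (paste(b[cs:(cs + 2L)], collapse = "") %in% stops) b[cs + 2L] <- "C"
      }
      b[(s + clen - 3L):(s + clen - 1L)] <-
        strsplit(sample(stops, 1L), "")[[1L]]
      cds_start[i] <- u5
      cds_end[i] <- u5 + clen
    }
    seqs[i] <- paste(b, collapse = "")
  }
  names(seqs) <- ids
  out <- list(
    seq = seqs,
    info = data.table(id = ids, length = lens, cds_start = cds_start,
                      cds_end = cds_end, is_coding = coding))
  class(out) <- "reference_set"
  out
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d transcripts, mean length %.0f bp, %d coding\n",
              nrow(x$info), mean(x$info$length), sum(x$info$is_coding)))
  invisible(x)
}

VARIANT_CLASSES <- c("shared_polymorphism", "group_exclusive_fixed",
                     "group_exclusive_polymorphic")

#' Plant variants into a reference set
#'
#' Creates a truth set of known variants of three classes:
#' `shared_polymorphism` (both groups segregate the same two alleles),
#' `group_exclusive_fixed` (each group fixed for a different allele), and
#' `group_exclusive_polymorphic` (one group segregates ref and alt, the other
#' carries only the reference, so one allele is always shared between groups).
#' A subset of variants can be single-base deletions (`alt = "-"`), the one
#' indel class the downstream caller classifies.
#'
#' @param reference a `reference_set`.
#' @param n_per_class named counts over
#'   `c("shared_polymorphism", "group_exclusive_fixed",
#'   "group_exclusive_polymorphic")`; missing names mean 0.
#' @param n_indel how many of the planted variants are single-base deletions.
#' @param freq_shared,freq_polymorphic within-group alternate-allele
#'   frequency for the polymorphic classes (scalar or vector, recycled);
#'   fixed variants always have frequency 1.
#' @param margin variants are placed at least this many bp from either
#'   transcript end (keeps planted sites inside typical read alignments).
#' @param seed integer seed.
#' @return a `truth_set`: list with `variants` (data.table: `tx`, `pos`
#'   0-based, `ref`, `alt`, `class`, `group`, `freq`), `fold_change`
#'   (NULL until assigned), and `seed`.
#' @export
plant_variants <- function(reference, n_per_class = c(), n_indel = 0L,
                           freq_shared = 0.5, freq_polymorphic = 0.5,
                           margin = 5L, seed = 1L) {
  stopifnot(inherits(reference, "reference_set"))
  n <- setNames(integer(3), VARIANT_CLASSES)
  if (length(n_per_class)) {
    bad <- setdiff(names(n_per_class), VARIANT_CLASSES)
    if (length(bad)) stop("unknown variant class: ", paste(bad, collapse = ", "))
    n[names(n_per_class)] <- as.integer(n_per_class)
  }
  total <- sum(n)
  set.seed(derive_seed(seed, "variants"))
  info <- reference$info
  usable <- pmax(info$length - 2L * margin, 0L)
  if (total > sum(usable))
    stop("requested ", total, " variants but only ", sum(usable),
         " sites are available")
  variants <- data.table(tx = character(), pos = integer(), ref = character(),
                         alt = character(), class = character(),
                         group = character(), freq = numeric())
  if (total > 0) {
    # sample distinct (transcript, position) pairs, transcripts length-weighted
    site_tx <- rep(info$id, usable)
    site_pos <- unlist(lapply(seq_len(nrow(info)), function(i) {
      if (usable[i] > 0) seq.int(margin, info$length[i] - margin - 1L)
      else integer()
    }))
    pick <- sample.int(length(site_tx), total)
    classes <- rep(VARIANT_CLASSES, n)
    refb <- substring(reference$seq[site_tx[pick]], site_pos[pick] + 1L,
                      site_pos[pick] + 1L)
    altb <- vapply(refb, function(r) sample(setdiff(BASES, r), 1L), "")
    if (n_indel > 0) {
      idx <- sample.int(total, min(n_indel, total))
      altb[idx] <- "-"
    }
    grp <- ifelse(classes == "shared_polymorphism", "both",
                  sample(c("AO", "LM"), total, replace = TRUE))
    fr <- rep(1, total)
    fr[classes == "shared_polymorphism"] <-
      rep_len(freq_shared, sum(classes == "shared_polymorphism"))
    fr[classes == "group_exclusive_polymorphic"] <-
      rep_len(freq_polymorphic, sum(classes == "group_exclusive_polymorphic"))
    stopifnot(all(fr > 0), all(fr <= 1))
    variants <- data.table(tx = site_tx[pick], pos = site_pos[pick],
                           ref = unname(refb), alt = unname(altb),
                           class = classes, group = grp, freq = fr)
    setorder(variants, tx, pos)
  }
  out <- list(variants = variants, fold_change = NULL, seed = seed)
  class(out) <- "truth_set"
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$variants), "planted variants\n")
  if (nrow(x$variants)) print(x$variants[, .N, by = class])
  if (!is.null(x$fold_change))
    cat(sum(x$fold_change$fc != 1), "transcripts with expression effects\n")
  invisible(x)
}

#' Plant per-transcript expression fold changes
#'
#' Assigns true LM/AO expression ratios to randomly chosen transcripts,
#' log-uniform over `fc_range` (half up- and half down-regulated in LM);
#' all other transcripts get fold change 1.
#'
#' @param reference a `reference_set`.
#' @param n_up,n_down transcripts over- and under-expressed in LM.
#' @param fc_range range of fold-change magnitudes (both > 1).
#' @param seed integer seed.
#' @return data.table with `tx` and `fc` (LM/AO).
#' @export
plant_fold_changes <- function(reference, n_up = 3L, n_down = 3L,
                               fc_range = c(2, 200), seed = 1L) {
  stopifnot(inherits(reference, "reference_set"), all(fc_range > 1),
            n_up + n_down <= nrow(reference$info))
  set.seed(derive_seed(seed, "fold_changes"))
  ids <- reference$info$id
  pick <- sample(ids, n_up + n_down)
  fc <- rep(1, length(ids))
  names(fc) <- ids
  mag <- exp(runif(n_up + n_down, log(fc_range[1]), log(fc_range[2])))
  dir <- rep(c(1, -1), c(n_up, n_down))
  fc[pick] <- ifelse(dir > 0, mag, 1 / mag)
  data.table(tx = ids, fc = unname(fc))
}

#' Build per-sample sequencing plans for a two-group study
#'
#' Emulates a non-normalized cDNA study: per-transcript sampling weights are
#' proportional to transcript length times a shared log-normal abundance, so
#' read counts track transcript abundance; LM samples additionally multiply
#' in the true fold changes.
#'
#' @param reference a `reference_set`.
#' @param n_ao,n_lm samples per group.
#' @param reads_per_sample scalar or vector (length `n_ao + n_lm`).
#' @param read_len_mean,read_len_sd,read_len_min read-length distribution (bp).
#' @param sub_rate,indel_rate per-base error rates.
#' @param fold_change optional data.table from [plant_fold_changes()].
#' @param abundance_sd sd of the log-normal abundance (log scale).
#' @param seed integer seed.
#' @return a list of plans (class `sample_plan_set`), each with `sample_id`,
#'   `group`, `n_reads`, read-length parameters, error rates and a normalized
#'   `weights` vector over transcripts.
#' @export
sample_plans <- function(reference, n_ao = 4L, n_lm = 3L,
                         reads_per_sample = 5000L,
                         read_len_mean = 187, read_len_sd = 60,
                         read_len_min = 40, sub_rate = 0.005,
                         indel_rate = 0.002, fold_change = NULL,
                         abundance_sd = 1, seed = 1L) {
  stopifnot(inherits(reference, "reference_set"), n_ao >= 1, n_lm >= 1,
            all(reads_per_sample > 0))
  set.seed(derive_seed(seed, "plans"))
  ids <- reference$info$id
  abundance <- exp(rnorm(length(ids), 0, abundance_sd))
  base_w <- abundance * reference$info$length
  fc <- rep(1, length(ids))
  if (!is.null(fold_change)) {
    stopifnot(all(fold_change$tx %in% ids))
    fc[match(fold_change$tx, ids)] <- fold_change$fc
  }
  groups <- rep(c("AO", "LM"), c(n_ao, n_lm))
  sample_ids <- c(sprintf("AO_%d", seq_len(n_ao)), sprintf("LM_%d", seq_len(n_lm)))
  n_reads <- rep_len(as.integer(reads_per_sample), n_ao + n_lm)
  plans <- lapply(seq_along(sample_ids), function(i) {
    w <- if (groups[i] == "LM") base_w * fc else base_w
    list(sample_id = sample_ids[i], group = groups[i], n_reads = n_reads[i],
         read_len_mean = read_len_mean, read_len_sd = read_len_sd,
         read_len_min = read_len_min, sub_rate = sub_rate,
         indel_rate = indel_rate, weights = setNames(w / sum(w), ids))
  })
  class(plans) <- "sample_plan_set"
  plans
}

# Build haplotype sequences for one transcript given its variants and a
# 0/1 matrix of alt-allele choices (rows = haplotypes).  Deletions shift
# coordinates, so alts are applied from the highest position down.
apply_haplotype <- function(seq, variants, choice) {
  ord <- order(variants$pos, decreasing = TRUE)
  for (k in ord) {
    if (!choice[k]) next
    p <- variants$pos[k] + 1L
    if (variants$alt[k] == "-") {
      seq <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + 1L, nchar(seq)))
    } else {
      substr(seq, p, p) <- variants$alt[k]
    }
  }
  seq
}

# per-read sequencing errors: independent substitutions plus rare 1-bp
# insertions/deletions
apply_read_errors <- function(seq, n_sub, n_indel) {
  len <- nchar(seq)
  if (n_sub > 0) {
    pos <- sample.int(len, min(n_sub, len))
    ch <- strsplit(seq, "")[[1L]]
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(BASES, b), 1L), "")
    seq <- paste(ch, collapse = "")
  }
  for (i in seq_len(n_indel)) {
    len <- nchar(seq)
    p <- sample.int(len, 1L)
    if (runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1L, p), sample(BASES, 1L),
                    substr(seq, p + 1L, len))
    } else if (len > 1L) {
      seq <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + 1L, len))
    }
  }
  seq
}

#' Simulate two-group 454-style read sets with planted truth
#'
#' For each sample, read counts per transcript are multinomial in the plan's
#' expression weights; each read is drawn from a haplotype of its transcript
#' (planted variants applied at their within-group frequencies, restricted to
#' the sample's group), truncated-normal length, uniform start, uniform
#' strand, then passed through the per-base error model.  Per-sample random
#' streams are derived from the master seed by sample id, so adding a sample
#' leaves the others' reads unchanged.
#'
#' @param reference a `reference_set`.
#' @param truth a `truth_set` (may contain zero variants).
#' @param plans a `sample_plan_set`.
#' @param seed master integer seed.
#' @param dir if non-NULL, write one FASTQ per sample (constant Q30
#'   qualities) plus a `manifest.tsv` there.
#' @return a `read_set`: list with `samples` (per sample, a named character
#'   vector of read sequences) and `manifest` (data.table: `sample_id`,
#'   `group`, `n_reads`, `path`).
#' @export
simulate_reads <- function(reference, truth, plans, seed = 1L, dir = NULL) {
  stopifnot(inherits(reference, "reference_set"), inherits(truth, "truth_set"),
            inherits(plans, "sample_plan_set"))
  variants <- truth$variants
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- list()
  manifest <- list()
  for (plan in plans) {
    set.seed(derive_seed(seed, paste0("reads:", plan$sample_id)))
    stopifnot(all(names(plan$weights) %in% names(reference$seq)))
    counts <- drop(rmultinom(1, plan$n_reads, plan$weights))
    seqs <- character(0)
    for (tx_id in names(counts)[counts > 0]) {
      n_tx <- counts[[tx_id]]
      tx_seq <- reference$seq[[tx_id]]
      if (nchar(tx_seq) == 0L) {
        warning("transcript ", tx_id, " has zero length; ", n_tx,
                " reads skipped")
        next
      }
      v <- variants[tx == tx_id & (group == "both" | group == plan$group)]
      if (nrow(v) > 0) {
        # enumerate haplotypes over the (few) variants on this transcript
        combos <- as.matrix(expand.grid(rep(list(0:1), nrow(v))))
        cprob <- apply(combos, 1, function(ch)
          prod(ifelse(ch == 1, v$freq, 1 - v$freq)))
        haps <- vapply(seq_len(nrow(combos)), function(r)
          apply_haplotype(tx_seq, v, combos[r, ]), "")
        n_hap <- drop(rmultinom(1, n_tx, cprob))
      } else {
        haps <- tx_seq
        n_hap <- n_tx
      }
      for (h in seq_along(haps)) {
        if (n_hap[h] == 0) next
        hl <- nchar(haps[h])
        rl <- pmin(rtrunc_norm_int(n_hap[h], plan$read_len_mean,
                                   plan$read_len_sd, plan$read_len_min), hl)
        st <- floor(runif(n_hap[h]) * (hl - rl + 1)) + 1L
        seqs <- c(seqs, substring(haps[h], st, st + rl - 1L))
      }
    }
    # sequencing errors
    n_sub <- rbinom(length(seqs), nchar(seqs), plan$sub_rate)
    n_ind <- rbinom(length(seqs), nchar(seqs), plan$indel_rate)
    touch <- which(n_sub + n_ind > 0)
    for (i in touch) seqs[i] <- apply_read_errors(seqs[i], n_sub[i], n_ind[i])
    # uniform strand
    flip <- which(runif(length(seqs)) < 0.5)
    if (length(flip)) seqs[flip] <- reverse_complement(seqs[flip])
    names(seqs) <- sprintf("%s:%06d", plan$sample_id, seq_along(seqs))
    samples[[plan$sample_id]] <- seqs
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(plan$sample_id, ".fastq"))
      write_fastq(seqs, path)
    }
    manifest[[plan$sample_id]] <- data.table(
      sample_id = plan$sample_id, group = plan$group,
      n_reads = length(seqs), path = path)
  }
  manifest <- rbindlist(manifest)
  if (!is.null(dir))
    fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  out <- list(samples = samples, manifest = manifest)
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x$manifest), "samples,",
      sum(x$manifest$n_reads), "reads\n")
  invisible(x)
}
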