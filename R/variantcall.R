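# SNP calling and group-specificity classification.
#
# Sites are called from raw-read pileups pooled over samples, filtered on the
# variant-allele-fraction window (default 25-75% of raw reads at the site,
# boundaries inclusive), then classified against the two group allele
# profiles.  An allele counts as "present" in a group with at least
# `min_present` supporting reads and "absent" only with zero reads; a
# single stray read neither establishes nor excludes an allele, which keeps
# isolated sequencing errors from creating or destroying exclusivity.

ALLELES <- c("A", "C", "G", "T", "-")
ALLELE_COLS <- c("A", "C", "G", "T", "gap")

#' Call putative SNP sites from a pileup
#'
#' A putative site has at least two alleles each supported by
#' `min_allele_reads` raw reads (pooled over all samples) and total depth of
#' at least `min_depth`.  The majority allele across all samples stands in
#' for the assembly consensus and is recorded as the site's reference allele.
#'
#' @param pileup a `pileup_table` from [build_pileup()].
#' @param groups named character vector mapping sample id to group
#'   (`"AO"`/`"LM"`).
#' @param min_depth minimum pooled depth at the site.
#' @param min_allele_reads minimum raw reads supporting an allele for it to
#'   count towards polymorphism.
#' @return a `snp_table` data.table: `tx`, `pos` (0-based), `depth`, pooled
#'   counts `n_A`..`n_gap`, per-group counts `AO_A`..`LM_gap`, `alleles`
#'   (comma-joined passing alleles, most supported first), `major`.
#' @export
call_putative_snps <- function(pileup, groups, min_depth = 10L,
                               min_allele_reads = 2L) {
  stopifnot(inherits(pileup, "pileup_table") || is.data.frame(pileup))
  p <- as.data.table(pileup)
  miss <- setdiff(unique(p$sample_id), names(groups))
  if (length(miss)) stop("samples without a group label: ",
                         paste(miss, collapse = ", "))
  p[, group := unname(groups[sample_id])]
  stopifnot(all(p$group %in% c("AO", "LM")))
  tot <- p[, lapply(.SD, sum), by = .(tx, pos), .SDcols = ALLELE_COLS]
  setnames(tot, ALLELE_COLS, paste0("n_", ALLELE_COLS))
  for (g in c("AO", "LM")) {
    gs <- p[group == g, lapply(.SD, sum), by = .(tx, pos),
            .SDcols = ALLELE_COLS]
    setnames(gs, ALLELE_COLS, paste0(g, "_", ALLELE_COLS))
    tot <- merge(tot, gs, by = c("tx", "pos"), all.x = TRUE)
  }
  for (col in grep("^(AO|LM)_", names(tot), value = TRUE))
    data.table::set(tot, which(is.na(tot[[col]])), col, 0L)
  cnt <- as.matrix(tot[, paste0("n_", ALLELE_COLS), with = FALSE])
  colnames(cnt) <- ALLELES
  tot[, depth := rowSums(cnt)]
  pass <- cnt >= min_allele_reads
  tot[, n_alleles := rowSums(pass)]
  keep <- tot$n_alleles >= 2L & tot$depth >= min_depth
  tot <- tot[keep]
  cnt <- cnt[keep, , drop = FALSE]
  pass <- pass[keep, , drop = FALSE]
  if (nrow(tot)) {
    tot[, alleles := vapply(seq_len(.N), function(i) {
      a <- ALLELES[pass[i, ]]
      paste(a[order(-cnt[i, a], match(a, ALLELES))], collapse = ",")
    }, "")]
    tot[, major := ALLELES[max.col(cnt, ties.method = "first")]]
  } else {
    tot[, c("alleles", "major") := .(character(), character())]
  }
  setattr(tot, "class", c("snp_table", "data.table", "data.frame"))
  tot[]
}

site_allele_counts <- function(sites, prefix = "n") {
  m <- as.matrix(as.data.table(sites)[, paste0(prefix, "_", ALLELE_COLS),
                                      with = FALSE])
  colnames(m) <- ALLELES
  m
}

#' Filter sites on the variant-allele-fraction window
#'
#' Keeps a site when its polymorphism involves an intermediate fraction of
#' the raw reads: under the default per-allele mode, every passing allele
#' other than the majority allele must have a read fraction within
#' `[low, high]` (boundaries inclusive); under `"total_nonref"` the summed
#' non-majority fraction is tested instead.
#'
#' @param sites a `snp_table`.
#' @param low,high window bounds as fractions of site depth (`low < high`).
#' @param mode `"per_allele"` (default) or `"total_nonref"`.
#' @return the filtered `snp_table`.
#' @export
filter_frequency <- function(sites, low = 0.25, high = 0.75,
                             mode = c("per_allele", "total_nonref")) {
  mode <- match.arg(mode)
  if (low >= high) stop("invalid frequency window: low >= high")
  s <- as.data.table(sites)
  if (nrow(s) == 0) return(sites)
  cnt <- site_allele_counts(s)
  keep <- vapply(seq_len(nrow(s)), function(i) {
    al <- strsplit(s$alleles[i], ",")[[1]]
    minor <- setdiff(al, s$major[i])
    f <- cnt[i, minor] / s$depth[i]
    if (mode == "total_nonref") f <- sum(f)
    all(f >= low & f <= high)
  }, TRUE)
  out <- s[keep]
  setattr(out, "class", class(sites))
  out[]
}

# Set-logic classification of one site given the per-group present-allele
# sets and per-group zero-count information.  Exported building block so the
# decision rule is testable in isolation against enumeration.

#' Classify the group specificity of allele profiles
#'
#' An allele is *exclusive* when present (>= `min_present` reads) in exactly
#' one group and entirely absent (0 reads) from the other; a site is
#' group-exclusive when it has at least one exclusive allele.  Subtypes:
#' `fixed_divergent` when each group presents a single, different allele;
#' `polymorphic_in_AO`/`_LM` when the named group presents two or more
#' alleles at least one of which the other group lacks; `polymorphic_in_both`
#' when both groups are polymorphic and each holds an exclusive allele.
#'
#' @param ao_counts,lm_counts named integer vectors of per-allele read counts
#'   for the two groups (names from `A`, `C`, `G`, `T`, `-`).
#' @param min_present reads required for presence.
#' @return list with `classification` (`group_exclusive`,
#'   `not_group_specific`, or `uncallable`) and `subtype` (NA unless
#'   group-exclusive).
#' @export
classify_profiles <- function(ao_counts, lm_counts, min_present = 2L) {
  ao <- setNames(rep(0L, 5L), ALLELES); ao[names(ao_counts)] <- ao_counts
  lm <- setNames(rep(0L, 5L), ALLELES); lm[names(lm_counts)] <- lm_counts
  if (sum(ao) == 0L || sum(lm) == 0L)
    return(list(classification = "uncallable", subtype = NA_character_))
  pres_ao <- ALLELES[ao >= min_present]
  pres_lm <- ALLELES[lm >= min_present]
  if (length(pres_ao) == 0L || length(pres_lm) == 0L)
    return(list(classification = "uncallable", subtype = NA_character_))
  excl_ao <- pres_ao[lm[pres_ao] == 0L]
  excl_lm <- pres_lm[ao[pres_lm] == 0L]
  if (length(excl_ao) == 0L && length(excl_lm) == 0L)
    return(list(classification = "not_group_specific",
                subtype = NA_character_))
  subtype <-
    if (length(pres_ao) >= 2L && length(pres_lm) >= 2L) "polymorphic_in_both"
    else if (length(pres_ao) >= 2L) "polymorphic_in_AO"
    else if (length(pres_lm) >= 2L) "polymorphic_in_LM"
    else "fixed_divergent"
  list(classification = "group_exclusive", subtype = subtype)
}

#' Classify sites as group-exclusive or not
#'
#' Applies [classify_profiles()] to every site of a `snp_table` and adds
#' `present_AO`, `present_LM`, `classification` and `subtype` columns.
#' Sites where a group has zero depth (or no allele reaches the presence
#' threshold) are marked `uncallable`.
#'
#' @param sites a `snp_table` with per-group counts.
#' @param min_present reads required for an allele to be present in a group.
#' @return the annotated `snp_table`.
#' @export
classify_group_specific <- function(sites, min_present = 2L) {
  s <- as.data.table(sites)
  if (nrow(s) == 0) {
    s[, c("present_AO", "present_LM", "classification", "subtype") :=
        .(character(), character(), character(), character())]
    setattr(s, "class", class(sites))
    return(s[])
  }
  ao <- site_allele_counts(s, "AO")
  lm <- site_allele_counts(s, "LM")
  res <- lapply(seq_len(nrow(s)), function(i)
    classify_profiles(ao[i, ], lm[i, ], min_present))
  s[, present_AO := vapply(seq_len(.N), function(i)
    paste(ALLELES[ao[i, ] >= min_present], collapse = ","), "")]
  s[, present_LM := vapply(seq_len(.N), function(i)
    paste(ALLELES[lm[i, ] >= min_present], collapse = ","), "")]
  s[, classification := vapply(res, `[[`, "", "classification")]
  s[, subtype := vapply(res, `[[`, "", "subtype")]
  setattr(s, "class", class(sites))
  s[]
}

#' Annotate the coding effect of classified sites
#'
#' Substitutions inside an annotated CDS are translated in frame with the
#' standard genetic code (the codon is taken from the transcript with the
#' site's majority allele standing in for the consensus base); a gap allele
#' inside a CDS is an `indel`; sites outside any CDS are `noncoding`.
#'
#' @param sites a `snp_table`.
#' @param reference the `reference_set` carrying CDS annotations.
#' @return the `snp_table` with `region`, `coding_effect` and `aa_change`
#'   columns.
#' @export
annotate_coding_effect <- function(sites, reference) {
  stopifnot(inherits(reference, "reference_set"))
  s <- as.data.table(sites)
  if (nrow(s) == 0) {
    s[, c("region", "coding_effect", "aa_change") :=
        .(character(), character(), character())]
    setattr(s, "class", class(sites))
    return(s[])
  }
  info <- reference$info
  idx <- match(s$tx, info$id)
  if (anyNA(idx)) stop("site references unknown transcript")
  if (any(s$pos >= info$length[idx] | s$pos < 0))
    stop("site position outside transcript")
  region <- character(nrow(s))
  effect <- character(nrow(s))
  aa_chg <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    j <- idx[i]
    in_cds <- isTRUE(info$is_coding[j]) && !is.na(info$cds_start[j]) &&
      s$pos[i] >= info$cds_start[j] && s$pos[i] < info$cds_end[j]
    region[i] <- if (in_cds) "CDS" else "noncoding"
    al <- strsplit(s$alleles[i], ",")[[1]]
    minor <- setdiff(al, s$major[i])
    if (!in_cds) {
      effect[i] <- if ("-" %in% al) "indel" else "noncoding"
      aa_chg[i] <- "-"
      next
    }
    if ("-" %in% al) {
      effect[i] <- "indel"
      aa_chg[i] <- "?"
      next
    }
    effs <- vapply(minor, function(alt)
      codon_effect(reference$seq[[s$tx[i]]], info$cds_start[j], s$pos[i],
                   s$major[i], alt), "")
    nonsyn <- effs[effs != "synonymous"]
    if (length(nonsyn)) {
      effect[i] <- "nonsynonymous"
      aa_chg[i] <- paste(nonsyn, collapse = ";")
    } else {
      effect[i] <- "synonymous"
      aa_chg[i] <- "-"
    }
  }
  s[, region := region]
  s[, coding_effect := effect]
  s[, aa_change := aa_chg]
  setattr(s, "class", class(sites))
  s[]
}

# effect of substituting `alt` for `ref_base` at 0-based `pos` inside the CDS
# starting at 0-based `cds_start`; returns "synonymous" or "X->Y"
codon_effect <- function(seq, cds_start, pos, ref_base, alt) {
  stopifnot(alt %in% BASES, ref_base %in% ALLELES)
  off <- pos - cds_start
  codon_start <- cds_start + (off %/% 3L) * 3L
  codon <- strsplit(substr(seq, codon_start + 1L, codon_start + 3L), "")[[1]]
  if (length(codon) < 3L) return("unknown")
  within <- off %% 3L + 1L
  ref_codon <- codon
  if (ref_base %in% BASES) ref_codon[within] <- ref_base
  alt_codon <- ref_codon
  alt_codon[within] <- alt
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[paste(ref_codon, collapse = "")])
  aa_alt <- unname(gc[paste(alt_codon, collapse = "")])
  if (is.na(aa_ref) || is.na(aa_alt)) return("unknown")
  if (aa_ref == aa_alt) "synonymous" else paste0(aa_ref, "->", aa_alt)
}

#' Run the full SNP-calling stage
#'
#' Convenience wrapper: putative calls, frequency window, group
#' classification, coding-effect annotation.  The filter funnel is strictly
#' nested: group-exclusive sites are a subset of frequency-filtered sites,
#' themselves a subset of putative sites.
#'
#' @inheritParams call_putative_snps
#' @inheritParams filter_frequency
#' @inheritParams classify_group_specific
#' @param reference the `reference_set`.
#' @return list with `putative`, `filtered` and `classified` snp_tables and
#'   a `counts` funnel.
#' @export
call_snps <- function(pileup, groups, reference, min_depth = 10L,
                      min_allele_reads = 2L, low = 0.25, high = 0.75,
                      mode = "per_allele", min_present = 2L) {
  putative <- call_putative_snps(pileup, groups, min_depth, min_allele_reads)
  filtered <- filter_frequency(putative, low, high, mode)
  classified <- annotate_coding_effect(
    classify_group_specific(filtered, min_present), reference)
  list(putative = putative, filtered = filtered, classified = classified,
       counts = c(putative = nrow(putative), filtered = nrow(filtered),
                  group_exclusive =
                    sum(classified$classification == "group_exclusive")))
}
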