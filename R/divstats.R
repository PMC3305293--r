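# Divergence summaries linking the SNP and expression analyses: the exact
# test contrasting how many group-specific sites remain polymorphic within
# each group, the overlap between SNP-bearing loci and the most misexpressed
# genes, and the run report with its funnel percentages.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-ordering convention: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one (`stats::fisher.test` semantics, which the
#' test suite confirms against direct enumeration).
#'
#' @param table 2x2 matrix of nonnegative integer cells, or a length-4
#'   vector `(a, b, c, d)` filled by row.
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  if (is.vector(table) && length(table) == 4L)
    table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be nonnegative integers")
  if (sum(table) == 0) return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Overlap between SNP-bearing loci and differentially expressed genes
#'
#' @param snp_loci ids of loci carrying group-specific SNPs.
#' @param de_genes ids of differentially expressed genes (same namespace).
#' @return list with `n_snp_loci`, `n_de_genes`, `n_shared`,
#'   `shared_fraction` (of SNP loci; NA when there are none) and
#'   `percent` (the fraction formatted to the nearest integer percent).
#' @export
snp_de_overlap <- function(snp_loci, de_genes) {
  snp_loci <- unique(as.character(snp_loci))
  de_genes <- unique(as.character(de_genes))
  n_shared <- length(intersect(snp_loci, de_genes))
  frac <- if (length(snp_loci) == 0) NA_real_ else n_shared / length(snp_loci)
  list(n_snp_loci = length(snp_loci), n_de_genes = length(de_genes),
       n_shared = n_shared, shared_fraction = frac,
       percent = if (is.na(frac)) NA_character_
                 else format_percent(n_shared, length(snp_loci)))
}

#' Assemble the pipeline report
#'
#' Collects the per-stage funnel counts and derived percentages.  Printed
#' percentages follow the report conventions: integer precision for read
#' incorporation and overlap, one decimal for the group-specific fraction of
#' filtered sites.  Full-precision values are kept in the machine-readable
#' form; missing stages yield explicit `NA` gaps rather than errors.
#'
#' @param total_reads,aligned_reads read funnel.
#' @param n_putative,n_filtered,n_group_specific,n_loci SNP funnel.
#' @param subtype_counts named counts over group-exclusive subtypes.
#' @param de_tiers named vector, e.g. `c(fold2 = ..., fold8 = ...,
#'   significant = ...)`.
#' @param overlap result of [snp_de_overlap()].
#' @param fisher list with `table` (2x2) and `p` from
#'   [fisher_exact_two_sided()].
#' @param run_id,seed provenance stamps.
#' @return a `pipeline_report` list with `counts`, `percent` (formatted
#'   strings), `values` (unrounded), and provenance.
#' @export
pipeline_report <- function(total_reads = NA, aligned_reads = NA,
                            n_putative = NA, n_filtered = NA,
                            n_group_specific = NA, n_loci = NA,
                            subtype_counts = NULL, de_tiers = NULL,
                            overlap = NULL, fisher = NULL,
                            run_id = NA_character_, seed = NA_integer_) {
  pct <- function(num, den, digits) {
    if (is.na(num) || is.na(den) || den == 0) NA_character_
    else format_percent(num, den, digits)
  }
  val <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else 100 * num / den
  }
  rep <- list(
    counts = list(total_reads = total_reads, aligned_reads = aligned_reads,
                  putative_snps = n_putative, filtered_snps = n_filtered,
                  group_specific_snps = n_group_specific, snp_loci = n_loci,
                  subtypes = as.list(subtype_counts),
                  de_tiers = as.list(de_tiers)),
    percent = list(
      reads_aligned = pct(aligned_reads, total_reads, 0),
      group_specific_of_filtered = pct(n_group_specific, n_filtered, 1),
      overlap = if (!is.null(overlap)) overlap$percent else NA_character_),
    values = list(
      reads_aligned = val(aligned_reads, total_reads),
      group_specific_of_filtered = val(n_group_specific, n_filtered),
      overlap = if (!is.null(overlap) && !is.na(overlap$shared_fraction))
        100 * overlap$shared_fraction else NA_real_),
    overlap = overlap, fisher = fisher,
    run_id = run_id, seed = seed)
  if (!is.na(total_reads) && !is.na(aligned_reads) && aligned_reads == 0)
    warning("no reads aligned")
  class(rep) <- "pipeline_report"
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  c0 <- function(v) if (is.null(v) || length(v) == 0 || is.na(v)) "?" else v
  cat("pipeline report", if (!is.na(x$run_id)) paste0("(run ", x$run_id, ")"),
      "\n")
  cat(sprintf("  reads aligned:        %s / %s (%s)\n",
              c0(x$counts$aligned_reads), c0(x$counts$total_reads),
              c0(x$percent$reads_aligned)))
  cat(sprintf("  putative SNP sites:   %s\n", c0(x$counts$putative_snps)))
  cat(sprintf("  frequency-filtered:   %s\n", c0(x$counts$filtered_snps)))
  cat(sprintf("  group-specific SNPs:  %s (%s of filtered) in %s loci\n",
              c0(x$counts$group_specific_snps),
              c0(x$percent$group_specific_of_filtered),
              c0(x$counts$snp_loci)))
  if (length(x$counts$subtypes))
    cat("  subtypes:            ",
        paste(names(x$counts$subtypes), unlist(x$counts$subtypes),
              sep = "=", collapse = ", "), "\n")
  if (length(x$counts$de_tiers))
    cat("  DE tiers:            ",
        paste(names(x$counts$de_tiers), unlist(x$counts$de_tiers),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$overlap))
    cat(sprintf("  SNP-locus / DE-gene overlap: %d of %d (%s)\n",
                x$overlap$n_shared, x$overlap$n_snp_loci,
                c0(x$overlap$percent)))
  if (!is.null(x$fisher))
    cat(sprintf("  within-group polymorphism Fisher test: P = %.3f\n",
                x$fisher$p))
  invisible(x)
}

#' Write a pipeline report as JSON and rendered text
#'
#' @param report a `pipeline_report`.
#' @param json,txt output paths (NULL skips).
#' @export
write_report <- function(report, json = NULL, txt = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!is.null(json)) {
    rep <- unclass(report)
    if (!is.null(rep$fisher$table)) {
      tab <- rep$fisher$table
      rep$fisher$table <- as.vector(t(tab))
    }
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  if (!is.null(txt)) {
    con <- file(txt, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(report)
}
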