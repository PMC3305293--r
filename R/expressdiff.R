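# RPKM quantification and moderated-t differential expression.
#
# Counts are best-hit read counts per contig per sample; RPKM divides by
# contig length (kb) and by total mapped reads (millions).  Testing is on
# log2(RPKM + 1).  The per-contig variance is shrunk towards an
# empirical-Bayes prior fitted by matching the first two moments of the
# log sample variances against a scaled inverse chi-square prior, the
# standard moderated t-statistic construction; the statistic gains the
# prior's degrees of freedom.

#' Tabulate per-contig, per-sample mapped read counts
#'
#' Each aligned read contributes exactly once, to its single best-hit
#' transcript, so column sums equal the per-sample mapped totals.
#'
#' @param alignments an `alignment_set` or list of them.
#' @param reference the `reference_set` (fixes the contig universe).
#' @return integer matrix contigs x samples.
#' @export
count_matrix <- function(alignments, reference) {
  if (inherits(alignments, "alignment_set")) alignments <- list(alignments)
  aln <- rbindlist(lapply(alignments, `[[`, "alignments"))
  samples <- unique(aln$sample_id)
  m <- matrix(0L, nrow(reference$info), length(samples),
              dimnames = list(reference$info$id, samples))
  if (nrow(aln)) {
    tab <- aln[, .N, by = .(tx, sample_id)]
    m[cbind(match(tab$tx, rownames(m)), match(tab$sample_id, samples))] <-
      tab$N
  }
  m
}

#' Compute RPKM from raw counts
#'
#' `RPKM[g, s] = count[g, s] / (length[g] / 1e3) / (total[s] / 1e6)`.
#'
#' @param counts integer matrix contigs x samples.
#' @param lengths contig lengths in bp (all > 0).
#' @param totals per-sample total mapped reads; defaults to column sums of
#'   `counts`.
#' @return an `expression_matrix`: list with `counts`, `rpkm`,
#'   `log2rpkm` (log2(RPKM + 1)), `lengths`, `totals`.
#' @export
compute_rpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), length(totals) == ncol(counts))
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  if (any(totals <= 0)) stop("zero total mapped reads for a sample")
  rpkm <- counts / (lengths / 1e3)
  rpkm <- sweep(rpkm, 2, totals / 1e6, "/")
  out <- list(counts = counts, rpkm = rpkm, log2rpkm = log2(rpkm + 1),
              lengths = lengths, totals = totals)
  class(out) <- "expression_matrix"
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d contigs x %d samples\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

# pooled two-group per-row sample variances and group means
row_group_stats <- function(log_expr, groups) {
  groups <- as.character(groups)
  g <- sort(unique(groups))  # "AO" before "LM": t > 0 means higher in AO
  stopifnot(length(g) == 2L)
  i1 <- which(groups == g[1]); i2 <- which(groups == g[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(log_expr[, i1, drop = FALSE])
  m2 <- rowMeans(log_expr[, i2, drop = FALSE])
  ss1 <- rowSums((log_expr[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((log_expr[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  list(mean1 = m1, mean2 = m2, s2 = (ss1 + ss2) / dg, dg = dg,
       n1 = n1, n2 = n2, g1 = g[1], g2 = g[2])
}

# Newton inverse of trigamma, as used for moment-matching the prior df
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes variance prior
#'
#' Matches the first two moments of `log(s_g^2)` for contigs with positive
#' sample variance against the scaled inverse chi-square prior with
#' parameters `d0` (prior degrees of freedom) and `s0_sq` (prior variance),
#' using the digamma/trigamma relations; when the observed spread of log
#' variances does not exceed the chi-square sampling component, `d0` is
#' infinite and `s0_sq` is the (geometric-mean-consistent) common variance.
#'
#' @param log_expr numeric matrix contigs x samples of log2 expression.
#' @param groups character vector of group labels, one per column.
#' @return a `moderated_params` list: `d0`, `s0_sq`, `dg`.
#' @export
fit_moderated_params <- function(log_expr, groups) {
  st <- row_group_stats(as.matrix(log_expr), groups)
  s2 <- st$s2[st$s2 > 0]
  if (length(s2) < 10L)
    stop("need >= 10 contigs with positive residual variance")
  dg <- st$dg
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) - trigamma(dg / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, dg = dg),
            class = "moderated_params")
}

#' Moderated two-sample t-test
#'
#' Shrinks each contig's pooled variance towards the prior,
#' `s2_tilde = (d0 * s0_sq + dg * s2) / (d0 + dg)`, and tests
#' `t = (mean1 - mean2) / sqrt(s2_tilde * (1/n1 + 1/n2))` against a t
#' distribution on `d0 + dg` degrees of freedom (capped at 1e6 when the
#' prior df is infinite).  With `d0 = 0` this is exactly the ordinary
#' pooled-variance two-sample t-test.
#'
#' @param log_expr numeric matrix contigs x samples.
#' @param groups group labels per column (2 groups, >= 2 samples each).
#' @param params a `moderated_params` fit, or a list with `d0` and `s0_sq`.
#' @return data.table with `contig`, group means, `t_stat`, `df`, `p_value`.
#' @export
moderated_t_test <- function(log_expr, groups, params) {
  log_expr <- as.matrix(log_expr)
  st <- row_group_stats(log_expr, groups)
  d0 <- params$d0
  s0 <- params$s0_sq
  stopifnot(is.numeric(d0), d0 >= 0, is.numeric(s0), s0 > 0 || d0 == 0)
  s2_tilde <- if (is.finite(d0)) {
    if (d0 == 0) st$s2 else (d0 * s0 + st$dg * st$s2) / (d0 + st$dg)
  } else rep(s0, length(st$s2))
  se <- sqrt(s2_tilde * (1 / st$n1 + 1 / st$n2))
  t_stat <- (st$mean1 - st$mean2) / se
  df <- min(d0 + st$dg, 1e6)
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  data.table(contig = rownames(log_expr) %||%
               sprintf("contig%05d", seq_along(t_stat)),
             mean1 = st$mean1, mean2 = st$mean2, group1 = st$g1,
             group2 = st$g2, t_stat = t_stat, df = df, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped
#' at 1 (delegates to `stats::p.adjust` after validating the input).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numbers in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression test on an expression matrix
#'
#' Tests log2(RPKM + 1) between the two groups with the moderated t-test
#' and BH adjustment.  Contigs with zero counts in every retained sample are
#' dropped before testing.  Fold change is the LM/AO ratio of group-mean
#' RPKM with a pseudocount of `fc_pseudo` in numerator and denominator.
#'
#' @param expr an `expression_matrix`.
#' @param groups named or plain character vector of group labels per sample
#'   column (`"AO"`/`"LM"`).
#' @param params optional pre-fitted `moderated_params`; fitted from the
#'   data when NULL.
#' @param fc_pseudo pseudocount (RPKM units) protecting the ratio.
#' @return a `de_result` data.table: `contig`, `mean_AO`, `mean_LM`, `fc`
#'   (LM/AO), `t_stat`, `p_value`, `q_value`.
#' @export
de_test <- function(expr, groups, params = NULL, fc_pseudo = 0.1) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- rowSums(expr$counts) > 0
  le <- expr$log2rpkm[keep, , drop = FALSE]
  rp <- expr$rpkm[keep, , drop = FALSE]
  if (is.null(params)) params <- fit_moderated_params(le, groups)
  # group labels sort AO < LM, so t_stat < 0 means overexpressed in LM
  tt <- moderated_t_test(le, groups, params)
  mean_lm <- rowMeans(rp[, groups == "LM", drop = FALSE])
  mean_ao <- rowMeans(rp[, groups == "AO", drop = FALSE])
  out <- data.table(contig = tt$contig, mean_AO = mean_ao, mean_LM = mean_lm,
                    fc = (mean_lm + fc_pseudo) / (mean_ao + fc_pseudo),
                    t_stat = tt$t_stat, p_value = tt$p_value,
                    q_value = bh_adjust(tt$p_value))
  setattr(out, "class", c("de_result", "data.table", "data.frame"))
  setattr(out, "params", params)
  out[]
}

#' Keep contigs past a fold-change tier
#'
#' Retains contigs whose fold change (in either direction) meets the tier:
#' `max(FC, 1/FC) >= threshold`.
#'
#' @param results a `de_result`.
#' @param threshold fold-change tier (> 1); the analysis uses 2 and 8.
#' @return the filtered `de_result`.
#' @export
fold_change_tier <- function(results, threshold) {
  if (!is.numeric(threshold) || threshold <= 1)
    stop("fold-change threshold must exceed 1")
  r <- as.data.table(results)
  out <- r[pmax(fc, 1 / fc) >= threshold]
  setattr(out, "class", class(results))
  out[]
}

#' Hierarchical clustering of an expression submatrix
#'
#' Agglomerative clustering of genes and of samples with Euclidean distance
#' and centroid linkage (merge criterion: distance between cluster
#' centroids, recomputed after each merge).  Heights are reported on the
#' Euclidean (not squared) scale.  Deterministic for a fixed input order;
#' permuting rows permutes leaves but preserves merge heights.
#'
#' @param mat numeric matrix (e.g. tier-filtered log2 RPKM), contigs x
#'   samples; needs >= 2 rows and columns.
#' @return list with `genes` and `samples` (hclust objects), `gene_order`,
#'   `sample_order`, and `table` (the matrix in dendrogram order).
#' @export
cluster_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 rows and 2 columns to cluster")
  cl <- function(m) {
    h <- hclust(dist(m)^2, method = "centroid")
    h$height <- sqrt(pmax(h$height, 0))
    h
  }
  genes <- cl(mat)
  samples <- cl(t(mat))
  list(genes = genes, samples = samples,
       gene_order = rownames(mat)[genes$order] %||% genes$order,
       sample_order = colnames(mat)[samples$order] %||% samples$order,
       table = mat[genes$order, samples$order, drop = FALSE])
}

#' Write dendrograms and the ordered heat-map table
#'
#' @param clust result of [cluster_expression()].
#' @param dir output directory; writes `genes.nwk`, `samples.nwk` (Newick)
#'   and `heatmap_table.tsv`.
#' @export
write_cluster <- function(clust, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(ape::as.phylo(clust$genes), file.path(dir, "genes.nwk"))
  ape::write.tree(ape::as.phylo(clust$samples), file.path(dir, "samples.nwk"))
  tab <- data.table(contig = rownames(clust$table), clust$table)
  fwrite(tab, file.path(dir, "heatmap_table.tsv"), sep = "\t")
  invisible(dir)
}
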