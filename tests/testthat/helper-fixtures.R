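# Shared fixtures, built in code at test time.

# a small seeded study: reference, planted variants, plans, reads
make_small_study <- function(seed = 11L, n_transcripts = 6L,
                             reads_per_sample = 400L,
                             n_per_class = c(shared_polymorphism = 2L,
                                             group_exclusive_fixed = 2L,
                                             group_exclusive_polymorphic = 2L),
                             sub_rate = 0.002, indel_rate = 5e-4, ...) {
  ref <- generate_reference(n_transcripts, length_mean = 320, seed = seed)
  truth <- plant_variants(ref, n_per_class = n_per_class, seed = seed, ...)
  plans <- sample_plans(ref, reads_per_sample = reads_per_sample,
                        sub_rate = sub_rate, indel_rate = indel_rate,
                        seed = seed)
  reads <- simulate_reads(ref, truth, plans, seed = seed)
  list(ref = ref, truth = truth, plans = plans, reads = reads,
       groups = setNames(reads$manifest$group, reads$manifest$sample_id))
}

# hand-built sample plan with explicit weights (bypasses abundance draws)
manual_plan <- function(sample_id, group, n_reads, weights,
                        read_len_mean = 120, read_len_sd = 20,
                        read_len_min = 40, sub_rate = 0, indel_rate = 0) {
  plans <- list(list(sample_id = sample_id, group = group,
                     n_reads = n_reads, read_len_mean = read_len_mean,
                     read_len_sd = read_len_sd, read_len_min = read_len_min,
                     sub_rate = sub_rate, indel_rate = indel_rate,
                     weights = weights))
  class(plans) <- "sample_plan_set"
  plans
}

# hand-built reference set from explicit sequences
manual_reference <- function(seqs, cds_start = NULL, cds_end = NULL) {
  ids <- names(seqs)
  n <- length(seqs)
  info <- data.table::data.table(
    id = ids, length = nchar(seqs),
    cds_start = if (is.null(cds_start)) rep(NA_integer_, n) else cds_start,
    cds_end = if (is.null(cds_end)) rep(NA_integer_, n) else cds_end,
    is_coding = if (is.null(cds_start)) rep(FALSE, n) else !is.na(cds_start))
  structure(list(seq = seqs, info = info), class = "reference_set")
}

# hand-built pileup rows (counts default 0)
pileup_rows <- function(...) {
  dt <- data.table::rbindlist(list(...), fill = TRUE)
  for (col in c("A", "C", "G", "T", "gap")) {
    if (!col %in% names(dt)) dt[, (col) := 0L]
    data.table::set(dt, which(is.na(dt[[col]])), col, 0L)
  }
  dt[, depth := A + C + G + T + gap]
  data.table::setattr(dt, "class",
                      c("pileup_table", "data.table", "data.frame"))
  dt[]
}

# log-scale expression matrix with variances drawn from a scaled
# inverse chi-square prior (d0, s0_sq); optional mean shift for group 1
sim_log_expr <- function(n_genes, d0, s0_sq, n1 = 4, n2 = 3, seed = 1,
                         delta = NULL) {
  set.seed(seed)
  s2 <- if (is.infinite(d0)) rep(s0_sq, n_genes) else
    d0 * s0_sq / rchisq(n_genes, df = d0)
  m <- matrix(rnorm(n_genes * (n1 + n2), 0, sqrt(s2)), n_genes, n1 + n2)
  if (!is.null(delta)) m[, seq_len(n1)] <- m[, seq_len(n1)] + delta
  list(m = m, groups = rep(c("AO", "LM"), c(n1, n2)), s2 = s2)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# introduce e random substitutions into a string
mutate_string <- function(x, e) {
  if (e == 0) return(x)
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), e)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
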