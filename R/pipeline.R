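# End-to-end orchestration: simulate -> qc -> align -> snps -> express ->
# stats, with one master seed, per-stage logging, config-hash stamping and
# hash-validated stage caching.

#' Default pipeline configuration (toy scale)
#'
#' A small two-group study that runs end-to-end in well under a minute: 20
#' transcripts, 7 samples (4 AO / 3 LM), 5,000 reads per sample, planted
#' variants of every class including one single-base indel, and expression
#' effects spanning 2x to 200x.  QC thresholds are scaled to the toy read
#' counts; [qc_samples()] defaults document the study-scale values.
#'
#' @param seed master seed.
#' @return nested configuration list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    synthio = list(
      n_transcripts = 20L, length_mean = 350, length_sd = 120,
      length_min = 150, cds_fraction = 0.7, gc = 0.45,
      variants = list(n_per_class = c(shared_polymorphism = 8L,
                                      group_exclusive_fixed = 6L,
                                      group_exclusive_polymorphic = 6L),
                      n_indel = 1L, freq_shared = 0.5,
                      freq_polymorphic = 0.7),
      fold_changes = list(n_up = 3L, n_down = 3L, fc_range = c(2, 200)),
      plans = list(n_ao = 4L, n_lm = 3L, reads_per_sample = 5000L,
                   read_len_mean = 187, read_len_sd = 60, read_len_min = 40,
                   sub_rate = 0.005, indel_rate = 0.002, abundance_sd = 1)),
    alignkit = list(k = 15L, min_identity = 0.90, match_score = 10,
                    mismatch_penalty = 20, gap_open = 20, gap_extend = 5,
                    max_gap = 15),
    variantcall = list(min_depth = 10L, min_allele_reads = 2L,
                       low = 0.25, high = 0.75, mode = "per_allele",
                       min_present = 2L),
    expressdiff = list(fc_tiers = c(2, 8), q_threshold = 0.05,
                       fc_pseudo = 0.1),
    qc = list(min_reads = 1000L, min_mean_len = 100))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = cfg$seed %||% 1L)
  cfg <- modifyList(unclass(base), cfg)
  # YAML maps/sequences come back as lists; restore the vector-valued fields
  cfg$synthio$variants$n_per_class <-
    unlist(cfg$synthio$variants$n_per_class)
  cfg$synthio$fold_changes$fc_range <-
    unlist(cfg$synthio$fold_changes$fc_range)
  cfg$synthio$plans$reads_per_sample <-
    as.integer(unlist(cfg$synthio$plans$reads_per_sample))
  cfg$expressdiff$fc_tiers <- unlist(cfg$expressdiff$fc_tiers)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # named vectors serialize as YAML maps
  cfg$synthio$variants$n_per_class <-
    as.list(cfg$synthio$variants$n_per_class)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Per-sample sequencing QC
#'
#' Reports read count and mean read length per sample and fails samples
#' under the thresholds.  In the pipeline, failed samples are excluded from
#' the expression stage only; their reads still contribute to SNP calling.
#'
#' @param reads a `read_set`, or a manifest data.frame with `sample_id` and
#'   `path` columns pointing at FASTQ files.
#' @param min_reads minimum read count (study-scale default 60,000).
#' @param min_mean_len minimum mean read length in bp (default 150).
#' @return data.table: `sample_id`, `n_reads`, `mean_len`, `pass`.
#' @export
qc_samples <- function(reads, min_reads = 60000L, min_mean_len = 150) {
  stopifnot(min_reads > 0, min_mean_len > 0)
  if (inherits(reads, "read_set")) {
    per <- lapply(names(reads$samples), function(s) {
      x <- reads$samples[[s]]
      data.table(sample_id = s, n_reads = length(x),
                 mean_len = if (length(x)) mean(nchar(x)) else 0)
    })
  } else {
    stopifnot(all(c("sample_id", "path") %in% names(reads)))
    per <- lapply(seq_len(nrow(reads)), function(i) {
      x <- tryCatch(read_fastq(reads$path[i]), error = function(e)
        stop("cannot read reads for sample ", reads$sample_id[i], ": ",
             conditionMessage(e)))
      data.table(sample_id = reads$sample_id[i], n_reads = length(x),
                 mean_len = if (length(x)) mean(nchar(x)) else 0)
    })
  }
  out <- rbindlist(per)
  out[, pass := n_reads >= min_reads & mean_len >= min_mean_len]
  out[]
}

stage_log <- function(run_id, stage, ...) {
  message(sprintf("[%s] %s: %s", run_id, stage, sprintf(...)))
}

# stage cache: <outdir>/cache/<stage>.rds guarded by the config hash
stage_cached <- function(outdir, stage, hash, resume, compute) {
  cache <- file.path(outdir, "cache")
  if (!dir.exists(cache)) dir.create(cache, recursive = TRUE)
  rds <- file.path(cache, paste0(stage, ".rds"))
  marker <- file.path(cache, paste0(stage, ".hash"))
  if (resume && file.exists(rds) && file.exists(marker) &&
      identical(readLines(marker, warn = FALSE), hash)) {
    return(readRDS(rds))
  }
  value <- compute()
  saveRDS(value, rds)
  writeLines(hash, marker)
  value
}

#' Run the full pipeline
#'
#' Executes all stages in order under one master seed, writing every
#' artifact (FASTA reference, truth TSV/JSON, per-sample FASTQ and SAM,
#' pileup, VCF and SNP report TSV, count/RPKM matrices, DE tables, Newick
#' dendrograms, JSON + text report) under `outdir`, each stamped with the
#' configuration hash.  Reruns with an identical configuration are
#' bit-identical for the deterministic stages; with `resume = TRUE`, stages
#' whose cached output matches the current config hash are not recomputed.
#' A stage failure halts the run with the stage name; completed artifacts
#' are left in place.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param outdir run directory (created if needed).
#' @param resume reuse hash-valid cached stage outputs.
#' @return invisible list with all stage outputs and the `report`.
#' @export
run_pipeline <- function(config = default_config(), outdir, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- hash_config(unclass(config))
  run_id <- substr(hash, 1, 8)
  write_config(config, file.path(outdir, "config.yaml"))
  writeLines(c(sprintf("config_hash: %s", hash),
               sprintf("seed: %d", config$seed)),
             file.path(outdir, "run_stamp.txt"))
  seed <- config$seed
  stage <- "synthio"
  res <- tryCatch({
    ## --- synthio ------------------------------------------------------
    sim <- stage_cached(outdir, "synthio", hash, resume, function() {
      sy <- config$synthio
      reference <- generate_reference(
        sy$n_transcripts, sy$length_mean, sy$length_sd, sy$length_min,
        sy$cds_fraction, sy$gc, seed = seed)
      truth <- plant_variants(
        reference, n_per_class = sy$variants$n_per_class,
        n_indel = sy$variants$n_indel,
        freq_shared = sy$variants$freq_shared,
        freq_polymorphic = sy$variants$freq_polymorphic, seed = seed)
      truth$fold_change <- plant_fold_changes(
        reference, sy$fold_changes$n_up, sy$fold_changes$n_down,
        sy$fold_changes$fc_range, seed = seed)
      plans <- do.call(sample_plans, c(
        list(reference = reference, fold_change = truth$fold_change,
             seed = seed), sy$plans))
      reads <- simulate_reads(reference, truth, plans, seed = seed,
                              dir = file.path(outdir, "reads"))
      write_reference(reference, file.path(outdir, "reference.fasta"))
      write_truth(truth, tsv = file.path(outdir, "truth.tsv"),
                  json = file.path(outdir, "truth.json"))
      fwrite(reads$manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
      list(reference = reference, truth = truth, plans = plans,
           reads = reads)
    })
    stage_log(run_id, stage, "%d transcripts, %d planted variants, %d reads",
              nrow(sim$reference$info), nrow(sim$truth$variants),
              sum(sim$reads$manifest$n_reads))

    ## --- qc -----------------------------------------------------------
    stage <- "qc"
    qc <- qc_samples(sim$reads, config$qc$min_reads, config$qc$min_mean_len)
    fwrite(qc, file.path(outdir, "qc.tsv"), sep = "\t")
    stage_log(run_id, stage, "%d/%d samples pass (failures excluded from DE)",
              sum(qc$pass), nrow(qc))

    ## --- alignkit -----------------------------------------------------
    stage <- "alignkit"
    aln <- stage_cached(outdir, "alignkit", hash, resume, function() {
      ak <- config$alignkit
      index <- build_index(sim$reference, k = ak$k)
      params <- align_params(ak$min_identity, ak$match_score,
                             ak$mismatch_penalty, ak$gap_open,
                             ak$gap_extend, ak$max_gap)
      sam_dir <- file.path(outdir, "sam")
      if (!dir.exists(sam_dir)) dir.create(sam_dir)
      per_sample <- lapply(names(sim$reads$samples), function(s) {
        a <- align_reads(sim$reads$samples[[s]], index, sim$reference,
                         params, sample_id = s)
        write_sam(a, sim$reference, file.path(sam_dir, paste0(s, ".sam")))
        a
      })
      names(per_sample) <- names(sim$reads$samples)
      per_sample
    })
    n_aligned <- sum(vapply(aln, function(a) nrow(a$alignments), 1L))
    n_total <- sum(sim$reads$manifest$n_reads)
    stage_log(run_id, stage, "%d/%d reads aligned (%s)", n_aligned, n_total,
              format_percent(n_aligned, n_total))

    ## --- variantcall --------------------------------------------------
    stage <- "variantcall"
    groups <- setNames(sim$reads$manifest$group, sim$reads$manifest$sample_id)
    snps <- stage_cached(outdir, "variantcall", hash, resume, function() {
      vc <- config$variantcall
      pileup <- build_pileup(aln, sim$reference)
      fwrite(pileup, file.path(outdir, "pileup.tsv"), sep = "\t")
      out <- call_snps(pileup, groups, sim$reference, vc$min_depth,
                       vc$min_allele_reads, vc$low, vc$high, vc$mode,
                       vc$min_present)
      gs <- out$classified[classification == "group_exclusive"]
      write_vcf(out$classified, sim$reference, file.path(outdir, "snps.vcf"))
      write_snp_tsv(gs, file.path(outdir, "group_specific_snps.tsv"))
      out
    })
    stage_log(run_id, stage,
              "putative %d -> frequency-filtered %d -> group-exclusive %d",
              snps$counts[["putative"]], snps$counts[["filtered"]],
              snps$counts[["group_exclusive"]])

    ## --- expressdiff --------------------------------------------------
    stage <- "expressdiff"
    ex <- config$expressdiff
    keep_samples <- qc$sample_id[qc$pass]
    if (length(keep_samples) < 4L)
      stop("fewer than 4 samples pass QC; cannot test expression")
    counts <- count_matrix(aln, sim$reference)
    fwrite(data.table(contig = rownames(counts), counts),
           file.path(outdir, "counts.tsv"), sep = "\t")
    cnt_kept <- counts[, keep_samples, drop = FALSE]
    expr <- compute_rpkm(cnt_kept, sim$reference$info$length)
    fwrite(data.table(contig = rownames(expr$rpkm), round(expr$rpkm, 4)),
           file.path(outdir, "rpkm.tsv"), sep = "\t")
    de <- de_test(expr, groups[keep_samples], fc_pseudo = ex$fc_pseudo)
    fwrite(de, file.path(outdir, "de_results.tsv"), sep = "\t")
    tiers <- lapply(ex$fc_tiers, function(th) fold_change_tier(de, th))
    names(tiers) <- paste0("fold", ex$fc_tiers)
    top <- copy(tiers[[length(tiers)]])
    # FDR within the top tier: the narrowed candidate list is what gets
    # multiplicity-corrected
    top[, q_value := bh_adjust(p_value)]
    sig <- top[q_value < ex$q_threshold]
    fwrite(top[order(q_value)], file.path(outdir, "de_top_tier.tsv"),
           sep = "\t")
    clust <- NULL
    keep_ids <- top$contig
    if (length(keep_ids) >= 2L) {
      clust <- cluster_expression(expr$log2rpkm[keep_ids, , drop = FALSE])
      write_cluster(clust, file.path(outdir, "cluster"))
    }
    de_tiers <- c(vapply(tiers, nrow, 1L), significant = nrow(sig))
    stage_log(run_id, stage, "tested %d contigs; tiers: %s", nrow(de),
              paste(names(de_tiers), de_tiers, sep = "=", collapse = ", "))

    ## --- divstats -----------------------------------------------------
    stage <- "divstats"
    gs <- snps$classified[classification == "group_exclusive"]
    n_gs <- nrow(gs)
    poly_ao <- sum(gs$subtype == "polymorphic_in_AO")
    poly_lm <- sum(gs$subtype == "polymorphic_in_LM")
    fisher <- NULL
    if (n_gs > 0) {
      tab <- matrix(c(poly_ao, n_gs - poly_ao, poly_lm, n_gs - poly_lm),
                    2, 2, byrow = TRUE,
                    dimnames = list(c("AO", "LM"),
                                    c("polymorphic", "not_polymorphic")))
      fisher <- list(table = tab, p = fisher_exact_two_sided(tab))
    }
    overlap <- snp_de_overlap(unique(gs$tx), sig$contig)
    subtype_counts <- if (n_gs) table(gs$subtype) else NULL
    report <- pipeline_report(
      total_reads = n_total, aligned_reads = n_aligned,
      n_putative = snps$counts[["putative"]],
      n_filtered = snps$counts[["filtered"]],
      n_group_specific = n_gs, n_loci = length(unique(gs$tx)),
      subtype_counts = subtype_counts, de_tiers = de_tiers,
      overlap = overlap, fisher = fisher, run_id = run_id, seed = seed)
    write_report(report, json = file.path(outdir, "report.json"),
                 txt = file.path(outdir, "report.txt"))
    stage_log(run_id, stage, "report written")

    list(config = config, hash = hash, reference = sim$reference,
         truth = sim$truth, reads = sim$reads, qc = qc, alignments = aln,
         snps = snps, expression = expr, de = de, tiers = tiers,
         de_top = top, significant = sig, cluster = clust, report = report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
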