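# Text-format readers/writers for the pipeline's artifacts.  Sequence formats
# go through Biostrings; VCF and SAM records are plain text emitted field by
# field (and round-trip checked in the test suite).

#' Write a reference set as FASTA
#'
#' CDS coordinates, when present, are stored in the description as
#' `cds=start-end` (1-based, inclusive) so the file round-trips through
#' [read_reference()].
#'
#' @param reference a `reference_set`.
#' @param path output FASTA path.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "reference_set"))
  info <- reference$info
  desc <- ifelse(info$is_coding,
                 sprintf("%s cds=%d-%d", info$id, info$cds_start + 1L,
                         info$cds_end),
                 info$id)
  x <- Biostrings::DNAStringSet(reference$seq)
  names(x) <- desc
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' @param path FASTA path; `cds=start-end` descriptions (1-based, inclusive)
#'   are parsed back into CDS coordinates.
#' @return a `reference_set`.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  cds <- regmatches(full, regexpr("cds=\\d+-\\d+", full))
  cds_start <- rep(NA_integer_, length(x))
  cds_end <- rep(NA_integer_, length(x))
  has <- grepl("cds=\\d+-\\d+", full)
  if (any(has)) {
    nums <- regmatches(full[has], gregexpr("\\d+", sub(".*cds=", "", full[has])))
    cds_start[has] <- vapply(nums, function(v) as.integer(v[1]), 1L) - 1L
    cds_end[has] <- vapply(nums, function(v) as.integer(v[2]), 1L)
  }
  seqs <- as.character(x)
  names(seqs) <- ids
  out <- list(seq = seqs,
              info = data.table(id = ids, length = nchar(seqs),
                                cds_start = cds_start, cds_end = cds_end,
                                is_coding = has))
  class(out) <- "reference_set"
  out
}

#' Write reads as FASTQ with constant Q30 qualities
#'
#' @param seqs named character vector of read sequences.
#' @param path output path (`.gz` suffix enables gzip).
#' @export
write_fastq <- function(seqs, path) {
  qual <- strrep("?", nchar(seqs))  # '?' is Q30 in Sanger encoding
  rec <- rbind(paste0("@", names(seqs)), unname(seqs), "+", unname(qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rec), con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of sequences
#' @param path FASTQ path (optionally gzipped).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTQ: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a truth set as TSV (1-based positions) and JSON
#'
#' @param truth a `truth_set`.
#' @param tsv,json output paths (either may be NULL to skip).
#' @export
write_truth <- function(truth, tsv = NULL, json = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  v <- copy(truth$variants)
  v[, pos := pos + 1L]  # 1-based in files
  setnames(v, "pos", "position")
  if (!is.null(tsv)) fwrite(v, tsv, sep = "\t")
  if (!is.null(json)) {
    jsonlite::write_json(
      list(variants = v, fold_change = truth$fold_change, seed = truth$seed),
      json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(truth)
}

#' Write SNP sites as a minimal VCF
#'
#' One record per site; group evidence is carried in INFO
#' (`AOALLELES`, `LMALLELES`, `CLASS`, `SUBTYPE`, `EFFECT`) and per-group
#' allele depths in the `AO`/`LM` sample columns (`AD` over REF,ALT order).
#' Deletion alleles are encoded with the anchor base preceding the gap,
#' per VCF convention.
#'
#' @param sites a `snp_table` (see [classify_group_specific()]).
#' @param reference the `reference_set` the sites were called against.
#' @param path output VCF path.
#' @export
write_vcf <- function(sites, reference, path) {
  s <- as.data.table(sites)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$info$id,
            reference$info$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total raw read depth\">",
    "##INFO=<ID=AOALLELES,Number=1,Type=String,Description=\"Alleles present in AO\">",
    "##INFO=<ID=LMALLELES,Number=1,Type=String,Description=\"Alleles present in LM\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Group-specificity classification\">",
    "##INFO=<ID=SUBTYPE,Number=1,Type=String,Description=\"Group-exclusive subtype\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "AO", "LM"), collapse = "\t"))
  if (nrow(s) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  dot <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)
  ao_cnt <- site_allele_counts(s, "AO")
  lm_cnt <- site_allele_counts(s, "LM")
  recs <- vapply(seq_len(nrow(s)), function(i) {
    row <- s[i]
    site_alleles <- strsplit(row$alleles, ",")[[1]]
    alts <- setdiff(site_alleles, row$major)
    has_gap <- "-" %in% site_alleles
    pos1 <- row$pos + 1L
    refal <- row$major
    if (has_gap && row$pos > 0) {
      # left-anchor the deletion on the previous reference base
      anchor <- substr(reference$seq[[row$tx]], row$pos, row$pos)
      refal <- paste0(anchor, row$major)
      alts <- ifelse(alts == "-", anchor, paste0(anchor, alts))
      pos1 <- row$pos  # anchor base position, 1-based
    } else if (has_gap) {
      alts[alts == "-"] <- "*"
    }
    ad <- function(cnt) paste(cnt[c(row$major, setdiff(site_alleles,
                                                       row$major))],
                              collapse = ",")
    info <- sprintf(
      "DP=%d;AOALLELES=%s;LMALLELES=%s;CLASS=%s;SUBTYPE=%s;EFFECT=%s",
      row$depth, dot(gsub(",", "/", row$present_AO)),
      dot(gsub(",", "/", row$present_LM)), dot(row$classification),
      dot(row$subtype),
      dot(if ("coding_effect" %in% names(row)) row$coding_effect else NA))
    paste(c(row$tx, pos1, ".", refal, paste(alts, collapse = ","), ".",
            "PASS", info, "AD", ad(ao_cnt[i, ]), ad(lm_cnt[i, ])),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write a table of classified SNP sites in the style of a per-locus report
#'
#' Columns: transcript, 1-based position, region (CDS/noncoding), the allele
#' sets seen in each group (comma-joined, e.g. `"A,G"` vs `"G"`), raw read
#' depth, classification, subtype and amino-acid change.
#'
#' @param sites a `snp_table`.
#' @param path output TSV path.
#' @export
write_snp_tsv <- function(sites, path) {
  s <- as.data.table(sites)
  out <- data.table(
    transcript = s$tx,
    position = s$pos + 1L,
    region = s$region,
    AO_alleles = s$present_AO,
    LM_alleles = s$present_LM,
    depth = s$depth,
    classification = s$classification,
    subtype = s$subtype,
    aa_change = s$aa_change)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits a minimal SAM 1.6 file: `@SQ` header lines plus one record per
#' aligned read.  CIGARs collapse match/mismatch to `M` and add soft clips
#' for unaligned read ends.
#'
#' @param alignments an `alignment_set`.
#' @param reference the `reference_set` aligned against.
#' @param path output SAM path.
#' @export
write_sam <- function(alignments, reference, path) {
  aln <- alignments$alignments
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", reference$info$id,
                   reference$info$length))
  if (nrow(aln) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  # collapse M/X to M, prepend/append soft clips
  sam_cigar <- function(cigar, clip5, clip3) {
    ops <- parse_cigar(cigar)
    ops$op[ops$op == "X"] <- "M"
    merged <- list()
    for (i in seq_len(nrow(ops))) {
      n <- length(merged)
      if (n > 0 && merged[[n]]$op == ops$op[i]) {
        merged[[n]]$len <- merged[[n]]$len + ops$len[i]
      } else merged[[n + 1]] <- list(op = ops$op[i], len = ops$len[i])
    }
    body <- paste(vapply(merged, function(o) paste0(o$len, o$op), ""),
                  collapse = "")
    paste0(if (clip5 > 0) paste0(clip5, "S") else "", body,
           if (clip3 > 0) paste0(clip3, "S") else "")
  }
  cig <- vapply(seq_len(nrow(aln)), function(i)
    sam_cigar(aln$cigar[i], aln$clip5[i], aln$clip3[i]), "")
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  recs <- paste(aln$read_id, flag, aln$tx, aln$start + 1L, 255L, cig,
                "*", 0L, 0L, aln$oriented_seq, "*",
                sprintf("AS:i:%d", aln$score),
                sprintf("XI:f:%.4f", aln$identity), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}
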