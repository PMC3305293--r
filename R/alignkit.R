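# Seed-and-extend read alignment against a transcript reference.
#
# Reads are anchored by exact k-mer seeds (default k = 15, the specific match
# size) looked up in an index of the forward reference strand; both read
# orientations are seeded.  Each candidate (transcript, strand, diagonal
# range) is extended with a local affine-gap Smith-Waterman restricted to a
# reference window around the seeded diagonals, and the best-scoring
# extension is kept if it clears the percent-identity threshold (default
# 0.90) and the per-gap length cap (default 15).

#' Alignment scoring and filtering parameters
#'
#' @param min_identity minimum fraction of matching columns over the aligned
#'   region (soft-clipped ends excluded); comparison is inclusive.
#' @param match_score,mismatch_penalty per-column scores (penalty is
#'   subtracted).
#' @param gap_open,gap_extend affine gap costs: a gap of length L costs
#'   `gap_open + L * gap_extend`, so a 1-bp gap (25) outscores no mismatch
#'   (20).
#' @param max_gap maximum length of any single gap; longer-gapped candidates
#'   are rejected.
#' @param band_pad reference window padding (bp) around the seeded diagonal
#'   range during extension.
#' @return a list of class `align_params`.
#' @export
align_params <- function(min_identity = 0.90, match_score = 10,
                         mismatch_penalty = 20, gap_open = 20,
                         gap_extend = 5, max_gap = 15, band_pad = 30) {
  stopifnot(min_identity >= 0, min_identity <= 1, match_score > 0,
            mismatch_penalty >= 0, gap_open >= 0, gap_extend >= 0,
            max_gap >= 1, band_pad >= 0)
  structure(list(min_identity = min_identity, match_score = match_score,
                 mismatch_penalty = mismatch_penalty, gap_open = gap_open,
                 gap_extend = gap_extend, max_gap = max_gap,
                 band_pad = band_pad),
            class = "align_params")
}

#' Build a k-mer seed index over a reference set
#'
#' Indexes every k-mer occurrence of every transcript (forward strand).
#'
#' @param reference a `reference_set`.
#' @param k seed length in bp (>= 8 and at most the shortest transcript).
#' @return a `seed_index`.
#' @export
build_index <- function(reference, k = 15L) {
  stopifnot(inherits(reference, "reference_set"))
  if (k < 8) stop("seed length k must be >= 8")
  if (k > min(reference$info$length))
    stop("k exceeds the shortest transcript length")
  hits <- rbindlist(lapply(seq_along(reference$seq), function(i) {
    s <- reference$seq[[i]]
    n <- nchar(s) - k + 1L
    data.table(kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
               tx_idx = i, hit_pos = seq_len(n) - 1L)  # 0-based
  }))
  setkey(hits, kmer)
  structure(list(k = as.integer(k), hits = hits,
                 ids = reference$info$id, lengths = reference$info$length),
            class = "seed_index")
}

#' Look up a k-mer in a seed index
#'
#' @param index a `seed_index`.
#' @param kmer a character scalar of length `index$k`.
#' @return data.table with `tx` (transcript id) and `pos` (0-based offset);
#'   zero rows when the k-mer does not occur.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"), nchar(kmer) == index$k)
  query <- data.table(kmer = kmer)
  h <- index$hits[query, on = "kmer", nomatch = NULL]
  data.table(tx = index$ids[h$tx_idx], pos = h$hit_pos)
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  data.table(op = ops, len = lens)
}

max_gap_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  g <- ops$len[ops$op %in% c("I", "D")]
  if (length(g)) max(g) else 0L
}

cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "X", "D")])
}

# seed offsets for a read: a handful of k-mer positions spread over the read,
# always including the first and last
seed_offsets <- function(len, k) {
  n <- len - k + 1L
  if (n <= 1L) return(if (n == 1L) 1L else integer())
  stride <- max(1L, (n - 1L) %/% 9L)
  unique(c(seq.int(1L, n, by = stride), n))
}

#' Align reads to a reference through a seed index
#'
#' Returns the best-scoring extension over both strands for each read;
#' exact score ties break to the lowest transcript id, then lowest start,
#' then forward strand.  A read is reported unaligned when no candidate
#' reaches `min_identity` or every candidate contains a gap longer than
#' `max_gap`.
#'
#' @param reads named character vector of read sequences.
#' @param index a `seed_index` built from `reference`.
#' @param reference the `reference_set`.
#' @param params an [align_params()] list.
#' @param sample_id optional sample label stored with each alignment.
#' @return an `alignment_set`: list with `alignments` (one row per aligned
#'   read: `read_id`, `sample_id`, `tx`, `start` 0-based, `strand`, `score`,
#'   `identity`, `cigar` with explicit `M`/`X`/`I`/`D` ops, `clip5`, `clip3`,
#'   `oriented_seq`), `unaligned` (read ids) and `params`.
#' @export
align_reads <- function(reads, index, reference, params = align_params(),
                        sample_id = NA_character_) {
  stopifnot(inherits(index, "seed_index"), inherits(reference, "reference_set"),
            inherits(params, "align_params"))
  if (length(reads) == 0)
    return(structure(list(alignments = empty_alignments(),
                          unaligned = character(), params = params),
                     class = "alignment_set"))
  if (any(!nzchar(reads))) stop("empty read sequence")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  k <- index$k
  lens <- nchar(reads)
  oriented <- list("+" = unname(reads), "-" = reverse_complement(reads))

  # seed lookups for both orientations
  seeds <- rbindlist(lapply(c("+", "-"), function(str) {
    offs <- lapply(lens, seed_offsets, k = k)
    nn <- lengths(offs)
    if (sum(nn) == 0) return(NULL)
    dt <- data.table(read_idx = rep(seq_along(reads), nn),
                     offset = unlist(offs), strand = str)
    dt[, kmer := substring(oriented[[str]][read_idx], offset, offset + k - 1L)]
    dt
  }))
  hits <- index$hits[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  results <- vector("list", length(reads))
  if (nrow(hits) > 0) {
    hits[, diag_ := hit_pos - (offset - 1L)]
    cand <- hits[, .(n_votes = .N, dmin = min(diag_), dmax = max(diag_)),
                 by = .(read_idx, strand, tx_idx)]
    setorder(cand, read_idx, -n_votes, tx_idx, strand)
    cand <- cand[, head(.SD, 4L), by = read_idx]
    c_ri <- cand$read_idx; c_tx <- cand$tx_idx; c_str <- cand$strand
    c_dmin <- cand$dmin; c_dmax <- cand$dmax
    for (i in seq_along(c_ri)) {
      ri <- c_ri[i]
      rl <- lens[ri]
      prev <- results[[ri]]
      if (!is.null(prev) && prev$score >= rl * params$match_score)
        next  # already a full-length perfect extension; no candidate beats it
      tx_i <- c_tx[i]
      str <- c_str[i]
      tl <- index$lengths[tx_i]
      # fast path: single seeded diagonal, read matches the reference exactly
      if (c_dmin[i] == c_dmax[i] && c_dmin[i] >= 0L &&
          c_dmin[i] + rl <= tl &&
          substr(reference$seq[[tx_i]], c_dmin[i] + 1L, c_dmin[i] + rl) ==
            oriented[[str]][ri]) {
        score <- rl * params$match_score
        start <- c_dmin[i]
        if (is.null(prev) || score > prev$score ||
            (score == prev$score && (tx_i < prev$tx_idx ||
              (tx_i == prev$tx_idx && (start < prev$start ||
                (start == prev$start && str == "+" &&
                   prev$strand == "-")))))) {
          results[[ri]] <- list(
            read_id = names(reads)[ri], sample_id = sample_id,
            tx = index$ids[tx_i], tx_idx = tx_i, start = start,
            strand = str, score = score, identity = 1,
            cigar = paste0(rl, "M"), clip5 = 0L, clip3 = 0L,
            oriented_seq = oriented[[str]][ri])
        }
        next
      }
      ws <- max(0L, c_dmin[i] - params$band_pad)
      we <- min(tl, c_dmax[i] + rl + params$band_pad)
      if (we - ws < k) next
      win <- substr(reference$seq[[tx_i]], ws + 1L, we)
      al <- .sw_align(oriented[[str]][ri], win,
                      match = params$match_score,
                      mismatch = -params$mismatch_penalty,
                      gap_open = params$gap_open,
                      gap_extend = params$gap_extend)
      if (al$n_cols == 0) next
      identity <- al$n_match / al$n_cols
      if (identity < params$min_identity) next
      if (grepl("[ID]", al$cigar) && max_gap_len(al$cigar) > params$max_gap)
        next
      start <- ws + al$ref_start
      if (!is.null(prev)) {
        better <- al$score > prev$score ||
          (al$score == prev$score && (tx_i < prev$tx_idx ||
            (tx_i == prev$tx_idx && (start < prev$start ||
              (start == prev$start && str == "+" && prev$strand == "-")))))
        if (!better) next
      }
      results[[ri]] <- list(
        read_id = names(reads)[ri], sample_id = sample_id,
        tx = index$ids[tx_i], tx_idx = tx_i, start = start, strand = str,
        score = al$score, identity = identity, cigar = al$cigar,
        clip5 = al$read_start, clip3 = rl - al$read_end,
        oriented_seq = oriented[[str]][ri])
    }
  }
  aligned <- rbindlist(results[!vapply(results, is.null, TRUE)])
  if (nrow(aligned) == 0) aligned <- empty_alignments()
  aligned[, tx_idx := NULL]
  unaligned <- setdiff(names(reads), aligned$read_id)
  structure(list(alignments = aligned, unaligned = unaligned,
                 params = params),
            class = "alignment_set")
}

empty_alignments <- function() {
  data.table(read_id = character(), sample_id = character(), tx = character(),
             tx_idx = integer(), start = integer(), strand = character(),
             score = integer(), identity = numeric(), cigar = character(),
             clip5 = integer(), clip3 = integer(), oriented_seq = character())
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read a single read sequence (character scalar).
#' @return one-row alignment data.table, or NULL when unaligned.
#' @export
align_read <- function(read, index, reference, params = align_params()) {
  stopifnot(is.character(read), length(read) == 1L)
  if (!nzchar(read)) stop("empty read sequence")
  res <- align_reads(c(query = read), index, reference, params)
  if (nrow(res$alignments) == 0) NULL else res$alignments
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d aligned, %d unaligned\n",
              nrow(x$alignments), length(x$unaligned)))
  invisible(x)
}

#' Build per-sample pileups from alignments
#'
#' Walks each alignment's operations: match/mismatch columns contribute the
#' read base at the reference position, deletions contribute gap counts at
#' the deleted reference positions, and insertions are excluded from columns
#' (kept in the `insertions` attribute).
#'
#' @param alignments an `alignment_set` or a list of them (one per sample).
#' @param reference the `reference_set`.
#' @return a `pileup_table` data.table: `tx`, `pos` (0-based), `sample_id`,
#'   counts `A`, `C`, `G`, `T`, `gap`, and `depth`; attribute `insertions`
#'   holds a data.table of insertion events.
#' @export
build_pileup <- function(alignments, reference) {
  if (inherits(alignments, "alignment_set")) alignments <- list(alignments)
  aln <- rbindlist(lapply(alignments, `[[`, "alignments"))
  stopifnot(inherits(reference, "reference_set"))
  samples <- unique(aln$sample_id)
  if (length(samples) == 0 || nrow(aln) == 0) {
    out <- data.table(tx = character(), pos = integer(), sample_id = character(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), gap = integer(), depth = integer())
    setattr(out, "class", c("pileup_table", class(out)))
    return(out)
  }
  lens <- reference$info$length
  offsets <- c(0L, cumsum(lens))  # global coordinate per transcript
  tx_idx <- match(aln$tx, reference$info$id)
  if (anyNA(tx_idx)) stop("alignment references unknown transcript")
  span <- vapply(aln$cigar, cigar_ref_span, 1L)
  if (any(aln$start + span > lens[tx_idx]))
    stop("alignment extends past transcript end")
  qseq <- substr(aln$oriented_seq, aln$clip5 + 1L,
                 nchar(aln$oriented_seq) - aln$clip3)
  tal <- .pileup_tally(tx_idx, aln$start, match(aln$sample_id, samples),
                       aln$cigar, qseq, offsets[seq_along(lens)] ,
                       sum(lens), length(samples))
  gp <- tal$gpos
  which_tx <- findInterval(gp, offsets[-1], left.open = FALSE) + 1L
  out <- data.table(
    tx = reference$info$id[which_tx],
    pos = gp - offsets[which_tx],
    sample_id = samples[tal$sample],
    A = tal$A, C = tal$C, G = tal$G, T = tal$T, gap = tal$gap)
  out[, depth := A + C + G + T + gap]
  setorder(out, tx, pos, sample_id)
  ins <- data.table(gpos = tal$ins_gpos, sample_idx = tal$ins_sample,
                    len = tal$ins_len)
  if (nrow(ins)) {
    wt <- findInterval(ins$gpos, offsets[-1], left.open = FALSE) + 1L
    ins <- data.table(tx = reference$info$id[wt], pos = ins$gpos - offsets[wt],
                      sample_id = samples[ins$sample_idx], len = ins$len)
  } else {
    ins <- data.table(tx = character(), pos = integer(),
                      sample_id = character(), len = integer())
  }
  setattr(out, "insertions", ins)
  setattr(out, "class", c("pileup_table", "data.table", "data.frame"))
  out
}
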