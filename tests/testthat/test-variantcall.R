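groups2 <- c(s1 = "AO", s2 = "LM")

test_that("putative SNP calling applies depth and allele-support floors", {
  # monomorphic column: no site
  p1 <- pileup_rows(list(tx = "t1", pos = 10L, sample_id = "s1", A = 50L))
  expect_equal(nrow(call_putative_snps(p1, groups2)), 0)
  # 1-read second allele is noise-suppressed
  p2 <- pileup_rows(list(tx = "t1", pos = 10L, sample_id = "s1",
                         A = 10L, G = 1L))
  expect_equal(nrow(call_putative_snps(p2, groups2)), 0)
  # two supported alleles, depth over floor
  p3 <- pileup_rows(
    list(tx = "t1", pos = 10L, sample_id = "s1", A = 6L, G = 2L),
    list(tx = "t1", pos = 10L, sample_id = "s2", A = 4L))
  s3 <- call_putative_snps(p3, groups2)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$depth, 12L)
  expect_equal(s3$major, "A")
  expect_equal(s3$alleles, "A,G")
  # depth floor
  expect_equal(nrow(call_putative_snps(p3, groups2, min_depth = 13L)), 0)
})

test_that("putative calls match a brute-force refilter on random columns", {
  set.seed(123)
  rows <- lapply(1:300, function(i) {
    cnt <- as.list(rpois(5, lambda = sample(c(0.3, 2, 8), 1)))
    names(cnt) <- c("A", "C", "G", "T", "gap")
    c(list(tx = "t1", pos = i, sample_id = sample(c("s1", "s2"), 1)), cnt)
  })
  pu <- do.call(pileup_rows, rows)
  got <- call_putative_snps(pu, groups2, min_depth = 10, min_allele_reads = 2)
  # brute force: pool counts per position, apply the definition directly
  pooled <- data.table::as.data.table(pu)[, .(A = sum(A), C = sum(C),
                                              G = sum(G), T = sum(T),
                                              gap = sum(gap)), by = pos]
  keep <- vapply(seq_len(nrow(pooled)), function(i) {
    v <- unlist(pooled[i, .(A, C, G, T, gap)])
    sum(v >= 2) >= 2 && sum(v) >= 10
  }, TRUE)
  expect_equal(sort(got$pos), sort(pooled$pos[keep]))
})

test_that("the allele-frequency window keeps intermediate fractions only", {
  mk <- function(a, g) pileup_rows(
    list(tx = "t1", pos = 5L, sample_id = "s1", A = a, G = g))
  s <- call_putative_snps(mk(30L, 70L), groups2)
  expect_equal(nrow(filter_frequency(s)), 1)       # f = 0.30 kept
  s5 <- call_putative_snps(mk(50L, 50L), groups2)
  expect_equal(nrow(filter_frequency(s5)), 1)      # f = 0.50 kept
  expect_error(filter_frequency(s, low = 0.8, high = 0.2), "low >= high")
  # sweep minor fraction over a grid against a direct interval test
  for (f10 in 1:9) {
    a <- as.integer(100 - f10 * 10); g <- as.integer(f10 * 10)
    st <- call_putative_snps(mk(a, g), groups2)
    kept <- nrow(filter_frequency(st)) == 1
    minor <- min(a, g) / 100
    expect_equal(kept, minor >= 0.25 && minor <= 0.75,
                 info = paste("f =", f10 / 10))
  }
  # boundaries are inclusive: exactly 25/75
  sb <- call_putative_snps(mk(25L, 75L), groups2)
  expect_equal(nrow(filter_frequency(sb)), 1)
})

test_that("multi-allelic sites need every minor allele inside the window", {
  p <- pileup_rows(list(tx = "t1", pos = 5L, sample_id = "s1",
                        A = 60L, G = 37L, T = 3L))
  s <- call_putative_snps(p, groups2)
  expect_equal(nrow(filter_frequency(s)), 0)          # T at 3% fails
  expect_equal(nrow(filter_frequency(s, mode = "total_nonref")), 1)  # 40%
})

test_that("classification matches the worked allele-profile examples", {
  # AO {A,G} vs LM {G}: polymorphism restricted to AO
  r <- classify_profiles(c(A = 10, G = 12), c(G = 15))
  expect_equal(r$classification, "group_exclusive")
  expect_equal(r$subtype, "polymorphic_in_AO")
  # AO {C} vs LM {T}: fixed divergence
  r <- classify_profiles(c(C = 20), c(T = 18))
  expect_equal(r$classification, "group_exclusive")
  expect_equal(r$subtype, "fixed_divergent")
  # same allele sets in both groups: nothing group-specific
  r <- classify_profiles(c(A = 5, G = 5), c(A = 7, G = 3))
  expect_equal(r$classification, "not_group_specific")
  # a single stray read neither creates nor destroys exclusivity
  r <- classify_profiles(c(A = 10, G = 12), c(G = 15, A = 1))
  expect_equal(r$classification, "not_group_specific")
  r <- classify_profiles(c(C = 20, T = 1), c(T = 18))
  expect_equal(r$classification, "group_exclusive")
  expect_equal(r$subtype, "fixed_divergent")
  # zero depth in one group: uncallable
  r <- classify_profiles(c(A = 10, G = 3), c())
  expect_equal(r$classification, "uncallable")
})

test_that("classification equals set-logic enumeration on all profile pairs", {
  alleles <- c("A", "C", "G", "T", "-")
  subsets <- c(lapply(alleles, identity),
               combn(alleles, 2, simplify = FALSE))  # sizes 1 and 2
  n_pairs <- 0
  for (sa in subsets) for (sl in subsets) {
    ao <- setNames(rep(5L, length(sa)), sa)
    lm <- setNames(rep(5L, length(sl)), sl)
    got <- classify_profiles(ao, lm)
    want <- oracle_classify(ao, lm)
    lab <- if (got$classification == "group_exclusive") got$subtype
           else got$classification
    expect_equal(lab, want,
                 info = paste("AO:", paste(sa, collapse = ""),
                              "LM:", paste(sl, collapse = "")))
    n_pairs <- n_pairs + 1
  }
  expect_equal(n_pairs, 225)
  # and with heterogeneous counts crossing the presence threshold
  set.seed(7)
  for (i in 1:125) {
    ao <- setNames(sample(0:6, 5, replace = TRUE), alleles)
    lm <- setNames(sample(0:6, 5, replace = TRUE), alleles)
    got <- classify_profiles(ao, lm)
    lab <- if (got$classification == "group_exclusive") got$subtype
           else got$classification
    expect_equal(lab, oracle_classify(ao, lm))
  }
})

test_that("swapping group labels mirrors the classification", {
  set.seed(17)
  for (i in 1:60) {
    ao <- setNames(sample(0:5, 5, replace = TRUE), c("A", "C", "G", "T", "-"))
    lm <- setNames(sample(0:5, 5, replace = TRUE), c("A", "C", "G", "T", "-"))
    r1 <- classify_profiles(ao, lm)
    r2 <- classify_profiles(lm, ao)
    expect_equal(r1$classification, r2$classification)
    map <- c(polymorphic_in_AO = "polymorphic_in_LM",
             polymorphic_in_LM = "polymorphic_in_AO",
             fixed_divergent = "fixed_divergent",
             polymorphic_in_both = "polymorphic_in_both")
    if (!is.na(r1$subtype)) expect_equal(unname(map[r1$subtype]), r2$subtype)
  }
})

test_that("no group-exclusive site has all alleles present in both groups", {
  st <- make_small_study(seed = 301, reads_per_sample = 300L,
                         n_per_class = c(shared_polymorphism = 3,
                                         group_exclusive_fixed = 3,
                                         group_exclusive_polymorphic = 3),
                         freq_polymorphic = 0.8)
  idx <- build_index(st$ref, k = 15)
  aln <- lapply(names(st$reads$samples), function(s)
    align_reads(st$reads$samples[[s]], idx, st$ref, sample_id = s))
  pu <- build_pileup(aln, st$ref)
  out <- call_snps(pu, st$groups, st$ref)
  # funnel nesting
  expect_lte(out$counts[["filtered"]], out$counts[["putative"]])
  expect_lte(out$counts[["group_exclusive"]], out$counts[["filtered"]])
  gs <- out$classified[classification == "group_exclusive"]
  for (i in seq_len(nrow(gs))) {
    pa <- strsplit(gs$present_AO[i], ",")[[1]]
    pl <- strsplit(gs$present_LM[i], ",")[[1]]
    ao_cnt <- unlist(gs[i, .(AO_A, AO_C, AO_G, AO_T, AO_gap)])
    lm_cnt <- unlist(gs[i, .(LM_A, LM_C, LM_G, LM_T, LM_gap)])
    names(ao_cnt) <- names(lm_cnt) <- c("A", "C", "G", "T", "-")
    expect_true(any(lm_cnt[pa] == 0) || any(ao_cnt[pl] == 0))
  }
})

test_that("coding effects follow the standard genetic code", {
  # CDS ATG GCA TAA starting at offset 3
  seqs <- c(cod = paste0("TTT", "ATGGCATAA", "GGG"))
  ref <- manual_reference(seqs, cds_start = 3L, cds_end = 12L)
  mk_site <- function(pos, major, alt) {
    p <- pileup_rows(
      list(tx = "cod", pos = pos, sample_id = "s1",
           A = 0L, C = 0L, G = 0L, T = 0L, gap = 0L))
    s <- data.table::data.table(
      tx = "cod", pos = pos, n_A = 0L, n_C = 0L, n_G = 0L, n_T = 0L,
      n_gap = 0L, AO_A = 0L, AO_C = 0L, AO_G = 0L, AO_T = 0L, AO_gap = 0L,
      LM_A = 0L, LM_C = 0L, LM_G = 0L, LM_T = 0L, LM_gap = 0L,
      depth = 20L, n_alleles = 2L,
      alleles = paste(major, alt, sep = ","), major = major)
    data.table::setattr(s, "class", c("snp_table", "data.table", "data.frame"))
    s
  }
  # codon 2 third base GCA->GCG: synonymous (both Ala)
  a <- annotate_coding_effect(mk_site(8L, "A", "G"), ref)
  expect_equal(a$coding_effect, "synonymous")
  expect_equal(a$region, "CDS")
  # codon 2 first base GCA->ACA: Ala -> Thr
  a <- annotate_coding_effect(mk_site(6L, "G", "A"), ref)
  expect_equal(a$coding_effect, "nonsynonymous")
  expect_equal(a$aa_change, "A->T")
  # gap allele in CDS: indel
  a <- annotate_coding_effect(mk_site(7L, "C", "-"), ref)
  expect_equal(a$coding_effect, "indel")
  # outside the CDS: noncoding
  a <- annotate_coding_effect(mk_site(1L, "T", "C"), ref)
  expect_equal(a$region, "noncoding")
  expect_equal(a$coding_effect, "noncoding")
  expect_error(annotate_coding_effect(mk_site(99L, "A", "C"), ref),
               "outside")
})

test_that("all nine single-base codon mutations match a codon-table oracle", {
  gc_table <- Biostrings::GENETIC_CODE
  codon <- "GAT"  # Asp
  seqs <- c(cod = paste0("ATG", codon, "TAA"))
  ref <- manual_reference(seqs, cds_start = 0L, cds_end = 9L)
  for (within in 1:3) {
    pos <- 3L + within - 1L
    refb <- substr(codon, within, within)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      got <- snpexpress:::codon_effect(seqs[["cod"]], 0L, pos, refb, alt)
      altcodon <- codon
      substr(altcodon, within, within) <- alt
      want <- if (gc_table[[codon]] == gc_table[[altcodon]]) "synonymous"
              else paste0(gc_table[[codon]], "->", gc_table[[altcodon]])
      expect_equal(got, want, info = paste(codon, within, alt))
    }
  }
})

test_that("classified sites export as parseable VCF", {
  st <- make_small_study(seed = 401, reads_per_sample = 300L,
                         n_per_class = c(group_exclusive_fixed = 3),
                         n_indel = 1)
  idx <- build_index(st$ref, k = 15)
  aln <- lapply(names(st$reads$samples), function(s)
    align_reads(st$reads$samples[[s]], idx, st$ref, sample_id = s))
  pu <- build_pileup(aln, st$ref)
  out <- call_snps(pu, st$groups, st$ref)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(out$classified, st$ref, vcf)
  v <- suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(out$classified))
  expect_true(all(grepl("CLASS=", v@fix[, "INFO"])))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_snp_tsv(out$classified[classification == "group_exclusive"], tsv)
  back <- data.table::fread(tsv)
  if (nrow(back))
    expect_true(all(c("transcript", "position", "AO_alleles", "LM_alleles",
                      "depth", "classification", "aa_change")
                    %in% names(back)))
})
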