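test_that("RPKM follows its defining formula and scale identities", {
  # unit-scale identity: 10 reads on a 1 kb contig in a 1e6-read library
  e <- compute_rpkm(matrix(10, 1, 1), lengths = 1000, totals = 1e6)
  expect_equal(unname(e$rpkm[1, 1]), 10)
  expect_equal(unname(compute_rpkm(matrix(0, 1, 1), 1000, 1e6)$rpkm[1, 1]), 0)
  expect_error(compute_rpkm(matrix(1, 1, 1), 1000, 0), "zero total")
  expect_error(compute_rpkm(matrix(1, 1, 1), 0, 1e6), "positive")

  set.seed(5)
  cnt <- matrix(rpois(200 * 6, 40), 200, 6)
  lens <- sample(200:2000, 200)
  tot <- colSums(cnt)
  e <- compute_rpkm(cnt, lens, tot)
  # elementwise against the long-form formula
  for (pick in sample(length(cnt), 50)) {
    g <- (pick - 1) %% 200 + 1; s <- (pick - 1) %/% 200 + 1
    expect_equal(e$rpkm[g, s], cnt[g, s] / (lens[g] / 1e3) / (tot[s] / 1e6))
  }
  # RPKM = 0 iff count = 0
  expect_identical(e$rpkm == 0, e$counts == 0)
  # doubling counts and totals leaves RPKM unchanged
  e2 <- compute_rpkm(2 * cnt, lens, 2 * tot)
  expect_equal(e2$rpkm, e$rpkm)
  # doubling a contig's length halves its RPKM
  lens2 <- lens; lens2[7] <- 2 * lens[7]
  e3 <- compute_rpkm(cnt, lens2, tot)
  expect_equal(e3$rpkm[7, ], e$rpkm[7, ] / 2)
  expect_equal(e3$rpkm[-7, ], e$rpkm[-7, ])
})

test_that("variance-prior fitting recovers known parameters", {
  sim <- sim_log_expr(5000, d0 = 4, s0_sq = 0.05, seed = 71)
  fit <- fit_moderated_params(sim$m, sim$groups)
  expect_lt(abs(fit$d0 - 4) / 4, 0.30)
  expect_lt(abs(fit$s0_sq - 0.05) / 0.05, 0.10)
  # equal variances: no excess spread, d0 infinite, s0 near the common value
  m <- matrix(rnorm(2000 * 7), 2000, 7)  # all true variances equal 1
  fit2 <- fit_moderated_params(m, rep(c("AO", "LM"), c(4, 3)))
  expect_true(is.infinite(fit2$d0) || fit2$d0 > 50)
  # shifting the data (doubling expression on the raw scale) changes nothing
  fit3 <- fit_moderated_params(sim$m + 1, sim$groups)
  expect_equal(fit3$d0, fit$d0)
  expect_equal(fit3$s0_sq, fit$s0_sq)
})

test_that("the fit agrees with limma's empirical-Bayes machinery", {
  suppressPackageStartupMessages(library(limma))
  sim <- sim_log_expr(1500, d0 = 6, s0_sq = 0.1, seed = 72)
  fit <- fit_moderated_params(sim$m, sim$groups)
  design <- model.matrix(~ factor(sim$groups, levels = c("LM", "AO")))
  lf <- eBayes(lmFit(sim$m, design))
  expect_lt(abs(fit$d0 - lf$df.prior) / lf$df.prior, 0.02)
  expect_lt(abs(fit$s0_sq - lf$s2.prior) / lf$s2.prior, 0.02)
  # moderated t for the group contrast matches limma's
  mine <- moderated_t_test(sim$m, sim$groups, fit)
  expect_lt(max(abs(abs(mine$t_stat) - abs(lf$t[, 2]))), 1e-6)
  expect_lt(max(abs(mine$p_value - lf$p.value[, 2])), 1e-8)
})

test_that("moderated t reduces to the ordinary t at d0 = 0", {
  sim <- sim_log_expr(100, d0 = 4, s0_sq = 0.05, seed = 73)
  res <- moderated_t_test(sim$m, sim$groups,
                          list(d0 = 0, s0_sq = 1))
  for (i in sample(100, 20)) {
    tt <- t.test(sim$m[i, sim$groups == "AO"], sim$m[i, sim$groups == "LM"],
                 var.equal = TRUE)
    expect_lt(abs(res$t_stat[i] - tt$statistic), 1e-10)
    expect_lt(abs(res$p_value[i] - tt$p.value), 1e-10)
  }
})

test_that("moderated t matches an independent re-derivation and its limits", {
  sim <- sim_log_expr(100, d0 = 4, s0_sq = 0.05, seed = 74)
  fit <- fit_moderated_params(sim$m, sim$groups)
  res <- moderated_t_test(sim$m, sim$groups, fit)
  o <- oracle_moderated_t(sim$m, sim$groups, fit$d0, fit$s0_sq)
  expect_lt(max(abs(res$t_stat - o[, "t"])), 1e-10)
  expect_lt(max(abs(res$p_value - o[, "p"])), 1e-10)
  # null point: equal group means, nonzero variance
  x <- matrix(rep(c(1, 2, 3, 1, 2, 3, 2), 1), 1, 7)
  g <- rep(c("AO", "LM"), c(4, 3))
  x[1, ] <- c(1, 2, 3, 2, 1, 2, 3)  # means: AO 2, LM 2
  r0 <- moderated_t_test(x, g, list(d0 = 0, s0_sq = 1))
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_value, 1)
  # d0 -> Inf: z-like statistic with the pooled prior variance
  rinf <- moderated_t_test(sim$m, sim$groups,
                           list(d0 = Inf, s0_sq = 0.05))
  se <- sqrt(0.05 * (1 / 4 + 1 / 3))
  st <- snpexpress:::row_group_stats(sim$m, sim$groups)
  expect_lt(max(abs(rinf$t_stat - (st$mean1 - st$mean2) / se)), 1e-10)
  expect_error(moderated_t_test(sim$m[, 1:5], rep(c("AO", "LM"), c(4, 1)),
                                fit), "at least 2")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:10) {
    p <- runif(50)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # order-invariance and rank monotonicity
  p <- runif(100)
  o <- sample(100)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("BH controls the null at its nominal level", {
  frac <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    mean(bh_adjust(runif(1000)) < 0.05)
  }, 1)
  expect_lte(mean(frac), 0.005)
})

test_that("fold-change tiers nest and respect the threshold", {
  r <- data.table::data.table(
    contig = c("a", "b", "c"), mean_AO = c(10, 5, 7), mean_LM = c(20, 5, 70),
    fc = c(2, 1, 10), t_stat = 0, p_value = 1, q_value = 1)
  data.table::setattr(r, "class", c("de_result", "data.table", "data.frame"))
  expect_equal(fold_change_tier(r, 2)$contig, c("a", "c"))
  expect_equal(fold_change_tier(r, 8)$contig, "c")
  expect_error(fold_change_tier(r, 1), "exceed 1")
  # direction-symmetric: FC 1/10 also passes tier 8
  r$fc[2] <- 0.1
  expect_true("b" %in% fold_change_tier(r, 8)$contig)
  set.seed(31)
  r2 <- data.table::data.table(contig = letters[1:20], mean_AO = 1,
                               mean_LM = 1, fc = exp(rnorm(20, 0, 2)),
                               t_stat = 0, p_value = 1, q_value = 1)
  data.table::setattr(r2, "class", c("de_result", "data.table", "data.frame"))
  expect_true(all(fold_change_tier(r2, 8)$contig %in%
                    fold_change_tier(r2, 2)$contig))
})

test_that("moderated testing is competitive with the ordinary t in power", {
  groups <- rep(c("AO", "LM"), c(4, 3))
  sens <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    m <- matrix(rnorm(300 * 7, 0, 0.5), 300, 7)  # noise sd 0.5 log2 units
    de_idx <- 1:30
    m[de_idx, 1:4] <- m[de_idx, 1:4] + 3          # planted 8-fold effects
    fit <- fit_moderated_params(m, groups)
    q_mod <- bh_adjust(moderated_t_test(m, groups, fit)$p_value)
    q_ord <- bh_adjust(moderated_t_test(m, groups,
                                        list(d0 = 0, s0_sq = 1))$p_value)
    c(mod = mean(q_mod[de_idx] < 0.05), ord = mean(q_ord[de_idx] < 0.05))
  }, c(mod = 0, ord = 0))
  diff_mean <- mean(sens["mod", ] - sens["ord", ])
  expect_lte(abs(diff_mean), 0.1)
  expect_gte(diff_mean, -0.02)
})

test_that("centroid clustering matches brute-force agglomeration", {
  set.seed(61)
  pts <- matrix(rnorm(10), 5, 2,
                dimnames = list(paste0("g", 1:5), c("x", "y")))
  cl <- cluster_expression(pts)
  o <- oracle_centroid_cluster(pts)
  expect_equal(hclust_merge_sets(cl$genes), o$merges)
  expect_equal(cl$genes$height, o$heights, tolerance = 1e-9)
})

test_that("clustering is deterministic and permutation-equivariant", {
  set.seed(62)
  m <- matrix(rnorm(8 * 4), 8, 4,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
  # identical samples merge first at height zero
  m2 <- cbind(m, s5 = m[, "s2"])
  cl <- cluster_expression(m2)
  expect_equal(min(cl$samples$height), 0)
  first <- hclust_merge_sets(cl$samples)[[1]]
  expect_equal(sort(colnames(m2)[first]), c("s2", "s5"))
  # permuting columns permutes leaves but preserves merge heights
  perm <- c(3, 1, 4, 2)
  cl1 <- cluster_expression(m)
  cl2 <- cluster_expression(m[, perm])
  expect_equal(sort(cl1$samples$height), sort(cl2$samples$height))
  expect_equal(cl1$genes$height, cl2$genes$height)
  expect_error(cluster_expression(m[1, , drop = FALSE]), "at least 2")
  # constant matrix: flat clustering at height zero, no error
  cl0 <- cluster_expression(matrix(1, 4, 3))
  expect_true(all(cl0$genes$height == 0))
})

test_that("count matrices conserve aligned reads and feed the DE pipeline", {
  st <- make_small_study(seed = 501, reads_per_sample = 250L,
                         n_transcripts = 12L)
  idx <- build_index(st$ref, k = 15)
  aln <- lapply(names(st$reads$samples), function(s)
    align_reads(st$reads$samples[[s]], idx, st$ref, sample_id = s))
  cm <- count_matrix(aln, st$ref)
  expect_equal(unname(colSums(cm)),
               vapply(aln, function(a) nrow(a$alignments), 1L))
  expr <- compute_rpkm(cm, st$ref$info$length)
  de <- de_test(expr, st$groups)
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  expect_true(all(de$q_value <= 1 & de$fc > 0))
  # newick export round-trips through ape
  tier <- fold_change_tier(de, 2)
  if (nrow(tier) >= 2) {
    cl <- cluster_expression(expr$log2rpkm[tier$contig, , drop = FALSE])
    d <- withr::local_tempdir()
    write_cluster(cl, d)
    tr <- ape::read.tree(file.path(d, "genes.nwk"))
    expect_setequal(tr$tip.label, tier$contig)
  }
})
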