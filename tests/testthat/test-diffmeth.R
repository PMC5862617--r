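test_that("diff_score reproduces the log-p anchors and rejects bad p", {
  expect_equal(round(abs(diff_score(0.05, 1))), 13)
  expect_equal(diff_score(1, 0.5), 0)
  expect_equal(diff_score(0.001, -0.1), -30)
  expect_equal(diff_score(0.05, 0), 0)        # no direction, no score
  expect_error(diff_score(0, 0.1), "p-values")
  expect_error(diff_score(-0.5, 0.1), "p-values")
  expect_error(diff_score(1.5, 0.1), "p-values")
})

test_that("probe_diffmeth matches stats::t.test probe by probe", {
  set.seed(2)
  tg <- two_group_beta(mu1 = runif(20, 0.2, 0.8),
                       mu2 = runif(20, 0.2, 0.8), n_per_group = 6,
                       jitter = 0.05, seed = 2)
  rec <- probe_diffmeth(tg$m, tg$groups)
  for (i in seq_len(nrow(rec))) {
    x1 <- tg$m$beta[i, tg$groups$g1]
    x2 <- tg$m$beta[i, tg$groups$g2]
    tt <- stats::t.test(x1, x2, var.equal = FALSE)
    expect_equal(rec$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(rec$delta_beta[i], mean(x2) - mean(x1), tolerance = 1e-12)
  }
  expect_equal(sign(rec$diff_score[rec$delta_beta != 0]),
               sign(rec$delta_beta[rec$delta_beta != 0]))
})

test_that("a clear separation lands in the strongest tier (hand Welch oracle)", {
  g1 <- c(0.1, 0.1, 0.1) + c(0.001, -0.002, 0.0005)
  g2 <- c(0.9, 0.9, 0.9) + c(-0.001, 0.0015, 0.0008)
  b <- rbind(cg001 = c(g1, g2))
  colnames(b) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- BetaMatrix(b)
  rec <- probe_diffmeth(m, list(g1 = c("a1", "a2", "a3"),
                                g2 = c("b1", "b2", "b3")))
  # textbook Welch on the jittered values
  se2 <- var(g1) / 3 + var(g2) / 3
  tt <- (mean(g2) - mean(g1)) / sqrt(se2)
  df <- se2^2 / (var(g1)^2 / (9 * 2) + var(g2)^2 / (9 * 2))
  p_hand <- 2 * stats::pt(-abs(tt), df)
  expect_equal(rec$p_value, p_hand, tolerance = 1e-12)
  expect_equal(rec$delta_beta, mean(g2) - mean(g1), tolerance = 1e-12)
  expect_gt(rec$delta_beta, 0.79)
  expect_equal(rec$tier, "p001")
})

test_that("degenerate and swapped-label behavior follow the score's symmetry", {
  # identical groups: delta 0, tier ns, p = 1
  b <- matrix(0.4, 2, 6, dimnames = list(c("cg1", "cg2"), letters[1:6]))
  m <- BetaMatrix(b)
  rec <- probe_diffmeth(m, list(g1 = letters[1:3], g2 = letters[4:6]))
  expect_equal(rec$p_value, c(1, 1))
  expect_equal(rec$diff_score, c(0, 0))
  expect_equal(rec$tier, c("ns", "ns"))

  # antisymmetry: swapping group labels negates delta and score, keeps p
  tg <- two_group_beta(runif(10, 0.2, 0.8), runif(10, 0.2, 0.8),
                       n_per_group = 5, jitter = 0.03, seed = 9)
  fwd <- probe_diffmeth(tg$m, tg$groups)
  rev <- probe_diffmeth(tg$m, list(g1 = tg$groups$g2, g2 = tg$groups$g1))
  expect_equal(rev$delta_beta, -fwd$delta_beta)
  expect_equal(rev$diff_score, -fwd$diff_score)
  expect_equal(rev$p_value, fwd$p_value)

  expect_error(probe_diffmeth(tg$m, list(g1 = tg$groups$g1[1],
                                         g2 = tg$groups$g2)), ">= 2 samples")
})

test_that("tier thresholds map 13/22/33 to p05/p01/p001", {
  rec <- data.frame(delta_beta = c(0.1, 0.1, -0.1, 0.1),
                    diff_score = c(12.9, 13, -22, 35))
  expect_equal(islandmeth:::.score_tier(rec$diff_score),
               c("ns", "p05", "p01", "p001"))
})

test_that("tier_counts equals a brute-force recount and is monotone", {
  sim <- simulate_paired_dataset(sim_config(n_islands = 60, seed = 21))
  rec <- probe_diffmeth(sim$beta_450k, sim$groups_450k)
  tc <- tier_counts(rec)
  for (d in c("hyper", "hypo")) {
    sel <- if (d == "hyper") rec$delta_beta > 0 else rec$delta_beta < 0
    for (th in c(13, 22, 33)) {
      manual <- sum(abs(rec$diff_score[sel]) >= th)
      expect_equal(tc$count[tc$direction == d & tc$threshold == th], manual)
    }
    cnt <- tc$count[tc$direction == d]
    expect_true(all(diff(cnt) <= 0))
  }
  # all-null scores give zero counts; a single strong hyper probe counts once
  zero <- data.frame(delta_beta = c(0.1, -0.2), diff_score = c(0, 0))
  expect_true(all(tier_counts(zero)$count == 0))
  one <- data.frame(delta_beta = 0.3, diff_score = 35)
  tc1 <- tier_counts(one)
  expect_equal(tc1$count[tc1$direction == "hyper"], c(1L, 1L, 1L))
  expect_equal(tc1$count[tc1$direction == "hypo"], c(0L, 0L, 0L))
})

test_that("permutation FDR equals an independent brute-force loop on the same stream", {
  tg <- two_group_beta(runif(10, 0.3, 0.7), runif(10, 0.3, 0.7) + 0.1,
                       n_per_group = 4, jitter = 0.05, seed = 13)
  n_perm <- 20; seed <- 99; thresholds <- c(13, 22, 33)
  got <- permutation_fdr(tg$m, tg$groups, thresholds = thresholds,
                         n_perm = n_perm, seed = seed)

  # brute force via stats::t.test over the identical permutation stream
  b <- tg$m$beta[, c(tg$groups$g1, tg$groups$g2)]
  n1 <- length(tg$groups$g1)
  score_of <- function(cols1, cols2) {
    vapply(seq_len(nrow(b)), function(i) {
      x <- b[i, cols1]; y <- b[i, cols2]
      -10 * log10(stats::t.test(x, y, var.equal = FALSE)$p.value)
    }, numeric(1))
  }
  obs <- score_of(seq_len(n1), n1 + seq_len(ncol(b) - n1))
  set.seed(seed)
  null_counts <- matrix(0, n_perm, length(thresholds))
  for (i in seq_len(n_perm)) {
    idx <- sample(ncol(b))
    a <- score_of(idx[seq_len(n1)], idx[-seq_len(n1)])
    null_counts[i, ] <- vapply(thresholds, function(th) sum(a >= th), numeric(1))
  }
  expected <- pmin(colMeans(null_counts) /
                     pmax(vapply(thresholds, function(th) sum(obs >= th),
                                 numeric(1)), 1), 1)
  expected[vapply(thresholds, function(th) sum(obs >= th), numeric(1)) == 0] <- NA
  expect_equal(got$fdr, unname(expected), tolerance = 1e-10)
})

test_that("permutation FDR saturates on null data and vanishes for huge effects", {
  null <- simulate_paired_dataset(sim_config(n_islands = 80, frac_dm_islands = 0,
                                             seed = 31))
  fd <- permutation_fdr(null$beta_450k, null$groups_450k, thresholds = 13,
                        n_perm = 60, seed = 1)
  expect_gt(fd$fdr, 0.5)  # near 1: label structure carries no signal

  big <- two_group_beta(rep(0.1, 50), rep(0.9, 50), n_per_group = 5,
                        jitter = 0.02, seed = 5)
  fd2 <- permutation_fdr(big$m, big$groups, thresholds = 13, n_perm = 100,
                         seed = 1)
  expect_lt(fd2$fdr, 0.1)

  # FDR nonincreasing in the threshold on a mixed dataset
  mix <- simulate_paired_dataset(sim_config(n_islands = 60, seed = 17))
  fd3 <- permutation_fdr(mix$beta_450k, mix$groups_450k, n_perm = 50, seed = 2)
  ok <- !is.na(fd3$fdr)
  expect_true(all(diff(fd3$fdr[ok]) <= 1e-12))

  # no observed probe at an unreachable threshold: NA with warning
  flat <- two_group_beta(rep(0.5, 5), rep(0.5, 5), n_per_group = 3,
                         jitter = 0.01, seed = 3)
  expect_warning(fd4 <- permutation_fdr(flat$m, flat$groups, thresholds = 500,
                                        n_perm = 5, seed = 1), "NA")
  expect_true(is.na(fd4$fdr))
})

test_that("add_permutation_fdr fills each probe's tier-level FDR", {
  tg <- two_group_beta(rep(0.2, 20), rep(0.7, 20), n_per_group = 5,
                       jitter = 0.04, seed = 8)
  rec <- probe_diffmeth(tg$m, tg$groups)
  rec <- add_permutation_fdr(rec, tg$m, tg$groups, n_perm = 30, seed = 4)
  expect_true(all(is.na(rec$fdr[rec$tier == "ns"])))
  expect_true(all(!is.na(rec$fdr[rec$tier != "ns"])))
  expect_true(all(rec$fdr >= 0 & rec$fdr <= 1, na.rm = TRUE))
})
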