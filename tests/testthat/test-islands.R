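test_that("candidate selection applies score, sex-chromosome and island filters", {
  rec <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    mean_beta_group1 = 0.3, mean_beta_group2 = 0.5,
                    delta_beta = 0.2, p_value = 0.001,
                    diff_score = c(25, 25, 15, 25, 40),
                    tier = "p01", fdr = NA_real_, stringsAsFactors = FALSE)
  man <- as_probe_manifest(data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    chromosome = c("7", "X", "7", "7", "2"),
    position = c(100, 200, 300, 400, 500),
    island_id = c("i1", "i2", "i3", NA, "i5"),
    gene = "G", region_class = "gene_body", platform = "P27K"))
  cand <- select_candidate_probes(rec, man)
  expect_setequal(cand$probe_id, c("p1", "p5"))   # p2 chrX, p3 score 15, p4 no island

  # a probe missing from the manifest is excluded with a warning
  rec2 <- rbind(rec, transform(rec[1, ], probe_id = "ghost"))
  expect_warning(cand2 <- select_candidate_probes(rec2, man), "ghost")
  expect_setequal(cand2$probe_id, c("p1", "p5"))

  # negative scores count by magnitude
  rec$diff_score <- -rec$diff_score
  rec$delta_beta <- -rec$delta_beta
  expect_setequal(select_candidate_probes(rec, man)$probe_id, c("p1", "p5"))
})

test_that("island enrichment recovers all dense probes with recomputable deltas", {
  sim <- simulate_paired_dataset(sim_config(n_islands = 40, seed = 12))
  rec <- probe_diffmeth(sim$beta_27k, sim$groups_27k)
  cand <- select_candidate_probes(rec, sim$manifest_27k)
  enr <- enrich_islands(cand, sim$manifest_450k, sim$beta_450k,
                        sim$groups_450k)
  expect_gt(length(enr$islands), 0)
  for (isl in names(enr$islands)) {
    tab <- enr$islands[[isl]]
    want <- sim$manifest_450k$probe_id[sim$manifest_450k$island_id == isl]
    expect_setequal(tab$probe_id, want)
    # independent recomputation from the dense matrix
    for (j in seq_len(nrow(tab))) {
      b <- sim$beta_450k$beta[tab$probe_id[j], ]
      d <- mean(b[sim$groups_450k$g2]) - mean(b[sim$groups_450k$g1])
      expect_equal(tab$delta_beta[j], d, tolerance = 1e-12)
    }
  }
})

test_that("islands absent from the dense data are reported, not fatal", {
  cand <- data.frame(probe_id = "p1", delta_beta = 0.2, diff_score = 30,
                     island_id = "lonely", stringsAsFactors = FALSE)
  tg <- two_group_beta(c(0.3, 0.4), c(0.5, 0.6), n_per_group = 3, seed = 1)
  man450 <- toy_manifest(c("cg001", "cg002"), island_id = "other",
                         platform = "P450K")
  enr <- enrich_islands(cand, man450, tg$m, tg$groups)
  expect_equal(enr$unenrichable, "lonely")
  expect_length(enr$islands, 0)

  # mixed-sign sparse candidates on one island are dropped with a warning
  cand2 <- data.frame(probe_id = c("a", "b"), delta_beta = c(0.2, -0.2),
                      diff_score = c(30, -30), island_id = "mix",
                      stringsAsFactors = FALSE)
  expect_warning(enr2 <- enrich_islands(cand2, man450, tg$m, tg$groups),
                 "mixed sign")
  expect_length(enr2$islands, 0)
})

test_that("validate_island evaluates the four criteria on hand-worked cases", {
  # worked example: mean 0.07; two probes at/above it -> fraction 0.5
  v <- validate_island(c(0.10, 0.06, 0.04, 0.08), "hyper")
  expect_equal(v$mean_delta, 0.07)
  expect_equal(v$concordant_fraction, 0.5)
  expect_true(v$direction_consistent && v$concordant_fraction_ok &&
              v$mean_abs_ok && v$min_probes_ok && v$validated)

  # too few probes
  v2 <- validate_island(c(0.10, 0.10), "hyper")
  expect_false(v2$min_probes_ok)
  expect_false(v2$validated)

  # effect too small: 0.04 < 0.05
  v3 <- validate_island(c(0.04, 0.04, 0.04), "hyper")
  expect_false(v3$mean_abs_ok)
  expect_false(v3$validated)

  # direction conflict: dense mean opposes the sparse call
  v4 <- validate_island(c(-0.10, -0.08, -0.09), "hyper")
  expect_false(v4$direction_consistent)
  expect_false(v4$validated)

  # inclusive boundaries: exactly 0.05 mean, exactly 30% concordant, exactly 3 probes
  v5 <- validate_island(c(0.05, 0.05, 0.05), "hyper")
  expect_true(v5$validated)
})

test_that("directional concordance is antisymmetric under sign flip", {
  set.seed(41)
  for (i in 1:50) {
    deltas <- round(stats::runif(sample(3:8, 1), -0.2, 0.2), 3)
    if (mean(deltas) == 0) next
    dir <- if (mean(deltas) > 0) "hyper" else "hypo"
    a <- validate_island(deltas, dir, concordance = "directional")
    b <- validate_island(-deltas, if (dir == "hyper") "hypo" else "hyper",
                         concordance = "directional")
    expect_identical(a$validated, b$validated)
    expect_equal(a$concordant_fraction, b$concordant_fraction)
  }
})

test_that("validate_island agrees with a brute-force rule evaluation on random islands", {
  set.seed(77)
  for (i in 1:120) {
    n <- sample(1:8, 1)
    deltas <- round(stats::runif(n, -0.15, 0.15), 3)
    dir <- sample(c("hyper", "hypo"), 1)
    for (mode in c("directional", "literal")) {
      got <- validate_island(deltas, dir, concordance = mode)
      want <- brute_force_validate(deltas, dir, mode)
      expect_equal(got$concordant_fraction, want$concordant_fraction)
      expect_identical(got$direction_consistent, want$direction_consistent)
      expect_identical(got$concordant_fraction_ok, want$concordant_fraction_ok)
      expect_identical(got$mean_abs_ok, want$mean_abs_ok)
      expect_identical(got$min_probes_ok, want$min_probes_ok)
      expect_identical(got$validated, want$validated)
    }
  }
})

test_that("validated islands are nested within enriched and candidate islands", {
  sim <- suppressWarnings(
    simulate_paired_dataset(sim_config(n_islands = 80, seed = 19)))
  res <- run_island_pipeline(sim$beta_27k, sim$groups_27k, sim$manifest_27k,
                             sim$manifest_450k, sim$beta_450k, sim$groups_450k)
  cand_islands <- unique(res$candidates$island_id)
  enriched <- names(res$enrichment$islands)
  expect_true(all(enriched %in% cand_islands))
  expect_true(all(res$validated_islands %in% enriched))
})

test_that("island profiles order probes by position and flag the TSS window", {
  man <- toy_manifest(sprintf("p%d", 1:5),
                      position = c(5000, 1000, 3000, 2000, 4000),
                      island_id = "isl1", gene = "G1", platform = "P450K")
  deltas <- c(p1 = 0.10, p2 = 0.01, p3 = 0.09, p4 = 0.02, p5 = 0.12)
  prof <- island_profile("isl1", man, deltas, tss = 1500, tss_window = 600)
  expect_equal(prof$position, sort(man$position))
  expect_equal(prof$delta_beta, c(0.01, 0.02, 0.09, 0.12, 0.10))
  expect_equal(prof$in_tss_window, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  # window 0 flags nothing, even a probe exactly at the TSS
  p0 <- island_profile("isl1", man, deltas, tss = 1000, tss_window = 0)
  expect_false(any(p0$in_tss_window))

  # body-only hypermethylation: TSS probes sit below the body mean
  body <- prof[!prof$in_tss_window, ]
  expect_true(all(abs(prof$delta_beta[prof$in_tss_window]) <
                  mean(abs(body$delta_beta))))

  # unknown region gives an empty track; lookup by gene symbol also works
  expect_equal(nrow(island_profile("nope", man, deltas)), 0)
  expect_equal(nrow(island_profile("G1", man, deltas)), 5)
})
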