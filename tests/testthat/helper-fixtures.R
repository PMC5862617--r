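# Small in-code fixtures shared across the suite.

toy_beta <- function(nprobe = 3, nsample = 4, values = NULL, detection = NULL) {
  b <- if (is.null(values)) {
    matrix(seq(0.1, 0.9, length.out = nprobe * nsample), nprobe, nsample)
  } else {
    matrix(values, nprobe, nsample)
  }
  dimnames(b) <- list(sprintf("cg%03d", seq_len(nprobe)),
                      sprintf("s%02d", seq_len(nsample)))
  d <- if (is.null(detection)) NULL else {
    m <- matrix(detection, nprobe, nsample)
    dimnames(m) <- dimnames(b)
    m
  }
  BetaMatrix(b, d)
}

# Two-group beta matrix with chosen per-group probe means plus jitter.
two_group_beta <- function(mu1, mu2, n_per_group = 5, jitter = 0.01, seed = 1) {
  set.seed(seed)
  nprobe <- length(mu1)
  b <- cbind(matrix(rep(mu1, n_per_group), nprobe) +
               matrix(stats::rnorm(nprobe * n_per_group, 0, jitter), nprobe),
             matrix(rep(mu2, n_per_group), nprobe) +
               matrix(stats::rnorm(nprobe * n_per_group, 0, jitter), nprobe))
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(sprintf("cg%03d", seq_len(nprobe)),
                      c(sprintf("a%02d", seq_len(n_per_group)),
                        sprintf("b%02d", seq_len(n_per_group))))
  list(m = BetaMatrix(b),
       groups = list(g1 = colnames(b)[seq_len(n_per_group)],
                     g2 = colnames(b)[n_per_group + seq_len(n_per_group)]))
}

toy_manifest <- function(probe_id, chromosome = "7", position = NULL,
                         island_id = "isl0001", gene = "GENE1",
                         region_class = "gene_body", platform = "P27K") {
  n <- length(probe_id)
  as_probe_manifest(data.frame(
    probe_id = probe_id,
    chromosome = rep_len(chromosome, n),
    position = if (is.null(position)) seq(1000, by = 100, length.out = n)
               else position,
    island_id = rep_len(island_id, n),
    gene = rep_len(gene, n),
    region_class = rep_len(region_class, n),
    platform = rep_len(platform, n),
    stringsAsFactors = FALSE))
}

table1_path <- function() {
  system.file("extdata", "table1_samples.csv", package = "islandmeth")
}

# Independent straightforward coding of the four island-validation rules,
# kept deliberately separate from the package implementation.
brute_force_validate <- function(deltas, direction, mode) {
  mu <- mean(deltas)
  conc <- if (mode == "literal") {
    sum(deltas >= mu) / length(deltas)
  } else {
    ok <- 0
    for (d in deltas) if (sign(d) == sign(mu) && abs(d) >= abs(mu)) ok <- ok + 1
    ok / length(deltas)
  }
  c1 <- (direction == "hyper" && mu > 0) || (direction == "hypo" && mu < 0)
  c2 <- conc >= 0.30
  c3 <- mean(abs(deltas)) >= 0.05
  c4 <- length(deltas) >= 3
  list(concordant_fraction = conc, direction_consistent = c1,
       concordant_fraction_ok = c2, mean_abs_ok = c3, min_probes_ok = c4,
       validated = c1 && c2 && c3 && c4)
}
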