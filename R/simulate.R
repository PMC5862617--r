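#' Simulation configuration
#'
#' Collects the knobs of the paired-platform methylation simulator. The
#' generator emulates a two-platform design: a sparse array interrogating
#' 1-2 probes per CpG island (27K-like) and a dense array interrogating
#' 3-20 probes per island (450K-like), over a shared island annotation,
#' with a two-group sample structure and island-level differential
#' methylation planted in a fraction of islands.
#'
#' Per-probe beta values are drawn from a Beta distribution parameterized
#' by mean and concentration (shape1 = mu * kappa, shape2 = (1 - mu) *
#' kappa), which respects the \[0, 1\] support of methylation fractions;
#' `noise_concentration = Inf` yields noiseless betas equal to the group
#' mean.
#'
#' @param n_islands number of CpG islands.
#' @param probes_per_island_27k integer range (length-2) of sparse-platform
#'   probes per island; these probes are a subset of the dense platform's.
#' @param probes_per_island_450k integer range of dense-platform probes
#'   per island.
#' @param n_samples_per_group samples per group on each platform.
#' @param frac_dm_islands fraction of islands carrying a planted effect.
#' @param effect_delta island-level group-mean beta shift for planted
#'   islands, in \[-1, 1\]; the sign of each island's effect is drawn at
#'   random and group-2 means are clipped to \[0.02, 0.98\].
#' @param noise_concentration Beta-noise concentration kappa > 0 (variance
#'   mu(1-mu)/(kappa+1)); `Inf` for the noiseless limit. Default 100,
#'   giving a per-probe beta s.d. of about 0.05 at mu = 0.5, typical of
#'   BeadChip replicates.
#' @param frac_sex_islands fraction of islands placed on chromosomes X/Y,
#'   so the sex-chromosome exclusion rule is exercised.
#' @param base_mean_range range the island baseline means are drawn from
#'   (uniformly).
#' @param seed integer RNG seed; the whole dataset, including the truth
#'   set, is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_islands = 200,
                       probes_per_island_27k = c(1L, 2L),
                       probes_per_island_450k = c(3L, 20L),
                       n_samples_per_group = 10,
                       frac_dm_islands = 0.2,
                       effect_delta = 0.15,
                       noise_concentration = 100,
                       frac_sex_islands = 0.05,
                       base_mean_range = c(0.15, 0.85),
                       seed = 1) {
  cfg <- list(n_islands = as.integer(n_islands),
              probes_per_island_27k = as.integer(probes_per_island_27k),
              probes_per_island_450k = as.integer(probes_per_island_450k),
              n_samples_per_group = as.integer(n_samples_per_group),
              frac_dm_islands = frac_dm_islands,
              effect_delta = effect_delta,
              noise_concentration = noise_concentration,
              frac_sex_islands = frac_sex_islands,
              base_mean_range = base_mean_range,
              seed = as.integer(seed))
  if (cfg$n_islands < 1 || cfg$n_samples_per_group < 1)
    stop("island and sample counts must be >= 1")
  if (any(cfg$probes_per_island_27k < 1) || any(cfg$probes_per_island_450k < 1))
    stop("probe counts per island must be >= 1")
  if (cfg$frac_dm_islands < 0 || cfg$frac_dm_islands > 1)
    stop("frac_dm_islands must be in [0, 1]")
  if (abs(cfg$effect_delta) > 1) stop("effect_delta must be in [-1, 1]")
  if (cfg$noise_concentration <= 0) stop("noise_concentration must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# Beta draw parameterized by mean and concentration; kappa = Inf returns
# the mean exactly (noiseless limit).
.rbeta_mc <- function(n, mu, kappa) {
  if (is.infinite(kappa)) return(rep(mu, length.out = n))
  stats::rbeta(n, shape1 = mu * kappa, shape2 = (1 - mu) * kappa)
}

#' Simulate a paired sparse/dense methylation dataset
#'
#' Generates a shared CpG-island annotation, a dense-platform (450K-like)
#' manifest, a sparse-platform (27K-like) manifest whose probes are a
#' subset of the dense one, and independent two-group beta matrices for
#' each platform. A random `frac_dm_islands` fraction of autosomal
#' islands carries a planted group-2 mean shift of `effect_delta` (random
#' sign per island); the truth set records which.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `manifest_27k`, `manifest_450k` (probe
#'   manifests), `islands` (island table with chromosome, span, TSS and
#'   planted effect), `beta_27k`, `beta_450k` ([BetaMatrix] objects with
#'   detection p-values), `groups_27k`, `groups_450k` (named lists of
#'   sample ids g1/g2), and `truth` (data frame of DM island ids with
#'   effect signs).
#' @export
simulate_paired_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ni <- cfg$n_islands

  n_sex <- round(cfg$frac_sex_islands * ni)
  chrom <- c(sample(c("X", "Y"), n_sex, replace = TRUE),
             sample(as.character(1:22), ni - n_sex, replace = TRUE))
  chrom <- sample(chrom)
  island_id <- sprintf("isl%04d", seq_len(ni))
  gene <- sprintf("GENE%04d", seq_len(ni))
  start <- sort(sample.int(2e8, ni))
  width <- sample(500:2000, ni, replace = TRUE)
  tss <- start + sample(0:200, ni, replace = TRUE)

  # plant effects only on autosomes so the truth set survives the
  # sex-chromosome exclusion applied downstream
  autosomal <- which(!chrom %in% c("X", "Y"))
  n_dm <- round(cfg$frac_dm_islands * length(autosomal))
  dm_idx <- sort(sample(autosomal, n_dm))
  effect_sign <- integer(ni)
  effect_sign[dm_idx] <- sample(c(-1L, 1L), n_dm, replace = TRUE)

  mu1 <- stats::runif(ni, cfg$base_mean_range[1], cfg$base_mean_range[2])
  mu2_raw <- mu1 + effect_sign * cfg$effect_delta
  mu2 <- pmin(pmax(mu2_raw, 0.02), 0.98)
  if (any(mu2 != mu2_raw))
    warning(sum(mu2 != mu2_raw),
            " island group-2 means clipped to [0.02, 0.98]; realized effects shrink")

  islands <- data.frame(island_id = island_id, gene = gene,
                        chromosome = chrom, start = start,
                        end = start + width, tss = tss,
                        mean_g1 = mu1, mean_g2 = mu2,
                        is_dm = effect_sign != 0L,
                        effect_sign = effect_sign,
                        stringsAsFactors = FALSE)

  n450 <- sample(cfg$probes_per_island_450k[1]:cfg$probes_per_island_450k[2],
                 ni, replace = TRUE)
  man450 <- do.call(rbind, lapply(seq_len(ni), function(i) {
    pos <- sort(sample(start[i]:(start[i] + width[i]), n450[i]))
    data.frame(probe_id = sprintf("cg_%s_%02d", island_id[i], seq_len(n450[i])),
               chromosome = chrom[i], position = pos,
               island_id = island_id[i], gene = gene[i],
               region_class = ifelse(abs(pos - tss[i]) <= 200,
                                     "TSS_proximal", "gene_body"),
               platform = "P450K", stringsAsFactors = FALSE)
  }))
  man450 <- as_probe_manifest(man450)

  # sparse platform: 1-2 of each island's probes, so dense supersets sparse
  n27 <- pmin(sample(cfg$probes_per_island_27k[1]:cfg$probes_per_island_27k[2],
                     ni, replace = TRUE), n450)
  keep27 <- unlist(lapply(seq_len(ni), function(i) {
    rows <- which(man450$island_id == island_id[i])
    sort(sample(rows, n27[i]))
  }))
  man27 <- man450[keep27, , drop = FALSE]
  man27$platform <- "P27K"
  man27 <- as_probe_manifest(man27)

  ns <- cfg$n_samples_per_group
  sim_beta <- function(man, prefix) {
    samples <- c(sprintf("%s_g1_%02d", prefix, seq_len(ns)),
                 sprintf("%s_g2_%02d", prefix, seq_len(ns)))
    mu_probe_g1 <- mu1[match(man$island_id, island_id)]
    mu_probe_g2 <- mu2[match(man$island_id, island_id)]
    b <- matrix(NA_real_, nrow(man), 2 * ns,
                dimnames = list(man$probe_id, samples))
    for (j in seq_len(ns)) {
      b[, j] <- .rbeta_mc(nrow(man), mu_probe_g1, cfg$noise_concentration)
      b[, ns + j] <- .rbeta_mc(nrow(man), mu_probe_g2, cfg$noise_concentration)
    }
    dp <- matrix(stats::runif(length(b), 0, 0.01), nrow(b), ncol(b),
                 dimnames = dimnames(b))
    list(m = BetaMatrix(b, dp),
         groups = list(g1 = samples[seq_len(ns)], g2 = samples[ns + seq_len(ns)]))
  }
  s27 <- sim_beta(man27, "s27")
  s450 <- sim_beta(man450, "s450")

  list(manifest_27k = man27, manifest_450k = man450, islands = islands,
       beta_27k = s27$m, beta_450k = s450$m,
       groups_27k = s27$groups, groups_450k = s450$groups,
       truth = data.frame(island_id = island_id[dm_idx],
                          effect_sign = effect_sign[dm_idx],
                          stringsAsFactors = FALSE))
}

#' Simulate a qPCR cycle-threshold table
#'
#' Builds a two-group CT table in which the expected delta-delta-CT fold
#' change of each target gene (group 2 relative to group 1) equals the
#' requested value: the group-2 target CT is lowered by log2(fold change)
#' relative to baseline. The endogenous-control gene must be included
#' with fold change 1.
#'
#' @param fold_changes named numeric vector of fold changes per gene; must
#'   include `control_gene` with value 1.
#' @param n_per_group samples per group.
#' @param control_gene name of the endogenous-control gene (default
#'   "TFRC").
#' @param noise_sd Gaussian noise s.d. added to every CT measurement
#'   (cycles).
#' @param base_ct baseline target CT (cycles).
#' @param control_ct endogenous-control CT (cycles).
#' @param seed RNG seed.
#' @return A validated `ct_table` data frame with an extra `group` column
#'   ("g1" reference, "g2").
#' @export
simulate_ct_table <- function(fold_changes, n_per_group = 10,
                              control_gene = "TFRC", noise_sd = 0.2,
                              base_ct = 26, control_ct = 20, seed = 1) {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes))))
    stop("`fold_changes` must be named by gene")
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  if (!control_gene %in% names(fold_changes) ||
      fold_changes[[control_gene]] != 1)
    stop("the endogenous control (", control_gene,
         ") must be included with fold change 1")
  if (n_per_group < 2) stop("need >= 2 samples per group")
  set.seed(seed)
  samples <- c(sprintf("q_g1_%02d", seq_len(n_per_group)),
               sprintf("q_g2_%02d", seq_len(n_per_group)))
  group <- rep(c("g1", "g2"), each = n_per_group)
  rows <- lapply(names(fold_changes), function(g) {
    is_ctrl <- identical(g, control_gene)
    mu <- if (is_ctrl) rep(control_ct, length(samples))
          else base_ct - ifelse(group == "g2", log2(fold_changes[[g]]), 0)
    data.frame(sample_id = samples, group = group, gene = g,
               ct = mu + stats::rnorm(length(samples), sd = noise_sd),
               is_endogenous_control = is_ctrl, stringsAsFactors = FALSE)
  })
  as_ct_table(do.call(rbind, rows))
}

#' Simulate survival data with an expression-linked hazard
#'
#' Draws an expression value per subject, splits at the median, and gives
#' the high-expression group an exponential event-time hazard scaled by
#' `hazard_ratio`. A `censor_frac` fraction of subjects (chosen
#' independently of group) is right-censored at a uniform fraction of its
#' event time; `censor_frac = 1` yields a dataset with no observed
#' events.
#'
#' @param n number of subjects (>= 2).
#' @param hazard_ratio hazard multiplier for the high-expression group
#'   (> 0).
#' @param base_hazard baseline exponential hazard per day.
#' @param censor_frac expected fraction of censored subjects, in \[0, 1\].
#' @param seed RNG seed.
#' @return A validated `survival_table` data frame (time in days).
#' @export
simulate_survival <- function(n, hazard_ratio, base_hazard = 1 / 1000,
                              censor_frac = 0.2, seed = 1) {
  if (n < 2) stop("need n >= 2 subjects")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_frac < 0 || censor_frac > 1) stop("censor_frac must be in [0, 1]")
  set.seed(seed)
  expression <- stats::rnorm(n)
  high <- expression > stats::median(expression)
  rate <- base_hazard * ifelse(high, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < censor_frac
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  as_survival_table(data.frame(sample_id = sprintf("pt%03d", seq_len(n)),
                               time = time, event = !censored,
                               expression = expression,
                               stringsAsFactors = FALSE))
}
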