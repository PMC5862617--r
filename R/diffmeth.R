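#' Signed DiffScore from a p-value and a methylation difference
#'
#' The DiffScore is the log-p significance score used by methylation
#' array software, signed by the direction of the methylation change:
#' `|score| = -10 * log10(p)`, positive for hypermethylation
#' (delta_beta > 0), negative for hypomethylation, and 0 when
#' delta_beta = 0. At p = 0.05 the magnitude is 13 to the nearest
#' integer, the conventional nominal-significance anchor.
#'
#' @param p p-value(s) in (0, 1].
#' @param delta_beta group-mean beta difference(s), giving the sign.
#' @return Numeric vector of signed scores.
#' @export
diff_score <- function(p, delta_beta) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  sign(delta_beta) * (-10 * log10(p))
}

# DiffScore magnitude -> significance tier. The conventional printed
# mapping (13/22/33 <-> 0.05/0.01/0.001) is used as lookup constants so
# that probe selections follow the standard filtering practice.
TIER_THRESHOLDS <- c(p05 = 13, p01 = 22, p001 = 33)

.score_tier <- function(score) {
  a <- abs(score)
  ifelse(a >= TIER_THRESHOLDS["p001"], "p001",
  ifelse(a >= TIER_THRESHOLDS["p01"], "p01",
  ifelse(a >= TIER_THRESHOLDS["p05"], "p05", "ns")))
}

# Resolve a group specification against the columns of a BetaMatrix:
# either a named list of two sample-id vectors, or a 2-level
# factor/character vector aligned to the columns.
.resolve_groups <- function(m, groups) {
  ids <- sample_ids(m)
  if (is.list(groups)) {
    if (length(groups) != 2) stop("`groups` must define exactly two groups")
    g1 <- intersect(ids, groups[[1]])
    g2 <- intersect(ids, groups[[2]])
  } else {
    groups <- as.character(groups)
    if (length(groups) != length(ids))
      stop("group vector length must match the number of samples")
    lev <- unique(groups)
    if (length(lev) != 2) stop("`groups` must have exactly two levels")
    g1 <- ids[groups == lev[1]]
    g2 <- ids[groups == lev[2]]
  }
  if (length(intersect(g1, g2)) > 0) stop("groups overlap")
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs >= 2 samples")
  list(g1 = g1, g2 = g2)
}

# Row-wise Welch unequal-variance two-sample test. Vectorized over
# probes so that 1000-permutation FDR estimation stays tractable;
# agreement with stats::t.test is asserted in the test suite.
# Degenerate rows (zero variance in both groups): p = 1 when the means
# agree, p = smallest double otherwise.
.row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  delta <- m2 - m1
  tt <- delta / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- ifelse(delta[degen] == 0, 1, .Machine$double.xmin)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] for the log score
  list(mean1 = m1, mean2 = m2, delta = delta, p = p)
}

#' Per-probe two-group differential methylation
#'
#' For each probe, computes the group-mean beta values, their difference
#' (delta beta = group 2 minus group 1), a two-sided unequal-variance
#' (Welch) two-sample test p-value on the beta values, the signed
#' DiffScore, and the significance tier implied by the conventional
#' score thresholds 13/22/33.
#'
#' @param m a [BetaMatrix].
#' @param groups two-group specification: a named list of two sample-id
#'   vectors (group 1 first), or a 2-level vector aligned to the samples.
#' @return Data frame with one row per probe: `probe_id`,
#'   `mean_beta_group1`, `mean_beta_group2`, `delta_beta`, `p_value`,
#'   `diff_score`, `tier` (ns/p05/p01/p001) and `fdr` (NA until
#'   [add_permutation_fdr()] fills it).
#' @export
probe_diffmeth <- function(m, groups) {
  stopifnot(inherits(m, "BetaMatrix"))
  g <- .resolve_groups(m, groups)
  x1 <- m$beta[, g$g1, drop = FALSE]
  x2 <- m$beta[, g$g2, drop = FALSE]
  w <- .row_welch(x1, x2)
  score <- diff_score(w$p, w$delta)
  data.frame(probe_id = probe_ids(m),
             mean_beta_group1 = w$mean1,
             mean_beta_group2 = w$mean2,
             delta_beta = w$delta,
             p_value = w$p,
             diff_score = score,
             tier = .score_tier(score),
             fdr = NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count probes per significance tier and direction
#'
#' Cumulative counts of probes whose DiffScore magnitude reaches the
#' 13/22/33 thresholds, split by direction of change (hyper:
#' delta beta > 0; hypo: delta beta < 0).
#'
#' @param records output of [probe_diffmeth()].
#' @param direction `"hyper"`, `"hypo"` or `"both"`.
#' @return Data frame with columns `direction`, `threshold`, `count`;
#'   counts are nonincreasing in the threshold within a direction.
#' @export
tier_counts <- function(records, direction = c("both", "hyper", "hypo")) {
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("hyper", "hypo") else direction
  out <- do.call(rbind, lapply(dirs, function(d) {
    sel <- if (d == "hyper") records$delta_beta > 0 else records$delta_beta < 0
    a <- abs(records$diff_score[sel])
    data.frame(direction = d, threshold = unname(TIER_THRESHOLDS),
               count = vapply(TIER_THRESHOLDS, function(th) sum(a >= th),
                              integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Permutation-based FDR for DiffScore thresholds
#'
#' Estimates the false discovery rate of the probe selection
#' `|DiffScore| >= threshold` by permuting group labels over whole
#' samples (columns), preserving inter-probe correlation. For each
#' permutation the full per-probe test is recomputed and the number of
#' threshold-passing probes counted; the FDR estimate is the mean
#' permutation count divided by the observed count (clipped to \[0, 1\]).
#'
#' @param m a [BetaMatrix].
#' @param groups two-group specification (see [probe_diffmeth()]).
#' @param thresholds DiffScore magnitude thresholds (default 13/22/33).
#' @param n_perm number of label permutations (>= 1; 1000 is the
#'   conventional choice).
#' @param seed RNG seed fixing the permutation stream.
#' @return Data frame with columns `threshold`, `observed`,
#'   `mean_null_count`, `fdr`; `fdr` is NA (with a warning) for
#'   thresholds no observed probe reaches.
#' @export
permutation_fdr <- function(m, groups, thresholds = unname(TIER_THRESHOLDS),
                            n_perm = 1000, seed = 1) {
  stopifnot(inherits(m, "BetaMatrix"), n_perm >= 1)
  g <- .resolve_groups(m, groups)
  cols <- c(g$g1, g$g2)
  n1 <- length(g$g1)
  b <- m$beta[, cols, drop = FALSE]
  obs <- .row_welch(b[, seq_len(n1), drop = FALSE],
                    b[, n1 + seq_len(length(g$g2)), drop = FALSE])
  obs_score <- abs(diff_score(obs$p, obs$delta))
  observed <- vapply(thresholds, function(th) sum(obs_score >= th), numeric(1))

  set.seed(seed)
  null_counts <- matrix(0, n_perm, length(thresholds))
  for (i in seq_len(n_perm)) {
    idx <- sample(ncol(b))
    w <- .row_welch(b[, idx[seq_len(n1)], drop = FALSE],
                    b[, idx[-seq_len(n1)], drop = FALSE])
    a <- -10 * log10(w$p)
    null_counts[i, ] <- vapply(thresholds, function(th) sum(a >= th), numeric(1))
  }
  fdr <- pmin(pmax(colMeans(null_counts) / pmax(observed, 1), 0), 1)
  fdr[observed == 0] <- NA_real_
  if (any(observed == 0))
    warning("no observed probes at threshold(s) ",
            paste(thresholds[observed == 0], collapse = ", "),
            "; FDR reported as NA")
  data.frame(threshold = thresholds, observed = observed,
             mean_null_count = colMeans(null_counts), fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Attach tier-level permutation FDR estimates to probe records
#'
#' Runs [permutation_fdr()] at the three tier thresholds and writes each
#' probe's `fdr` field from the FDR of its own tier threshold
#' (non-significant probes keep NA). Findings are conventionally
#' retained up to FDR 0.20.
#'
#' @inheritParams permutation_fdr
#' @param records output of [probe_diffmeth()] on the same matrix/groups.
#' @return `records` with the `fdr` column filled.
#' @export
add_permutation_fdr <- function(records, m, groups, n_perm = 1000, seed = 1) {
  fd <- permutation_fdr(m, groups, thresholds = unname(TIER_THRESHOLDS),
                        n_perm = n_perm, seed = seed)
  lookup <- stats::setNames(fd$fdr, names(TIER_THRESHOLDS))
  records$fdr <- ifelse(records$tier == "ns", NA_real_,
                        lookup[records$tier])
  records
}
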