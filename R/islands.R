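#' Select candidate probes for island-level validation
#'
#' Applies the conventional candidate filter to probe-level differential
#' methylation records: keep probes with `|DiffScore| >= min_score`
#' (default 22), drop probes on the sex chromosomes, and keep only
#' probes located on a CpG island. Probes without an annotation entry
#' are excluded with a warning.
#'
#' @param records output of [probe_diffmeth()].
#' @param manifest probe manifest (see [as_probe_manifest()]) for the
#'   records' platform.
#' @param min_score DiffScore magnitude cutoff (default 22).
#' @return Data frame of candidate probes: the records joined with
#'   `chromosome`, `island_id` and `gene`.
#' @export
select_candidate_probes <- function(records, manifest, min_score = 22) {
  manifest <- as_probe_manifest(as.data.frame(manifest))
  idx <- match(records$probe_id, manifest$probe_id)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " probe(s) without annotation excluded: ",
            paste(utils::head(records$probe_id[is.na(idx)], 5), collapse = ", "))
  }
  out <- cbind(records,
               chromosome = manifest$chromosome[idx],
               island_id = manifest$island_id[idx],
               gene = manifest$gene[idx])
  keep <- !is.na(idx) &
    abs(out$diff_score) >= min_score &
    !out$chromosome %in% c("X", "Y") &
    !is.na(out$island_id)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrich candidate islands with dense-platform probes
#'
#' For every island carrying at least one sparse-platform candidate
#' probe, looks up all dense-platform probes on that island and computes
#' their per-probe group-mean beta difference on the dense dataset. This
#' raises sparse single-probe island findings to multi-probe evidence.
#'
#' The sparse-platform direction of each island is the sign of its
#' candidate probes' delta beta; islands whose candidate probes disagree
#' in sign are dropped with a warning. Islands absent from the dense
#' manifest or beta matrix are reported as unenrichable rather than
#' erroring.
#'
#' @param candidates output of [select_candidate_probes()].
#' @param manifest_450k dense-platform probe manifest.
#' @param beta_450k dense-platform [BetaMatrix].
#' @param groups two-group specification for the dense dataset (see
#'   [probe_diffmeth()]); group order must match the sparse analysis.
#' @return List with `islands`: a list (by island id) of data frames of
#'   per-probe `probe_id`, `position`, `delta_beta`; `direction`: named
#'   character vector ("hyper"/"hypo") per island; `unenrichable`:
#'   character vector of candidate island ids with no usable dense data.
#' @export
enrich_islands <- function(candidates, manifest_450k, beta_450k, groups) {
  manifest_450k <- as_probe_manifest(as.data.frame(manifest_450k))
  rec450 <- probe_diffmeth(beta_450k, groups)
  delta450 <- stats::setNames(rec450$delta_beta, rec450$probe_id)

  isl_ids <- unique(candidates$island_id)
  direction <- character(0)
  islands <- list()
  unenrichable <- character(0)
  for (isl in isl_ids) {
    signs <- sign(candidates$delta_beta[candidates$island_id == isl])
    if (length(unique(signs[signs != 0])) != 1) {
      warning("island ", isl, " has candidate probes of mixed sign; dropped")
      next
    }
    probes <- manifest_450k[manifest_450k$island_id %in% isl, , drop = FALSE]
    probes <- probes[probes$probe_id %in% names(delta450), , drop = FALSE]
    if (nrow(probes) == 0) {
      unenrichable <- c(unenrichable, isl)
      next
    }
    islands[[isl]] <- data.frame(probe_id = probes$probe_id,
                                 position = probes$position,
                                 delta_beta = unname(delta450[probes$probe_id]),
                                 stringsAsFactors = FALSE)
    direction[isl] <- if (unique(signs[signs != 0]) > 0) "hyper" else "hypo"
  }
  list(islands = islands, direction = direction, unenrichable = unenrichable)
}

#' Validate one island against the four region-level criteria
#'
#' An island finding from the sparse platform is validated on the dense
#' platform when all four criteria hold:
#' \enumerate{
#'   \item direction consistency: the sign of the island's mean dense
#'     delta beta matches the sparse-platform direction;
#'   \item probe concordance: at least `min_concordant_frac` (default
#'     30\%) of the island's probes are concordant with the island mean.
#'     In the default `"directional"` mode a probe is concordant when its
#'     delta beta has the island mean's sign and at least its magnitude;
#'     `"literal"` mode uses the raw comparison delta beta >= island
#'     mean, which is asymmetric for hypomethylated islands;
#'   \item effect size: mean |delta beta| over island probes >=
#'     `min_mean_abs` (default 0.05);
#'   \item coverage: at least `min_probes` probes (default 3).
#' }
#' All boundary comparisons are inclusive.
#'
#' @param delta_beta numeric vector of per-probe dense-platform delta
#'   beta values for the island.
#' @param direction_27k `"hyper"` or `"hypo"`: the island's direction on
#'   the sparse platform.
#' @param min_concordant_frac minimum concordant-probe fraction.
#' @param min_mean_abs minimum mean absolute delta beta.
#' @param min_probes minimum probe count.
#' @param concordance `"directional"` (default) or `"literal"`.
#' @return A one-row data frame: `direction_27k`, `n_probes`,
#'   `mean_delta`, `concordant_fraction`, the four criterion flags
#'   (`direction_consistent`, `concordant_fraction_ok`, `mean_abs_ok`,
#'   `min_probes_ok`) and `validated` (their conjunction).
#' @export
validate_island <- function(delta_beta, direction_27k = c("hyper", "hypo"),
                            min_concordant_frac = 0.30, min_mean_abs = 0.05,
                            min_probes = 3,
                            concordance = c("directional", "literal")) {
  direction_27k <- match.arg(direction_27k)
  concordance <- match.arg(concordance)
  if (length(delta_beta) < 1) stop("island must have >= 1 probe")
  n <- length(delta_beta)
  mu <- mean(delta_beta)
  want_sign <- if (direction_27k == "hyper") 1 else -1
  concordant <- if (concordance == "literal") {
    delta_beta >= mu
  } else {
    sign(delta_beta) == sign(mu) & abs(delta_beta) >= abs(mu)
  }
  cf <- mean(concordant)
  crit <- c(direction_consistent = sign(mu) == want_sign,
            concordant_fraction_ok = cf >= min_concordant_frac,
            mean_abs_ok = mean(abs(delta_beta)) >= min_mean_abs,
            min_probes_ok = n >= min_probes)
  data.frame(direction_27k = direction_27k, n_probes = n, mean_delta = mu,
             concordant_fraction = cf,
             direction_consistent = unname(crit[1]),
             concordant_fraction_ok = unname(crit[2]),
             mean_abs_ok = unname(crit[3]),
             min_probes_ok = unname(crit[4]),
             validated = all(crit), stringsAsFactors = FALSE)
}

#' Validate every enriched island
#'
#' @param enrichment output of [enrich_islands()].
#' @param ... criteria passed on to [validate_island()].
#' @return Data frame with one row per enriched island (column
#'   `island_id` plus the [validate_island()] columns).
#' @export
validate_islands <- function(enrichment, ...) {
  ids <- names(enrichment$islands)
  if (length(ids) == 0)
    return(data.frame(island_id = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(ids, function(isl) {
    cbind(island_id = isl,
          validate_island(enrichment$islands[[isl]]$delta_beta,
                          enrichment$direction[[isl]], ...))
  }))
  rownames(out) <- NULL
  out
}

#' Positional delta-beta profile along a gene or island
#'
#' Orders the probes of a region by genomic position and flags those
#' lying within a window of the transcription start site. Used to
#' visualize the recurrent pattern of gene-body hypermethylation sparing
#' the TSS region.
#'
#' @param region an island id or gene symbol present in the manifest.
#' @param manifest probe manifest.
#' @param delta_by_probe named numeric vector of per-probe delta beta.
#' @param tss optional TSS coordinate (1-based); when NULL no probe is
#'   flagged.
#' @param tss_window half-width of the TSS window in bp (default 500);
#'   a window of 0 flags no probe.
#' @return Data frame sorted by position: `probe_id`, `position`,
#'   `delta_beta`, `in_tss_window`. Empty (zero rows) when the region
#'   has no probes.
#' @export
island_profile <- function(region, manifest, delta_by_probe, tss = NULL,
                           tss_window = 500) {
  manifest <- as_probe_manifest(as.data.frame(manifest))
  rows <- manifest[(!is.na(manifest$island_id) & manifest$island_id == region) |
                   (!is.na(manifest$gene) & manifest$gene == region), ,
                   drop = FALSE]
  rows <- rows[order(rows$position), , drop = FALSE]
  in_tss <- if (is.null(tss) || tss_window <= 0) rep(FALSE, nrow(rows))
            else abs(rows$position - tss) <= tss_window
  data.frame(probe_id = rows$probe_id, position = rows$position,
             delta_beta = unname(delta_by_probe[rows$probe_id]),
             in_tss_window = in_tss, row.names = NULL,
             stringsAsFactors = FALSE)
}
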