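#' Delta-delta-CT relative expression
#'
#' Implements the standard ddCT relative-quantification method with
#' amplification efficiency fixed at 2. Per sample, delta CT is the
#' target gene's CT minus the endogenous control's CT; delta-delta CT
#' subtracts the reference group's mean delta CT; the per-sample fold
#' change is `2^(-ddCT)`, so the reference group's geometric-mean fold
#' change is 1 by construction. The group fold change is the ratio of
#' group geometric means, and the group comparison is a two-sided Welch
#' t-test on the delta-CT values (the log2 scale on which they are
#' approximately normal).
#'
#' @param ct a CT table (see [as_ct_table()]).
#' @param gene target gene symbol.
#' @param groups named vector (sample id -> group label) or a `group`
#'   column already present in `ct`.
#' @param reference_group label of the reference group.
#' @return Object of class `expression_result`: list with `gene`,
#'   `samples` (data frame: sample_id, group, delta_ct, ddct,
#'   fold_change), `group_fold_change` (named, non-reference groups),
#'   and `p_value` (two-group case; NA otherwise).
#' @export
ddct_fold_changes <- function(ct, gene, groups = NULL, reference_group) {
  ct <- as_ct_table(as.data.frame(ct))
  ctrl_gene <- unique(ct$gene[ct$is_endogenous_control])
  tgt <- ct[ct$gene == gene & !ct$is_endogenous_control, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no CT rows for target gene ", gene)
  ctl <- ct[ct$is_endogenous_control, , drop = FALSE]

  if (is.null(groups)) {
    if (!"group" %in% names(ct)) stop("supply `groups` or a group column")
    groups <- stats::setNames(ct$group, ct$sample_id)
    groups <- groups[!duplicated(names(groups))]
  }

  idx <- match(tgt$sample_id, ctl$sample_id)
  dropped <- tgt$sample_id[is.na(idx)]
  if (length(dropped) > 0) {
    warning("sample(s) without endogenous-control CT dropped: ",
            paste(dropped, collapse = ", "))
    tgt <- tgt[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  delta_ct <- tgt$ct - ctl$ct[idx]
  grp <- as.character(groups[tgt$sample_id])
  if (any(is.na(grp))) stop("group missing for sample(s): ",
                            paste(tgt$sample_id[is.na(grp)], collapse = ", "))
  if (!reference_group %in% grp) stop("reference group '", reference_group,
                                      "' has no samples")
  ref_mean <- mean(delta_ct[grp == reference_group])
  ddct <- delta_ct - ref_mean
  fc <- 2^(-ddct)

  others <- setdiff(unique(grp), reference_group)
  gfc <- vapply(others, function(g) 2^(-(mean(delta_ct[grp == g]) - ref_mean)),
                numeric(1))

  p <- NA_real_
  if (length(others) == 1 && min(table(grp)) >= 2) {
    p <- group_expression_test(delta_ct, grp)
  }
  structure(list(gene = gene, control_gene = ctrl_gene,
                 reference_group = reference_group,
                 samples = data.frame(sample_id = tgt$sample_id, group = grp,
                                      delta_ct = delta_ct, ddct = ddct,
                                      fold_change = fc,
                                      stringsAsFactors = FALSE),
                 group_fold_change = gfc, p_value = p),
            class = "expression_result")
}

#' Two-group comparison of delta-CT values
#'
#' Two-sided unequal-variance (Welch) t-test on per-sample delta-CT
#' values, via [stats::t.test()]. The degenerate case — zero variance in
#' both groups — returns p = 1 when the group means agree and p near 0
#' otherwise.
#'
#' @param delta_ct numeric vector of per-sample delta-CT values.
#' @param groups 2-level group vector aligned to `delta_ct`.
#' @return The two-sided p-value.
#' @export
group_expression_test <- function(delta_ct, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups")
  x <- delta_ct[groups == lev[1]]
  y <- delta_ct[groups == lev[2]]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 samples per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("ddCT expression of %s (control %s, reference %s)\n",
              x$gene, x$control_gene, x$reference_group))
  for (g in names(x$group_fold_change))
    cat(sprintf("  %s: fold change %.3g\n", g, x$group_fold_change[[g]]))
  if (!is.na(x$p_value)) cat(sprintf("  Welch p = %.3g\n", x$p_value))
  invisible(x)
}
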