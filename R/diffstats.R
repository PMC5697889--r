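## The statistical layer shared by the pathway- and taxon-level comparisons:
## Welch's t-test per feature across two sample groups, Benjamini-Hochberg
## FDR, and effect-size-ranked differential reports. Effect size follows the
## field's proportion-profile convention: the difference in mean proportions
## between groups.

#' Welch's two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (`var.equal = FALSE`, two-sided)
#' with explicit conventions for the degenerate zero-variance inputs that
#' compositional profiles produce: if both groups have zero variance, p = 1
#' when the means are equal and p = 0 when they differ (t is +/-Inf, df NA).
#'
#' @param a,b Numeric vectors, >= 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH via [stats::p.adjust()], with input validation.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Vector of q-values (same order as input).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential features between two sample groups
#'
#' Applies [welch_t()] to every feature (row) of a proportion matrix, adjusts
#' with [bh_adjust()], and returns results ranked by absolute effect size
#' (difference in mean proportions, group A minus group B) among flagged
#' features first. Flagging: `q < threshold` in `"pathway_q"` mode, `p <
#' threshold` in `"taxon_p"` mode. Features that are all-zero across both
#' groups are dropped before testing (their count is reported in the
#' `n_dropped` attribute). Ties in |effect| break lexicographically by
#' feature id.
#'
#' @param profile Numeric matrix, features x samples (relative proportions).
#' @param group_a,group_b `sample_group`s with >= 2 samples each, columns of
#'   `profile`.
#' @param mode `"pathway_q"` or `"taxon_p"`.
#' @param threshold Significance threshold; default 0.05.
#' @return data.frame with `feature`, `mean_a`, `mean_b`, `effect`, `t`,
#'   `p`, `q`, `flagged`, `enriched_in`, sorted flagged-first by descending
#'   |effect|.
#' @export
differential_features <- function(profile, group_a, group_b,
                                  mode = c("pathway_q", "taxon_p"),
                                  threshold = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(profile),
            length(group_a$sample_ids) >= 2,
            length(group_b$sample_ids) >= 2,
            all(c(group_a$sample_ids, group_b$sample_ids) %in%
                  colnames(profile)))
  ma <- profile[, group_a$sample_ids, drop = FALSE]
  mb <- profile[, group_b$sample_ids, drop = FALSE]
  nonzero <- rowSums(ma) + rowSums(mb) > 0
  n_dropped <- sum(!nonzero)
  ma <- ma[nonzero, , drop = FALSE]
  mb <- mb[nonzero, , drop = FALSE]
  feats <- rownames(ma)
  res <- lapply(seq_along(feats), function(i) welch_t(ma[i, ], mb[i, ]))
  out <- data.frame(
    feature = feats,
    mean_a = rowMeans(ma),
    mean_b = rowMeans(mb),
    t = vapply(res, `[[`, numeric(1), "t"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$effect <- out$mean_a - out$mean_b
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out$flagged <- if (mode == "pathway_q") out$q < threshold else
    out$p < threshold
  out$enriched_in <- ifelse(out$effect >= 0, group_a$group_id,
                            group_b$group_id)
  ord <- order(!out$flagged, -abs(out$effect), out$feature)
  out <- out[ord, c("feature", "mean_a", "mean_b", "effect", "t", "p", "q",
                    "flagged", "enriched_in")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
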