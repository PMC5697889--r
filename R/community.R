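## Taxon-profile community structure: abundance filtering, abundance-weighted
## Bray-Curtis dissimilarities, deterministic UPGMA clustering, and
## host-discriminating lineage ranking.

#' Filter low-abundance lineages
#'
#' Retains a lineage iff its relative abundance reaches `min_abundance` in at
#' least one sample. The removed per-sample mass is reported via the
#' `removed_mass` attribute (and the number of rows via `n_removed`), never
#' silently discarded.
#'
#' @param profile A `taxon_profile`.
#' @param min_abundance Fraction threshold; defaults to the profile's
#'   `min_abundance` attribute (0.0005, i.e. 0.05%).
#' @return Filtered `taxon_profile`.
#' @export
filter_taxa <- function(profile,
                        min_abundance = attr(profile, "min_abundance")) {
  stopifnot(inherits(profile, "taxon_profile"))
  samples <- setdiff(names(profile), "lineage")
  vals <- as.matrix(as.data.frame(profile)[, samples, drop = FALSE])
  keep <- if (nrow(vals)) apply(vals, 1, max) >= min_abundance else
    logical(0)
  out <- taxon_profile(as.data.frame(profile)[keep, , drop = FALSE],
                       min_abundance)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_mass") <- colSums(vals[!keep, , drop = FALSE])
  out
}

#' Abundance-weighted Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x, y)) / sum(x + y)` on non-negative abundance vectors
#' over a shared taxon index. Two all-zero vectors are defined as distance 0
#' with a warning.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Dissimilarity in \[0,1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) {
    warning("both vectors are all-zero; Bray-Curtis defined as 0")
    return(0)
  }
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis distance matrix of a taxon profile
#'
#' Samples are renormalised to relative abundance after filtering, then all
#' pairwise dissimilarities are computed.
#'
#' @param profile A `taxon_profile` (typically after [filter_taxa()]).
#' @param renormalize Renormalise each sample to sum 1 first (default TRUE).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
bray_curtis_matrix <- function(profile, renormalize = TRUE) {
  samples <- setdiff(names(profile), "lineage")
  vals <- as.matrix(as.data.frame(profile)[, samples, drop = FALSE])
  if (renormalize) {
    cs <- colSums(vals)
    cs[cs == 0] <- 1
    vals <- sweep(vals, 2, cs, "/")
  }
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <- bray_curtis(vals[, i], vals[, j])
  }
  d
}

#' Deterministic UPGMA (average-linkage) clustering
#'
#' Agglomerates a distance matrix with average linkage. Ties in the minimum
#' inter-cluster distance are broken by the lexicographically smallest pair
#' of cluster representative labels (the alphabetically first member of each
#' cluster), making the result invariant to input order.
#'
#' @param d Symmetric distance matrix with dimnames (or a `dist`).
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
hierarchical_cluster <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples to cluster")
  # canonical label order so the agglomeration is input-order invariant
  ord0 <- order(labels)
  d <- d[ord0, ord0]
  labels <- labels[ord0]

  active <- seq_len(n)            # current cluster ids (index into sets)
  sets <- as.list(seq_len(n))     # members (original indices)
  reps <- labels                  # representative label per cluster
  sizes <- rep(1L, n)
  node <- -(seq_len(n))           # hclust code: negative = singleton
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      dij <- dm[i, j]
      pair_rep <- sort(c(reps[i], reps[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (pair_rep[1] < best$rep[1] ||
            (pair_rep[1] == best$rep[1] && pair_rep[2] < best$rep[2])))) {
        best <- list(i = i, j = j, d = dij, rep = pair_rep)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best$d
    # average linkage update
    newrow <- (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    sets[[i]] <- c(sets[[i]], sets[[j]])
    new_set <- sets[[i]]
    new_rep <- min(c(reps[i], reps[j]))
    new_size <- sizes[i] + sizes[j]
    sets <- c(sets[keep], list(new_set))
    reps <- c(reps[keep], new_rep)
    sizes <- c(sizes[keep], new_size)
    node <- c(node[keep], step)
    active <- seq_len(k - 1L)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = integer(n), labels = labels,
                       method = "average",
                       call = match.call(), dist.method = "bray-curtis"),
                  class = "hclust")
  # leaf order without branch crossings
  leaf_order <- function(node_id) {
    if (node_id < 0) return(-node_id)
    c(leaf_order(merge[node_id, 1]), leaf_order(merge[node_id, 2]))
  }
  hc$order <- leaf_order(n - 1L)
  hc
}

#' Export a dendrogram as Newick
#' @param hc An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Aggregate a taxon profile at a taxonomic rank
#'
#' Lineage rows are collapsed by their prefix up to `rank` (prefixes
#' `k/p/c/o/f/g`). Rows not classified at that rank are aggregated under
#' their deepest classified ancestor with an `unc` (unclassified) label.
#'
#' @param profile A `taxon_profile`.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Aggregated `taxon_profile`.
#' @export
aggregate_taxa <- function(profile, rank = "family") {
  ranks <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
             family = "f", genus = "g")
  stopifnot(rank %in% names(ranks))
  depth <- match(rank, names(ranks))
  samples <- setdiff(names(profile), "lineage")
  lab <- vapply(strsplit(profile$lineage, ";", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    parts <- parts[seq_len(min(depth, length(parts)))]
    filled <- nzchar(sub("^[a-z]__", "", parts))
    if (length(parts) >= depth && filled[depth]) {
      paste(parts, collapse = ";")
    } else {
      keep <- if (any(filled)) parts[seq_len(max(which(filled)))] else
        character(0)
      paste(c(keep, paste0(ranks[depth], "__unc")), collapse = ";")
    }
  }, character(1))
  vals <- as.matrix(as.data.frame(profile)[, samples, drop = FALSE])
  agg <- rowsum(vals, lab)
  df <- data.frame(lineage = rownames(agg), agg, row.names = NULL,
                   check.names = FALSE)
  taxon_profile(df, attr(profile, "min_abundance"))
}

#' Host-discriminating lineages
#'
#' Ranks lineages by effect size (absolute difference in mean relative
#' abundance) among those that differ significantly between hosts (Welch's
#' t-test, p below `threshold`; taxon mode, no FDR adjustment for flagging).
#'
#' @param profile A `taxon_profile` (filter first with [filter_taxa()]).
#' @param group_a,group_b `sample_group`s (>= 2 samples each).
#' @param threshold p-value threshold; default 0.05.
#' @return data.frame from [differential_features()] in `taxon_p` mode.
#' @export
discriminating_lineages <- function(profile, group_a, group_b,
                                    threshold = 0.05) {
  samples <- setdiff(names(profile), "lineage")
  m <- as.matrix(as.data.frame(profile)[, samples, drop = FALSE])
  rownames(m) <- profile$lineage
  differential_features(m, group_a, group_b, mode = "taxon_p",
                        threshold = threshold)
}
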