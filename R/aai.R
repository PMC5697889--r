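## Aggregate amino-acid identity (AAI) between population genomes.
## Orthologs are reciprocal best-scoring hits from exact affine-gap local
## alignment (BLOSUM62, gap open 11, extend 1 — the familiar protein-search
## defaults), subject to minimum thresholds of 30% identity and 70% coverage
## of the shorter sequence; AAI is the mean (and population SD) of ortholog
## identities. Raw substitution score decides "best-scoring".

#' Exact local protein alignment
#'
#' Optimal Smith-Waterman alignment under affine gap penalties. Identity is
#' the fraction of exact residue matches over aligned columns; gap columns
#' count toward aligned length (and hence coverage) but not identity.
#' Coverage is aligned columns divided by the length of the shorter
#' sequence. A pair with no positive-scoring local alignment returns score
#' 0 with identity and coverage 0.
#'
#' @param a,b Non-empty amino-acid strings (letters outside the matrix
#'   alphabet are scored as X).
#' @param matrix Integer substitution matrix with residue dimnames; default
#'   [blosum62()].
#' @param gap_open,gap_extend Affine gap penalties (positive costs); a gap
#'   of length L costs `gap_open + L * gap_extend`. Defaults 11 and 1.
#' @return List with `score`, `identity` (percent), `coverage` (fraction),
#'   `nmatch`, `ncols`.
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11L,
                        gap_extend = 1L) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .sw_align_pair(a, b, matrix, paste(rownames(matrix), collapse = ""),
                 as.integer(gap_open), as.integer(gap_extend))
}

sw_all <- function(query, subject, matrix = blosum62(), gap_open = 11L,
                   gap_extend = 1L) {
  res <- .sw_align_all(unname(query), unname(subject), matrix,
                       paste(rownames(matrix), collapse = ""),
                       as.integer(gap_open), as.integer(gap_extend))
  for (k in seq_along(res))
    dimnames(res[[k]]) <- list(names(query), names(subject))
  res
}

# fast route: score matrix for all pairs, counters only for best-hit
# candidates; proteomes are pre-sorted by name so the C++ index tie-break
# equals the lexicographic subject-id tie-break
sw_rbh <- function(query, subject, min_identity, min_coverage,
                   matrix = blosum62(), gap_open = 11L, gap_extend = 1L) {
  query <- query[order(names(query))]
  subject <- subject[order(names(subject))]
  res <- .sw_rbh(unname(query), unname(subject), matrix,
                 paste(rownames(matrix), collapse = ""),
                 as.integer(gap_open), as.integer(gap_extend),
                 min_identity, min_coverage)
  as_frame <- function(h, qn, sn) {
    data.frame(query = qn[h$query], subject = sn[h$subject],
               score = h$score, identity = h$identity,
               coverage = h$coverage, stringsAsFactors = FALSE)
  }
  list(fwd = as_frame(res$fwd, names(query), names(subject)),
       rev = as_frame(res$rev, names(subject), names(query)))
}

best_from_matrices <- function(mats, min_identity, min_coverage) {
  pass <- mats$identity / 100 >= min_identity &
    mats$coverage >= min_coverage & mats$score > 0
  qn <- rownames(mats$score)
  sn <- colnames(mats$score)
  hits <- lapply(seq_along(qn), function(i) {
    ok <- which(pass[i, ])
    if (!length(ok)) return(NULL)
    sc <- mats$score[i, ok]
    id <- mats$identity[i, ok]
    # best score; ties: higher identity, then subject id
    ord <- order(-sc, -id, sn[ok])
    j <- ok[ord[1]]
    data.frame(query = qn[i], subject = sn[j],
               score = mats$score[i, j], identity = mats$identity[i, j],
               coverage = mats$coverage[i, j], stringsAsFactors = FALSE)
  })
  do.call(rbind, hits)
}

#' Best passing hits of every query protein
#'
#' For each query, the subject with maximal alignment score among hits
#' passing the identity and coverage thresholds. Queries with no passing hit
#' are absent from the result. Score ties break by higher identity, then
#' subject id.
#'
#' @param query,subject Named character vectors of protein sequences.
#' @param min_identity Identity floor as a fraction (default 0.30).
#' @param min_coverage Coverage floor as a fraction of the shorter sequence
#'   (default 0.70).
#' @inheritParams local_align
#' @return data.frame `query`, `subject`, `score`, `identity`, `coverage`.
#' @export
best_hits <- function(query, subject, min_identity = 0.30,
                      min_coverage = 0.70, matrix = blosum62(),
                      gap_open = 11L, gap_extend = 1L) {
  stopifnot(length(query) >= 1, length(subject) >= 1)
  if (is.null(names(query)) || is.null(names(subject)))
    stop("proteomes must be named")
  sw_rbh(query, subject, min_identity, min_coverage, matrix, gap_open,
         gap_extend)$fwd
}

#' Aggregate amino-acid identity between two proteomes
#'
#' Orthologs are mutual best hits under [best_hits()] thresholds; AAI is
#' the mean percent identity across orthologs, with the population
#' (n-denominator) standard deviation. The computation is exactly symmetric
#' in its two arguments: one all-vs-all alignment matrix serves both
#' directions. Zero orthologs yield `mean_aai = NA` with `n_orthologs = 0`,
#' never a silent 0.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences.
#' @inheritParams best_hits
#' @return An `aai_result`: list with `mean_aai`, `sd_aai`, `n_orthologs`,
#'   and `orthologs` (data.frame `protein_a`, `protein_b`, `identity`,
#'   `score`, `coverage`).
#' @export
aai <- function(proteome_a, proteome_b, min_identity = 0.30,
                min_coverage = 0.70, matrix = blosum62(), gap_open = 11L,
                gap_extend = 1L) {
  stopifnot(length(proteome_a) >= 1, length(proteome_b) >= 1)
  if (is.null(names(proteome_a)) || is.null(names(proteome_b)))
    stop("proteomes must be named")
  hits <- sw_rbh(proteome_a, proteome_b, min_identity, min_coverage,
                 matrix, gap_open, gap_extend)
  fwd <- hits$fwd
  rev <- hits$rev
  orth <- NULL
  if (nrow(fwd) && nrow(rev)) {
    key_f <- paste(fwd$query, fwd$subject, sep = "\r")
    key_r <- paste(rev$subject, rev$query, sep = "\r")
    mutual <- fwd[key_f %in% key_r, , drop = FALSE]
    if (nrow(mutual)) {
      orth <- data.frame(protein_a = mutual$query,
                         protein_b = mutual$subject,
                         identity = mutual$identity,
                         score = mutual$score,
                         coverage = mutual$coverage,
                         stringsAsFactors = FALSE)
      orth <- orth[order(orth$protein_a), , drop = FALSE]
      rownames(orth) <- NULL
    }
  }
  n <- if (is.null(orth)) 0L else nrow(orth)
  mean_aai <- if (n > 0) mean(orth$identity) else NA_real_
  sd_aai <- if (n > 1)
    sqrt(sum((orth$identity - mean_aai)^2) / n) else
      if (n == 1) 0 else NA_real_
  structure(list(mean_aai = mean_aai, sd_aai = sd_aai, n_orthologs = n,
                 orthologs = orth),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  if (x$n_orthologs == 0) {
    cat("AAI: no orthologs under thresholds\n")
  } else {
    cat(sprintf("AAI: %.1f%% (SD %.1f%%) across %d orthologs\n",
                x$mean_aai, x$sd_aai, x$n_orthologs))
  }
  invisible(x)
}
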