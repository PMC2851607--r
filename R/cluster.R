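#' Refining common regions into subregions (CLUSTER)
#'
#' A common region found by COVER or COMPOSITE is often a mixture of two
#' or more partially overlapping subregions, each supported by a different
#' subset of individuals. CLUSTER recovers these by hierarchical
#' clustering of the region's supporting calls on a pairwise overlap
#' dissimilarity.
#'
#' For two calls A and B inside a common region of length L bases, the
#' pair is summarised as (a, b, c, d): a = bases where both overlap the
#' region, b = bases where only A does, c = bases where only B does,
#' d = L - a - b - c. The Jaccard similarity a / (a + b + c) is the shared
#' overlap relative to the union of the two overlaps; clustering uses the
#' dissimilarity 1 - a / (a + b + c), so "at least 60% similar" means a
#' dendrogram cut at height 0.4.
#'
#' @name cluster
NULL

.bases_overlap <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2) + 1)
}

#' Pairwise overlap summary of two calls within a common region
#'
#' Counts are in bases (1-based inclusive), computed on the intersection
#' of each call with the region span, so a + b + c + d = L where L is the
#' region length.
#'
#' @param start_a,end_a span of the first call.
#' @param start_b,end_b span of the second call.
#' @param region_start,region_end span of the common region.
#' @return A list (a, b, c, d, L).
#' @export
pair_overlap <- function(start_a, end_a, start_b, end_b,
                         region_start, region_end) {
  L <- region_end - region_start + 1
  la <- .bases_overlap(start_a, end_a, region_start, region_end)
  lb <- .bases_overlap(start_b, end_b, region_start, region_end)
  if (la == 0 || lb == 0) {
    stop("both calls must overlap the common region")
  }
  a <- .bases_overlap(max(start_a, region_start), min(end_a, region_end),
                      max(start_b, region_start), min(end_b, region_end))
  list(a = a, b = la - a, c = lb - a, L = L, d = L - la - lb + a)
}

#' Jaccard dissimilarity of a pair-overlap summary
#'
#' 1 - a / (a + b + c): zero for identical overlaps, one for disjoint
#' ones. Symmetric in b and c; d never enters.
#'
#' @param po a list with elements a, b, c as returned by [pair_overlap].
#' @return Dissimilarity in \[0, 1\].
#' @export
jaccard_dissimilarity <- function(po) {
  denom <- po$a + po$b + po$c
  if (denom <= 0) stop("a + b + c = 0: both calls are empty inside the region")
  1 - po$a / denom
}

.dissimilarity_matrix <- function(sup, region_start, region_end) {
  n <- nrow(sup)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      po <- pair_overlap(sup$start_bp[i], sup$end_bp[i],
                         sup$start_bp[j], sup$end_bp[j],
                         region_start, region_end)
      D[i, j] <- D[j, i] <- jaccard_dissimilarity(po)
    }
  }
  D
}

#' Split one common region into subregions
#'
#' Agglomerative clustering (\code{stats::hclust}) of the region's
#' supporting calls on the pairwise Jaccard overlap dissimilarity. The
#' dendrogram is cut at height \code{1 - cluster_limit}, so calls at least
#' \code{cluster_limit} similar end up in the same subregion. Each cluster
#' becomes a subregion whose boundaries are the minimum and maximum
#' positions of its member calls, clipped back to the parent region where
#' members overshoot it. Summary statistics (frequency, median confidence,
#' size) are recomputed on the members.
#'
#' @param region one row of a \code{cnv_regions} data frame.
#' @param calls the [cnv_calls] the region was derived from.
#' @param linkage "complete" (default), "single" or "average".
#' @param cluster_limit required within-cluster similarity in \[0, 1\];
#'   default 0.6.
#' @param samples all sample ids (frequency denominator).
#' @return A \code{cnv_regions} data frame of subregions in genomic order,
#'   with columns \code{parent_id} and \code{cluster} added; member sets
#'   partition the parent's supporting calls.
#' @export
refine_region <- function(region, calls,
                          linkage = c("complete", "single", "average"),
                          cluster_limit = 0.6,
                          samples = unique(calls$sample_id)) {
  linkage <- match.arg(linkage)
  stopifnot(cluster_limit >= 0, cluster_limit <= 1)
  ids <- region$support[[1]]
  if (length(ids) == 0L) stop("region has no supporting calls")
  sup <- calls[match(ids, calls$call_id), , drop = FALSE]
  if (nrow(sup) == 1L) {
    grp <- 1L
  } else {
    D <- .dissimilarity_matrix(sup, region$start_bp, region$end_bp)
    tree <- stats::hclust(stats::as.dist(D), method = linkage)
    # cutree(h) keeps merges at height <= h together; guard against
    # floating-point noise right at the cut
    grp <- stats::cutree(tree, h = 1 - cluster_limit + 1e-9)
  }
  parts <- lapply(split(seq_len(nrow(sup)), grp), function(idx) {
    m <- sup[idx, , drop = FALSE]
    start <- max(min(m$start_bp), region$start_bp)  # clip to parent
    end <- min(max(m$end_bp), region$end_bp)
    df <- .region_row(chromosome = region$chromosome,
                      state_class = region$state_class, kind = "cluster",
                      first_probe = NA_integer_, last_probe = NA_integer_,
                      start_bp = start, end_bp = end,
                      support = m$call_id, support_calls = m,
                      n_total_samples = length(samples))
    df
  })
  out <- do.call(rbind, parts)
  out$parent_id <- if (is.null(region$region_id)) NA_integer_ else region$region_id
  ord <- order(out$start_bp, out$end_bp)
  out <- out[ord, , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cnv_regions", "data.frame")
  attr(out, "total_samples") <- length(samples)
  out
}

#' Refine every region of a region set
#'
#' Applies [refine_region] to each row and concatenates the subregions in
#' genomic order.
#'
#' @inheritParams refine_region
#' @param regions a \code{cnv_regions} data frame.
#' @return A \code{cnv_regions} data frame of subregions with
#'   \code{parent_id} linking back to \code{regions$region_id}.
#' @export
refine_regions <- function(regions, calls,
                           linkage = c("complete", "single", "average"),
                           cluster_limit = 0.6,
                           samples = unique(calls$sample_id)) {
  linkage <- match.arg(linkage)
  parts <- lapply(seq_len(nrow(regions)), function(i) {
    refine_region(regions[i, , drop = FALSE], calls, linkage,
                  cluster_limit, samples)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) return(.empty_regions())
  ord <- order(as.integer(out$chromosome), out$start_bp, out$end_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- seq_len(nrow(out))
  class(out) <- c("cnv_regions", "data.frame")
  attr(out, "total_samples") <- length(samples)
  out
}
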