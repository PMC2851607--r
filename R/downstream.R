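#' Downstream analyses on common regions
#'
#' Once common regions are identified, each sample gets an integer copy
#' number at every region (its largest-overlap supporting call, diploid 2
#' otherwise), giving a samples x regions matrix for association testing
#' between groups and principal component analysis of CNV profiles.
#'
#' @name downstream
NULL

#' Samples x regions copy-number matrix
#'
#' @param regions a \code{cnv_regions} data frame (supports attached).
#' @param calls the [cnv_calls] behind the regions.
#' @param samples all sample ids (matrix rows).
#' @return Integer matrix, rows = samples, columns = regions in genomic
#'   order (named \code{region_<id>}), default entry 2.
#' @export
cn_matrix <- function(regions, calls, samples = unique(calls$sample_id)) {
  if (nrow(regions) == 0L) stop("no regions")
  cols <- vapply(seq_len(nrow(regions)), function(i) {
    region_sample_cn(regions[i, , drop = FALSE], calls, samples)
  }, integer(length(samples)))
  m <- matrix(cols, nrow = length(samples),
              dimnames = list(samples,
                              paste0("region_", regions$region_id)))
  m
}

#' Group-association tests per region
#'
#' For each region, samples are dichotomised into carriers (copy number
#' differing from 2) and non-carriers, and the carrier x group contingency
#' table is tested with Fisher's exact test (default) or the chi-square
#' test. With \code{dichotomize = FALSE}, the full copy-number x group
#' table is tested instead. Multiple testing is handled with the
#' Benjamini-Hochberg false discovery rate.
#'
#' @param matrix a [cn_matrix] (samples x regions).
#' @param groups data frame with columns sample_id, group.
#' @param test "fisher" (default) or "chisq".
#' @param dichotomize carrier/non-carrier (default TRUE) or genotype-level.
#' @return Data frame per region: region, p, q (BH-adjusted), and
#'   \code{no_carriers} flag (such regions get p = 1).
#' @export
association_test <- function(matrix, groups, test = c("fisher", "chisq"),
                             dichotomize = TRUE) {
  test <- match.arg(test)
  g <- groups$group[match(rownames(matrix), groups$sample_id)]
  if (anyNA(g)) stop("every sample in the matrix needs a group label")
  if (length(unique(g)) < 2L) stop("need at least 2 groups")
  res <- lapply(colnames(matrix), function(reg) {
    cn <- matrix[, reg]
    x <- if (dichotomize) factor(cn != 2L, levels = c(FALSE, TRUE)) else factor(cn)
    tab <- table(x, g)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    flag <- dichotomize && all(cn == 2L)
    p <- if (nrow(tab) < 2L) 1 else if (test == "fisher") {
      stats::fisher.test(tab, workspace = 2e6)$p.value
    } else {
      suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    data.frame(region = reg, p = p, no_carriers = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("region", "p", "q", "no_carriers")]
}

#' PCA of copy-number profiles
#'
#' Principal component analysis of the samples x regions copy-number
#' matrix (columns centered; scaling optional). Scores are deterministic:
#' each component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param matrix a [cn_matrix].
#' @param n_components number of components to return.
#' @param center,scale. passed to [stats::prcomp]; defaults TRUE / FALSE.
#' @return A list: \code{scores} (samples x components),
#'   \code{loadings}, \code{variance_explained} (proportions).
#' @export
pca_profiles <- function(matrix, n_components = 2, center = TRUE,
                         scale. = FALSE) {
  storage.mode(matrix) <- "double"
  if (all(apply(matrix, 2, stats::var) == 0)) {
    warning("constant copy-number matrix: all components have zero variance")
  }
  pc <- stats::prcomp(matrix, center = center, scale. = scale.)
  k <- min(n_components, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  rot[, flip] <- -rot[, flip]
  sc[, flip] <- -sc[, flip]
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  list(scores = sc, loadings = rot, variance_explained = ve)
}
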