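#' Hardy-Weinberg testing of copy-number genotypes
#'
#' Most common CNV regions are inherited, so in a healthy population the
#' integer copy numbers at a common region should follow Hardy-Weinberg
#' equilibrium (HWE). A diallelic loss region (copy numbers 0/1/2) maps to
#' genotypes as 0 = minor-allele homozygote, 1 = heterozygote,
#' 2 = reference homozygote; a diallelic gain region (2/3/4) maps as
#' 2 = reference homozygote, 3 = heterozygote, 4 = minor-allele
#' homozygote. Regions showing both losses and gains (or copy numbers
#' outside these ranges) are multiallelic: unphased copy number is then
#' ambiguous (different allele combinations give the same total) and no
#' HWE test is attempted.
#'
#' The rate of HWE violation across regions, computed per population group
#' on unrelated individuals, is the tuning signal for the COVER/COMPOSITE
#' thresholds: excess violation suggests the thresholds admit unreliable
#' regions.
#'
#' @name hwe
NULL

#' Per-sample copy number at a region
#'
#' Each sample's copy number is taken from its supporting call covering
#' the largest number of bases of the region; ties broken by higher
#' confidence, then lower copy number. Samples without a supporting call
#' are diploid (2).
#'
#' @param region one row of a \code{cnv_regions} data frame.
#' @param calls the [cnv_calls] the region was derived from.
#' @param samples character vector of all sample ids.
#' @return Named integer vector of copy numbers, one per sample.
#' @export
region_sample_cn <- function(region, calls, samples) {
  cn <- stats::setNames(rep(2L, length(samples)), samples)
  ids <- region$support[[1]]
  if (length(ids) == 0L) return(cn)
  sup <- calls[match(ids, calls$call_id), , drop = FALSE]
  ov <- pmin(sup$end_bp, region$end_bp) - pmax(sup$start_bp, region$start_bp) + 1
  ord <- order(-ov, -sup$confidence, sup$copy_number)
  sup <- sup[ord, , drop = FALSE]
  best <- sup[!duplicated(sup$sample_id), , drop = FALSE]
  hit <- best$sample_id %in% samples
  cn[best$sample_id[hit]] <- best$copy_number[hit]
  cn
}

.classify_allelicity <- function(cn) {
  u <- unique(cn)
  if (all(u %in% c(0L, 1L, 2L))) {
    if (all(u == 2L)) "monomorphic" else "diallelic-loss"
  } else if (all(u %in% c(2L, 3L, 4L))) {
    "diallelic-gain"
  } else {
    "multiallelic"
  }
}

#' Genotype a common region across samples
#'
#' Assigns every sample an integer copy number at the region (see
#' [region_sample_cn]), classifies the region's allelicity and, for
#' diallelic regions, maps copy numbers to (reference homozygote,
#' heterozygote, variant homozygote) counts.
#'
#' @inheritParams region_sample_cn
#' @return A list of class \code{region_genotypes}: \code{cn} (named
#'   vector), \code{allelicity}, \code{counts} (ref/het/var, NA for
#'   multiallelic regions) and \code{maf} (minor allele frequency, folded
#'   to \[0, 0.5\]).
#' @export
genotype_region <- function(region, calls, samples) {
  cn <- region_sample_cn(region, calls, samples)
  allelicity <- .classify_allelicity(cn)
  counts <- genotype_counts(cn, allelicity)
  maf <- if (is.null(counts)) NA_real_ else {
    f <- (2 * counts[["n_var_hom"]] + counts[["n_het"]]) / (2 * sum(counts))
    min(f, 1 - f)
  }
  structure(list(region_id = region$region_id, cn = cn,
                 allelicity = allelicity, counts = counts, maf = maf),
            class = "region_genotypes")
}

#' Map copy numbers to diallelic genotype counts
#'
#' @param cn integer copy numbers (a vector over samples).
#' @param allelicity "diallelic-loss", "diallelic-gain" or "monomorphic"
#'   (classified from \code{cn} when missing); multiallelic returns NULL.
#' @return Named vector (n_ref_hom, n_het, n_var_hom), or NULL.
#' @export
genotype_counts <- function(cn, allelicity = .classify_allelicity(cn)) {
  if (allelicity == "multiallelic") return(NULL)
  if (allelicity == "diallelic-gain") {
    c(n_ref_hom = sum(cn == 2L), n_het = sum(cn == 3L),
      n_var_hom = sum(cn == 4L))
  } else {
    c(n_ref_hom = sum(cn == 2L), n_het = sum(cn == 1L),
      n_var_hom = sum(cn == 0L))
  }
}

#' Hardy-Weinberg test on genotype counts
#'
#' The default is the conditional exact test: given the observed allele
#' counts, the probability of each possible heterozygote count is computed
#' under HWE and the two-sided p-value is the sum of the probabilities of
#' all configurations no more probable than the observed one. The
#' chi-square option is the usual 1-df goodness-of-fit test against the
#' expected HWE frequencies. Monomorphic counts (no heterozygotes, no
#' variant homozygotes) return p = 1 by convention.
#'
#' @param counts named vector (n_ref_hom, n_het, n_var_hom).
#' @param method "exact" (default) or "chisq".
#' @return p-value in \[0, 1\].
#' @export
hwe_test <- function(counts, method = c("exact", "chisq")) {
  method <- match.arg(method)
  n_ref <- counts[["n_ref_hom"]]; n_het <- counts[["n_het"]]
  n_var <- counts[["n_var_hom"]]
  n <- n_ref + n_het + n_var
  if (n < 1L) stop("empty genotype table")
  if (n_het == 0 && (n_var == 0 || n_ref == 0)) return(1)
  if (method == "exact") {
    .hwe_exact_p(n_ref, n_het, n_var)
  } else {
    n1 <- 2 * n_var + n_het
    q <- n1 / (2 * n)
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- c(n_ref, n_het, n_var)
    x2 <- sum((obs - expected)^2 / expected)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
}

# conditional distribution of the heterozygote count given allele counts;
# log-space for numerical stability at large n
.hwe_exact_p <- function(n_ref, n_het, n_var) {
  n <- n_ref + n_het + n_var
  n1 <- 2 * n_var + n_het          # variant allele count
  hets <- seq.int(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  nv <- (n1 - hets) / 2
  nr <- n - hets - nv
  logp <- lgamma(n + 1) - lgamma(nr + 1) - lgamma(hets + 1) -
    lgamma(nv + 1) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}

#' HWE violation rate over a set of regions
#'
#' Restricted to diallelic regions (monomorphic included, with p = 1).
#' Within each group, genotype counts are taken over the unrelated
#' samples of that group, and a region violates HWE if any group's
#' p-value falls below \code{alpha}.
#'
#' @param genotypes list of \code{region_genotypes} (from
#'   [genotype_region]).
#' @param groups data frame with columns sample_id, group, unrelated (see
#'   [read_sample_groups]).
#' @param alpha per-test significance level; default 0.01.
#' @param method passed to [hwe_test].
#' @return A list: \code{rate} (violating / diallelic), \code{n_diallelic},
#'   \code{n_violating}, and per-region minimum p-values.
#' @export
violation_rate <- function(genotypes, groups, alpha = 0.01,
                           method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  dial <- vapply(genotypes, function(g) g$allelicity != "multiallelic",
                 logical(1))
  if (!any(dial)) stop("no diallelic regions: violation rate undefined")
  keep <- groups[groups$unrelated, , drop = FALSE]
  by_group <- split(keep$sample_id, keep$group)
  min_p <- vapply(genotypes[dial], function(g) {
    ps <- vapply(by_group, function(ids) {
      ids <- intersect(ids, names(g$cn))
      if (length(ids) == 0L) return(1)
      cnt <- genotype_counts(g$cn[ids], g$allelicity)
      if (is.null(cnt)) return(1)
      hwe_test(cnt, method)
    }, numeric(1))
    min(ps)
  }, numeric(1))
  viol <- min_p < alpha
  list(rate = mean(viol), n_diallelic = sum(dial),
       n_violating = sum(viol), min_p = min_p)
}

#' Threshold tuning by HWE violation rate
#'
#' Runs the full COVER or COMPOSITE pipeline for every grid point and
#' tabulates the resulting number of regions, the HWE violation rate (per
#' group, unrelated samples), the mean minor allele frequency of
#' diallelic regions and the median region size. The row after which the
#' violation rate drops steepest (most negative first difference) is
#' flagged; the table, not an automatic choice, is the product, since
#' threshold selection also weighs region size and external concordance.
#'
#' @param calls a [cnv_calls] data frame.
#' @param probes a [probe_map] or NULL (derived grid).
#' @param groups sample-group table (see [read_sample_groups]).
#' @param grid for method "cover", a data frame with columns
#'   \code{percentile} (confidence percentile for c) and \code{u}; for
#'   "composite", a numeric vector of score percentiles for v.
#' @param method "cover" or "composite".
#' @param alpha significance level for the HWE test; default 0.01.
#' @param state passed to the pipeline ("separate" or "combined").
#' @param samples all sample ids.
#' @return A data frame with one row per grid point: the settings,
#'   n_regions, violation_rate, mean_maf, median_size_kb and a logical
#'   \code{steepest_drop} flag.
#' @export
tune_thresholds <- function(calls, probes = NULL, groups, grid,
                            method = c("cover", "composite"),
                            alpha = 0.01,
                            state = c("separate", "combined"),
                            samples = unique(calls$sample_id)) {
  method <- match.arg(method)
  state <- match.arg(state)
  if (method == "cover") {
    stopifnot(is.data.frame(grid), all(c("percentile", "u") %in% names(grid)))
    settings <- grid
  } else {
    stopifnot(is.numeric(grid), length(grid) > 0)
    settings <- data.frame(percentile = grid)
  }
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    regs <- if (method == "cover") {
      cover_regions(calls, probes, conf_percentile = settings$percentile[i],
                    min_individuals = settings$u[i], state = state,
                    samples = samples)
    } else {
      composite_regions(calls, probes,
                        score_percentile = settings$percentile[i],
                        state = state, samples = samples)
    }
    out <- settings[i, , drop = FALSE]
    out$n_regions <- nrow(regs)
    if (nrow(regs) == 0L) {
      out$violation_rate <- NA_real_
      out$mean_maf <- NA_real_
      out$median_size_kb <- NA_real_
      return(out)
    }
    gt <- lapply(seq_len(nrow(regs)), function(j) {
      genotype_region(regs[j, , drop = FALSE], calls, samples)
    })
    vr <- tryCatch(violation_rate(gt, groups, alpha),
                   error = function(e) NULL)
    out$violation_rate <- if (is.null(vr)) NA_real_ else vr$rate
    mafs <- vapply(gt, `[[`, numeric(1), "maf")
    out$mean_maf <- mean(mafs, na.rm = TRUE)
    out$median_size_kb <- stats::median(regs$size_kb)
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$steepest_drop <- FALSE
  if (nrow(tab) > 1L) {
    d <- diff(tab$violation_rate)
    if (any(is.finite(d))) {
      tab$steepest_drop[which.min(d) + 1L] <- TRUE
    }
  }
  tab
}
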