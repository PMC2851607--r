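#' Concordance with reference CNV lists
#'
#' A detected common region is concordant with a reference CNV when it is
#' contained within the reference interval, or when it overlaps at least
#' 50% of the reference interval. Note the 50% is a fraction of the
#' REFERENCE covered, not reciprocal overlap (most interval tools default
#' to reciprocal). A sample's discordance rate is the proportion of the
#' common regions attributed to it (i.e. regions it supports) that are
#' concordant with none of that sample's reference CNVs.
#'
#' @name evaluate
NULL

#' Is a region concordant with a reference CNV?
#'
#' @param region_chr,region_start,region_end the detected region (1-based
#'   inclusive).
#' @param ref_chr,ref_start,ref_end the reference CNV.
#' @param region_type,ref_type optional state labels; when
#'   \code{match_type} is TRUE and the reference type is known
#'   ("loss"/"gain"), the types must agree.
#' @param match_type require matching CNV type; default FALSE.
#' @return TRUE iff the region is contained in the reference, or covers at
#'   least half of it (base counts, 1-based inclusive). Different
#'   chromosomes give FALSE.
#' @export
is_concordant <- function(region_chr, region_start, region_end,
                          ref_chr, ref_start, ref_end,
                          region_type = NULL, ref_type = "unknown",
                          match_type = FALSE) {
  if (.norm_chrom(region_chr) != .norm_chrom(ref_chr)) return(FALSE)
  if (match_type && !is.null(region_type) &&
      ref_type %in% c("loss", "gain") && region_type != ref_type) {
    return(FALSE)
  }
  contained <- region_start >= ref_start && region_end <= ref_end
  ov <- .bases_overlap(region_start, region_end, ref_start, ref_end)
  ref_len <- ref_end - ref_start + 1
  contained || ov >= 0.5 * ref_len
}

.any_concordant <- function(region, refs, match_type = FALSE) {
  for (j in seq_len(nrow(refs))) {
    if (is_concordant(region$chromosome, region$start_bp, region$end_bp,
                      refs$chromosome[j], refs$start_bp[j], refs$end_bp[j],
                      region_type = region$state_class,
                      ref_type = refs$type[j], match_type = match_type)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Discordance rate of one sample's regions against its reference CNVs
#'
#' @param sample_regions \code{cnv_regions} rows attributed to one sample.
#' @param sample_reference that sample's reference CNVs (see
#'   [read_reference_cnvs]).
#' @param match_type require matching CNV type; default FALSE.
#' @return Proportion of regions concordant with no reference CNV; NA when
#'   no regions are evaluated; 1 (with a warning) when the reference list
#'   is empty.
#' @export
discordance_rate <- function(sample_regions, sample_reference,
                             match_type = FALSE) {
  if (nrow(sample_regions) == 0L) return(NA_real_)
  if (nrow(sample_reference) == 0L) {
    warning("empty reference list: every region is discordant")
    return(1)
  }
  conc <- vapply(seq_len(nrow(sample_regions)), function(i) {
    .any_concordant(sample_regions[i, , drop = FALSE], sample_reference,
                    match_type)
  }, logical(1))
  1 - mean(conc)
}

#' Per-sample concordance report
#'
#' For every sample present in the reference list, evaluates the common
#' regions attributed to that sample (regions whose supporting calls
#' include it) against that sample's reference CNVs.
#'
#' @param regions a \code{cnv_regions} data frame with supports attached.
#' @param calls the [cnv_calls] behind the regions.
#' @param reference a reference CNV table (see [read_reference_cnvs]).
#' @param match_type require matching CNV type; default FALSE.
#' @return Data frame: sample_id, n_regions_evaluated, n_concordant,
#'   discordance_rate; attribute \code{mean_discordance} holds the mean
#'   over samples with at least one evaluated region.
#' @export
concordance_report <- function(regions, calls, reference,
                               match_type = FALSE) {
  ss <- support_samples(regions, calls)
  out <- lapply(unique(reference$sample_id), function(s) {
    mine <- vapply(ss, function(x) s %in% x, logical(1))
    sr <- regions[mine, , drop = FALSE]
    refs <- reference[reference$sample_id == s, , drop = FALSE]
    dr <- discordance_rate(sr, refs, match_type)
    data.frame(sample_id = s, n_regions_evaluated = nrow(sr),
               n_concordant = if (nrow(sr)) round((1 - dr) * nrow(sr)) else 0L,
               discordance_rate = dr, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  attr(rep, "mean_discordance") <-
    mean(rep$discordance_rate, na.rm = TRUE)
  rep
}

#' Summary statistics of a region set
#'
#' @param regions a non-empty \code{cnv_regions} data frame.
#' @return Data frame (one row): n_regions, mean_frequency,
#'   median_confidence (median over the per-region median supporting-call
#'   confidences), mean_size_kb, median_size_kb.
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0L) stop("no regions to summarise")
  data.frame(
    n_regions = nrow(regions),
    mean_frequency = mean(regions$frequency),
    median_confidence = stats::median(regions$median_confidence, na.rm = TRUE),
    mean_size_kb = mean(regions$size_kb),
    median_size_kb = stats::median(regions$size_kb)
  )
}

#' Concordance of one region set against another
#'
#' Checks each region of set A for concordance (same rule as
#' [is_concordant]) with any region of set B, then summarises the
#' concordant and non-concordant groups separately: the layout used to
#' compare region sets produced by different methods.
#'
#' @param regions_a,regions_b \code{cnv_regions} data frames on the same
#'   coordinate system.
#' @param match_type require matching CNV type; default FALSE.
#' @return A list: \code{concordant} (logical per region of A) and
#'   \code{summary}, a data frame with rows "concordant"/"discordant"
#'   carrying n, mean frequency and median confidence.
#' @export
cross_method_concordance <- function(regions_a, regions_b,
                                     match_type = FALSE) {
  refs <- data.frame(chromosome = regions_b$chromosome,
                     start_bp = regions_b$start_bp,
                     end_bp = regions_b$end_bp,
                     type = regions_b$state_class,
                     stringsAsFactors = FALSE)
  conc <- vapply(seq_len(nrow(regions_a)), function(i) {
    .any_concordant(regions_a[i, , drop = FALSE], refs, match_type)
  }, logical(1))
  summ <- do.call(rbind, lapply(c(TRUE, FALSE), function(f) {
    sub <- regions_a[conc == f, , drop = FALSE]
    data.frame(group = if (f) "concordant" else "discordant",
               n = nrow(sub),
               mean_frequency = if (nrow(sub)) mean(sub$frequency) else NA_real_,
               median_confidence = if (nrow(sub)) {
                 stats::median(sub$median_confidence, na.rm = TRUE)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(concordant = conc, summary = summ)
}
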