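#' Write common regions to BED or TSV
#'
#' Internal coordinates are 1-based inclusive; BED output converts to the
#' 0-based half-open convention (start_bp - 1, end_bp). TSV output carries
#' the full summary (probe span, support counts, frequency, median
#' confidence, size in kb to one decimal) and round-trips through
#' [read_regions].
#'
#' @param regions a \code{cnv_regions} data frame.
#' @param path output file path.
#' @param format "tsv" (default) or "bed".
#' @param header optional character vector of comment lines (written with a
#'   leading "#") recording provenance.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed"),
                          header = NULL) {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  cols <- c("region_id", "chromosome", "state_class", "kind",
            "first_probe", "last_probe", "start_bp", "end_bp",
            "n_support", "n_samples", "frequency", "median_confidence",
            "size_kb")
  if (is.null(regions$region_id)) regions$region_id <- seq_len(nrow(regions))
  if (format == "bed") {
    name <- sprintf("%s_region_%d_%s", regions$kind, regions$region_id,
                    regions$state_class)
    bed <- data.frame(chrom = paste0("chr", regions$chromosome),
                      start = regions$start_bp - 1L,
                      end = regions$end_bp,
                      name = if (nrow(regions)) name else character(),
                      score = regions$n_samples,
                      stringsAsFactors = FALSE)
    writeLines("#chrom\tstart\tend\tname\tscore", con)
    if (nrow(bed) > 0L) {
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  } else {
    tab <- as.data.frame(regions)[, cols, drop = FALSE]
    tab$size_kb <- sprintf("%.1f", tab$size_kb)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a region TSV written by [write_regions]
#'
#' Restores all summary columns; the \code{support} call-id list is not
#' serialised and comes back empty. Use [attach_support] to re-link
#' supporting calls if needed.
#'
#' @param path path to a region TSV.
#' @param total_samples optional frequency denominator to attach.
#' @return A \code{cnv_regions} data frame.
#' @export
read_regions <- function(path, total_samples = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  tab$chromosome <- .norm_chrom(tab$chromosome)
  tab$support <- I(rep(list(integer()), nrow(tab)))
  class(tab) <- c("cnv_regions", "data.frame")
  if (!is.null(total_samples)) attr(tab, "total_samples") <- total_samples
  tab
}

#' Re-link supporting calls to regions read from disk
#'
#' Fills each region's \code{support} list with the call_ids of calls of
#' the matching state class overlapping the region span. For regions of
#' kind "cover", pass the confidence cutoff the regions were produced
#' with, so that only qualifying calls are attached.
#'
#' @param regions a \code{cnv_regions} data frame.
#' @param calls a [cnv_calls] data frame.
#' @param conf_cutoff confidence filter applied to supporting calls.
#' @return \code{regions} with the \code{support} column filled.
#' @export
attach_support <- function(regions, calls, conf_cutoff = 0) {
  sup <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cc <- filter_state(calls, regions$state_class[i])
    hit <- cc$chromosome == regions$chromosome[i] &
      cc$confidence >= conf_cutoff &
      cc$start_bp <= regions$end_bp[i] & cc$end_bp >= regions$start_bp[i]
    sup[[i]] <- cc$call_id[hit]
  }
  regions$support <- I(sup)
  regions
}

#' Samples supporting each region
#'
#' @param regions a \code{cnv_regions} data frame.
#' @param calls the [cnv_calls] the regions were derived from.
#' @return A list (one element per region) of distinct sample_ids.
#' @export
support_samples <- function(regions, calls) {
  lapply(regions$support, function(ids) {
    unique(calls$sample_id[match(ids, calls$call_id)])
  })
}
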