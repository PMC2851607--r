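#' Copy-number call tables
#'
#' A call table is a data frame with one row per detected CNV in one
#' individual, the segmented output of a per-sample caller (e.g. an HMM on
#' SNP-array intensities). Required columns:
#' \describe{
#'   \item{sample_id}{character, sample identifier}
#'   \item{chromosome}{character, autosome label ("1".."22", with or without
#'     a "chr" prefix, which is stripped)}
#'   \item{start_bp, end_bp}{integer, 1-based inclusive genomic span}
#'   \item{copy_number}{integer >= 0, never 2 (a call is an aberration)}
#'   \item{confidence}{finite non-negative reliability score, e.g. a log
#'     Bayes factor}
#' }
#' A derived \code{state} column ("loss" if copy_number < 2, "gain" if > 2)
#' and a stable \code{call_id} are added. Rows are ordered by
#' (chromosome, start_bp, sample_id).
#'
#' @name cnv_calls
NULL

.AUTOSOMES <- as.character(1:22)

.norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Build a validated CNV call table
#'
#' @param sample_id character vector of sample identifiers.
#' @param chromosome chromosome labels (autosomes; "chr" prefixes stripped).
#' @param start_bp,end_bp 1-based inclusive call boundaries.
#' @param copy_number integer copy numbers (aberrations only, never 2).
#' @param confidence finite, non-negative per-call confidence scores.
#' @return A data frame of class \code{cnv_calls}; see [cnv_calls].
#' @export
new_cnv_calls <- function(sample_id, chromosome, start_bp, end_bp,
                          copy_number, confidence) {
  calls <- data.frame(
    sample_id   = as.character(sample_id),
    chromosome  = .norm_chrom(chromosome),
    start_bp    = as.integer(round(as.numeric(start_bp))),
    end_bp      = as.integer(round(as.numeric(end_bp))),
    copy_number = as.integer(copy_number),
    confidence  = as.numeric(confidence),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(calls)
}

#' @rdname new_cnv_calls
#' @param calls a data frame with the columns of [cnv_calls].
#' @export
validate_cnv_calls <- function(calls) {
  bad <- which(calls$start_bp > calls$end_bp)
  if (length(bad) > 0L) {
    stop("start_bp > end_bp in call row(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(calls$confidence)) || any(calls$confidence < 0)) {
    stop("confidence scores must be finite and non-negative")
  }
  if (any(calls$copy_number < 0L)) stop("copy_number must be >= 0")

  cn2 <- calls$copy_number == 2L
  if (any(cn2)) {
    warning(sum(cn2), " call(s) with copy_number = 2 rejected (not aberrations)")
    calls <- calls[!cn2, , drop = FALSE]
  }
  nonauto <- !(calls$chromosome %in% .AUTOSOMES)
  if (any(nonauto)) {
    warning(sum(nonauto), " call(s) on non-autosomal chromosomes dropped")
    calls <- calls[!nonauto, , drop = FALSE]
  }
  calls$state <- ifelse(calls$copy_number < 2L, "loss", "gain")
  ord <- order(as.integer(calls$chromosome), calls$start_bp, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls$call_id <- seq_len(nrow(calls))
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

#' Read a CNV call table from a tab-delimited file
#'
#' The file must carry one row per call with sample name, chromosome,
#' integer copy number, start and end genomic positions and a confidence
#' score. Column names are remappable via \code{dialect}, so tables from
#' different callers (e.g. PennCNV-style exports) can be read directly.
#' Non-autosomal rows are dropped with a warning; rows with copy number 2
#' are rejected with a warning.
#'
#' @param path path to a tab-delimited text file with a header line.
#' @param dialect named character vector mapping the internal column names
#'   (\code{sample_id}, \code{chromosome}, \code{start_bp}, \code{end_bp},
#'   \code{copy_number}, \code{confidence}) to the file's column names.
#' @return A validated [cnv_calls] data frame ordered by
#'   (chromosome, start_bp, sample_id).
#' @export
read_cnv_calls <- function(path,
                           dialect = c(sample_id = "sample_id",
                                       chromosome = "chromosome",
                                       start_bp = "start_bp",
                                       end_bp = "end_bp",
                                       copy_number = "copy_number",
                                       confidence = "confidence")) {
  if (!file.exists(path)) stop("call table not found: ", path)
  need <- c("sample_id", "chromosome", "start_bp", "end_bp",
            "copy_number", "confidence")
  dflt <- stats::setNames(need, need)
  dflt[names(dialect)] <- dialect
  dialect <- dflt
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(unname(dialect[need]), names(raw))
  if (length(miss) > 0L) {
    stop("call table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  new_cnv_calls(
    sample_id   = raw[[dialect[["sample_id"]]]],
    chromosome  = raw[[dialect[["chromosome"]]]],
    start_bp    = raw[[dialect[["start_bp"]]]],
    end_bp      = raw[[dialect[["end_bp"]]]],
    copy_number = raw[[dialect[["copy_number"]]]],
    confidence  = raw[[dialect[["confidence"]]]]
  )
}

#' Subset calls by CNV state class
#'
#' @param calls a [cnv_calls] data frame.
#' @param state_class "loss", "gain", or "combined" (no filtering).
#' @return The matching subset of \code{calls}.
#' @export
filter_state <- function(calls, state_class = c("combined", "loss", "gain")) {
  state_class <- match.arg(state_class)
  if (state_class == "combined") return(calls)
  calls[calls$state == state_class, , drop = FALSE]
}

#' Read a sample-to-group table
#'
#' Expects tab-delimited columns \code{sample_id}, \code{group} and an
#' optional logical \code{unrelated} flag (defaults to TRUE when absent).
#' The unrelated flag marks the subset on which Hardy-Weinberg tests are
#' run; related individuals stay in the call set but are excluded from the
#' per-group genotype counts.
#'
#' @param path path to the group table.
#' @return data frame with columns sample_id, group, unrelated.
#' @export
read_sample_groups <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    stop("group table needs columns: sample_id, group")
  }
  if (is.null(tab$unrelated)) tab$unrelated <- TRUE
  tab$unrelated <- as.logical(tab$unrelated)
  tab[, c("sample_id", "group", "unrelated")]
}

#' Read a reference CNV table
#'
#' A reference list (e.g. sequencing-validated CNVs for a subset of samples)
#' used for concordance evaluation: tab-delimited columns \code{sample_id},
#' \code{chromosome}, \code{start_bp}, \code{end_bp} and an optional
#' \code{type} ("loss", "gain" or "unknown"; defaults to "unknown").
#'
#' @param path path to the reference table.
#' @return data frame with the columns above, "chr" prefixes stripped.
#' @export
read_reference_cnvs <- function(path) {
  if (!file.exists(path)) stop("reference table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "chromosome", "start_bp", "end_bp")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("reference table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(tab$type)) tab$type <- "unknown"
  tab$chromosome <- .norm_chrom(tab$chromosome)
  bad <- which(tab$start_bp > tab$end_bp)
  if (length(bad) > 0L) {
    stop("start_bp > end_bp in reference row(s): ", paste(bad, collapse = ", "))
  }
  tab[, c("sample_id", "chromosome", "start_bp", "end_bp", "type")]
}
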