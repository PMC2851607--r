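#' Probe maps
#'
#' The per-probe statistics are defined on an ordered grid of probe
#' positions per chromosome (a SNP-array manifest). When no manifest is
#' available the grid can be derived from the calls themselves: the
#' statistics are piecewise constant between call breakpoints, so the union
#' of breakpoints is a lossless pseudo-probe grid.
#'
#' A \code{probe_map} is a named list (chromosome -> strictly increasing
#' integer vector of positions).
#'
#' @name probe_map
NULL

new_probe_map <- function(positions) {
  stopifnot(is.list(positions), length(positions) > 0L)
  out <- lapply(positions, function(p) {
    p <- sort(unique(as.integer(p)))
    if (length(p) < 1L) stop("a chromosome with zero probes is not allowed")
    p
  })
  structure(out, class = "probe_map")
}

#' Derive a pseudo-probe grid from call breakpoints
#'
#' Per chromosome, the sorted set of all distinct call start and end
#' positions. Every call covers at least one pseudo-probe (its own start).
#' The result is invariant to the input ordering of calls.
#'
#' @param calls a [cnv_calls] data frame (non-empty).
#' @return A [probe_map].
#' @export
derive_probe_map <- function(calls) {
  if (nrow(calls) == 0L) stop("cannot derive a probe map from zero calls")
  pos <- split(c(calls$start_bp, calls$end_bp),
               c(calls$chromosome, calls$chromosome))
  new_probe_map(pos)
}

#' Read a probe manifest
#'
#' Two tab-delimited columns, \code{chromosome} and \code{position}.
#' Positions are sorted per chromosome; duplicates are collapsed with a
#' warning; non-autosomal probes are dropped silently.
#'
#' @param path path to the manifest.
#' @return A [probe_map].
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("probe manifest not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("chromosome", "position") %in% names(tab))) {
    stop("probe manifest needs columns: chromosome, position")
  }
  if (nrow(tab) == 0L) stop("probe manifest is empty")
  if (is.character(tab$position) &&
      anyNA(suppressWarnings(as.numeric(tab$position)))) {
    stop("probe manifest has non-numeric positions")
  }
  pos <- as.numeric(tab$position)
  if (any(pos != round(pos))) stop("probe positions must be integers")
  tab$chromosome <- .norm_chrom(tab$chromosome)
  tab <- tab[tab$chromosome %in% .AUTOSOMES, , drop = FALSE]
  if (nrow(tab) == 0L) stop("probe manifest has no autosomal probes")
  ndup <- sum(duplicated(tab[, c("chromosome", "position")]))
  if (ndup > 0L) warning(ndup, " duplicate probe position(s) collapsed")
  new_probe_map(split(as.integer(tab$position), tab$chromosome))
}

#' @export
print.probe_map <- function(x, ...) {
  cat("probe_map:", length(x), "chromosome(s),",
      sum(lengths(x)), "probes\n")
  invisible(x)
}

# first/last probe index covered by [start, end]; (first > last) => no probe
.probe_span <- function(positions, start, end) {
  first <- findInterval(start - 1L, positions) + 1L
  last <- findInterval(end, positions)
  list(first = first, last = last)
}
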