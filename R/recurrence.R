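#' Per-probe recurrence statistics
#'
#' Two per-probe statistics summarise how consistently a probe is covered
#' by CNV calls across individuals:
#' \itemize{
#'   \item COVER: \eqn{y_k} = number of calls with confidence >= c that
#'     overlap probe k. Only reliable calls count, each with weight one.
#'   \item COMPOSITE: \eqn{s_k} = sum of the confidence scores of all calls
#'     overlapping probe k. Every call contributes, proportionally to its
#'     confidence.
#' }
#' Common regions are maximal runs of consecutive probes whose statistic
#' stays at or above a threshold (u for COVER, v for COMPOSITE).
#'
#' A \code{probe_track} is a list with elements \code{chromosome},
#' \code{state_class}, \code{kind} ("cover"/"composite"), \code{positions}
#' and \code{values} (aligned to positions).
#'
#' @name recurrence
NULL

new_probe_track <- function(chromosome, state_class, kind, positions, values,
                            gap_values = NULL) {
  stopifnot(length(positions) == length(values), all(values >= 0))
  structure(list(chromosome = chromosome, state_class = state_class,
                 kind = kind, positions = positions, values = values,
                 gap_values = gap_values),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track [%s] chr%s %s: %d probes, max value %.3g\n",
              x$kind, x$chromosome, x$state_class,
              length(x$values), if (length(x$values)) max(x$values) else 0))
  invisible(x)
}

#' Resolve a confidence cutoff from a percentile
#'
#' Percentile of the pooled confidence scores of all calls (all samples,
#' all chromosomes), with linear interpolation between order statistics.
#' Percentile 0 returns the minimum, so filtering at percentile 0 keeps
#' every call (the filter is \code{confidence >= c}).
#'
#' @param calls a [cnv_calls] data frame (non-empty).
#' @param percentile value in \[0, 100\].
#' @return The confidence cutoff (scalar).
#' @export
resolve_confidence_cutoff <- function(calls, percentile) {
  if (nrow(calls) == 0L) stop("no calls: cannot resolve a confidence percentile")
  stopifnot(percentile >= 0, percentile <= 100)
  unname(stats::quantile(calls$confidence, percentile / 100, type = 7))
}

# calls filtered to one chromosome + state + confidence; shared by both tracks
.track_values <- function(calls, positions, weights) {
  M <- length(positions)
  vals <- numeric(M)
  if (nrow(calls) == 0L) return(vals)
  sp <- .probe_span(positions, calls$start_bp, calls$end_bp)
  keep <- sp$first <= sp$last
  if (!any(keep)) return(vals)
  first <- sp$first[keep]
  last <- sp$last[keep]
  w <- weights[keep]
  # difference-array accumulation, O(calls + probes)
  d <- numeric(M + 1L)
  for (i in seq_along(first)) {
    d[first[i]] <- d[first[i]] + w[i]
    d[last[i] + 1L] <- d[last[i] + 1L] - w[i]
  }
  pmax(cumsum(d[seq_len(M)]), 0)  # guard against cumsum round-off
}

# statistic on the open interval between consecutive probes: since every
# call start and end is known, it equals the weight of calls spanning the
# whole gap. Adjacent positions (no base between them) never break a run
# and carry +Inf. Used so that runs of probes do not bridge genomic
# stretches that no call covers (a sparse pseudo-probe grid has no probe
# there to break the run).
.gap_values <- function(calls, positions, weights) {
  M <- length(positions)
  if (M < 2L) return(numeric(0))
  gaps <- rep(Inf, M - 1L)
  open <- which(positions[-1L] > positions[-M] + 1L)
  for (g in open) {
    covers <- calls$start_bp <= positions[g] &
      calls$end_bp >= positions[g + 1L]
    gaps[g] <- sum(weights[covers])
  }
  gaps
}

.chrom_calls <- function(calls, probes, chromosome) {
  if (!chromosome %in% names(probes)) {
    stop("calls on chromosome ", chromosome, " but no probes there")
  }
  calls[calls$chromosome == chromosome, , drop = FALSE]
}

#' COVER track: per-probe count of reliable overlapping calls
#'
#' For each probe k on one chromosome, counts the calls of the requested
#' state class with confidence >= \code{conf_cutoff} whose span contains
#' the probe position. A sample with two qualifying calls over the same
#' probe contributes twice (the statistic sums over calls, not samples);
#' such overlaps are flagged with a warning.
#'
#' @param calls a [cnv_calls] data frame.
#' @param probes a [probe_map] covering every call chromosome.
#' @param conf_cutoff confidence threshold c; calls below it are ignored.
#' @param state_class "loss", "gain" or "combined".
#' @param chromosome chromosome to compute the track on.
#' @return A \code{probe_track} of kind "cover".
#' @export
cover_track <- function(calls, probes, conf_cutoff = 0,
                        state_class = c("combined", "loss", "gain"),
                        chromosome) {
  state_class <- match.arg(state_class)
  cc <- .chrom_calls(filter_state(calls, state_class), probes, chromosome)
  cc <- cc[cc$confidence >= conf_cutoff, , drop = FALSE]
  .warn_same_sample_overlaps(cc)
  w <- rep(1, nrow(cc))
  new_probe_track(chromosome, state_class, "cover", probes[[chromosome]],
                  .track_values(cc, probes[[chromosome]], w),
                  .gap_values(cc, probes[[chromosome]], w))
}

#' COMPOSITE track: per-probe sum of confidence scores
#'
#' For each probe k, the sum of the confidence scores of all calls of the
#' requested state class overlapping the probe. No confidence filter is
#' applied: low-confidence calls contribute, just with small weight.
#'
#' @inheritParams cover_track
#' @return A \code{probe_track} of kind "composite".
#' @export
composite_track <- function(calls, probes,
                            state_class = c("combined", "loss", "gain"),
                            chromosome) {
  state_class <- match.arg(state_class)
  cc <- .chrom_calls(filter_state(calls, state_class), probes, chromosome)
  .warn_same_sample_overlaps(cc)
  new_probe_track(chromosome, state_class, "composite", probes[[chromosome]],
                  .track_values(cc, probes[[chromosome]], cc$confidence),
                  .gap_values(cc, probes[[chromosome]], cc$confidence))
}

.warn_same_sample_overlaps <- function(cc) {
  if (nrow(cc) < 2L) return(invisible())
  for (s in unique(cc$sample_id[duplicated(cc$sample_id)])) {
    x <- cc[cc$sample_id == s, , drop = FALSE]
    x <- x[order(x$start_bp), , drop = FALSE]
    if (any(x$start_bp[-1L] <= x$end_bp[-nrow(x)])) {
      warning("sample ", s, " has overlapping calls of the same state; ",
              "each call contributes separately to the track")
      return(invisible())
    }
  }
  invisible()
}

#' Resolve a COMPOSITE threshold from a percentile
#'
#' Percentile (linear interpolation) of the pooled per-probe composite
#' scores across all supplied tracks, zeros included. Probes not covered
#' by any call score zero, so on sparse genomes low percentiles resolve to
#' zero and filtering is vacuous.
#'
#' @param tracks list of \code{probe_track}s of kind "composite".
#' @param percentile value in \[0, 100\].
#' @return The score threshold v (scalar).
#' @export
resolve_composite_threshold <- function(tracks, percentile) {
  if (length(tracks) == 0L) stop("no tracks supplied")
  stopifnot(percentile >= 0, percentile <= 100)
  pooled <- unlist(lapply(tracks, `[[`, "values"), use.names = FALSE)
  unname(stats::quantile(pooled, percentile / 100, type = 7))
}

#' Extract common regions as maximal runs of consecutive probes
#'
#' Returns the maximal runs of consecutive probes whose track value is
#' >= \code{threshold}. Runs additionally break between two consecutive
#' probes when the calls connecting them (spanning the whole between-probe
#' gap) fall below the threshold, so a region never bridges a genomic
#' stretch the statistic does not actually sustain -- important on sparse
#' pseudo-probe grids, which have no probe inside uncovered gaps to break
#' a run. Region boundaries are the genomic positions of the
#' run's first and last probe. Supporting calls are the qualifying calls
#' (same state class and, for COVER, confidence >= the track's cutoff)
#' that overlap at least one probe of the run.
#'
#' @param track a \code{probe_track}.
#' @param threshold u (cover) or v (composite); must be > 0.
#' @param calls the [cnv_calls] the track was computed from.
#' @param samples character vector of all sample identifiers (denominator
#'   of the region frequency); defaults to the distinct samples in
#'   \code{calls}.
#' @param conf_cutoff confidence filter to apply to supporting calls; use
#'   the same value the track was built with (0 for composite).
#' @return A \code{cnv_regions} data frame: one row per region with
#'   columns chromosome, state_class, kind, first_probe, last_probe,
#'   start_bp, end_bp, n_support, n_samples, frequency, median_confidence,
#'   size_kb, and a list column \code{support} of supporting call_ids.
#' @export
extract_regions <- function(track, threshold, calls,
                            samples = unique(calls$sample_id),
                            conf_cutoff = 0) {
  stopifnot(threshold > 0)
  cc <- filter_state(calls, track$state_class)
  cc <- cc[cc$chromosome == track$chromosome &
             cc$confidence >= conf_cutoff, , drop = FALSE]
  pos <- track$positions
  above <- track$values >= threshold
  # break runs across between-probe gaps no qualifying call spans: two
  # consecutive probes belong to one region only if some call(s) of
  # sufficient weight connect them (tracks built by cover_track /
  # composite_track carry these gap values; hand-built tracks without
  # them fall back to plain consecutive-probe runs)
  M <- length(above)
  connected <- if (is.null(track$gap_values)) {
    rep(TRUE, max(M - 1L, 0L))
  } else {
    track$gap_values >= threshold
  }
  if (M == 0L) return(.empty_regions())
  brk <- if (M > 1L) {
    !(above[-M] & above[-1L] & connected)
  } else logical(0)
  run_id <- cumsum(c(TRUE, brk))
  keep <- vapply(split(above, run_id), all, logical(1))
  idx_by_run <- split(seq_len(M), run_id)[keep]
  starts <- vapply(idx_by_run, min, integer(1))
  ends <- vapply(idx_by_run, max, integer(1))
  if (length(starts) == 0L) {
    return(.empty_regions())
  }
  sp <- .probe_span(pos, cc$start_bp, cc$end_bp)
  rows <- lapply(seq_along(starts), function(i) {
    sup <- which(sp$first <= ends[i] & sp$last >= starts[i] &
                   sp$first <= sp$last)
    .region_row(chromosome = track$chromosome,
                state_class = track$state_class, kind = track$kind,
                first_probe = starts[i], last_probe = ends[i],
                start_bp = pos[starts[i]], end_bp = pos[ends[i]],
                support = cc$call_id[sup],
                support_calls = cc[sup, , drop = FALSE],
                n_total_samples = length(samples))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cnv_regions", "data.frame")
  attr(out, "total_samples") <- length(samples)
  out
}

.region_row <- function(chromosome, state_class, kind, first_probe,
                        last_probe, start_bp, end_bp, support,
                        support_calls, n_total_samples) {
  df <- data.frame(
    chromosome = chromosome, state_class = state_class, kind = kind,
    first_probe = as.integer(first_probe),
    last_probe = as.integer(last_probe),
    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
    n_support = length(support),
    n_samples = length(unique(support_calls$sample_id)),
    frequency = length(unique(support_calls$sample_id)) / n_total_samples,
    median_confidence = if (length(support)) {
      stats::median(support_calls$confidence)
    } else NA_real_,
    size_kb = region_size_kb(start_bp, end_bp),
    stringsAsFactors = FALSE
  )
  df$support <- I(list(as.integer(support)))
  df
}

.empty_regions <- function() {
  out <- data.frame(
    chromosome = character(), state_class = character(), kind = character(),
    first_probe = integer(), last_probe = integer(),
    start_bp = integer(), end_bp = integer(),
    n_support = integer(), n_samples = integer(), frequency = numeric(),
    median_confidence = numeric(), size_kb = numeric(),
    stringsAsFactors = FALSE
  )
  out$support <- I(list())
  class(out) <- c("cnv_regions", "data.frame")
  out
}

#' Region size in kilobases
#'
#' Reporting convention used throughout: (end_bp - start_bp) / 1000,
#' rounded to one decimal.
#'
#' @param start_bp,end_bp 1-based inclusive region boundaries.
#' @return size in kb, one decimal.
#' @export
region_size_kb <- function(start_bp, end_bp) {
  round((as.numeric(end_bp) - as.numeric(start_bp)) / 1000, 1)
}

.bind_regions <- function(parts, total_samples) {
  parts <- parts[vapply(parts, nrow, 1L) > 0L]
  if (length(parts) == 0L) {
    out <- .empty_regions()
    out$region_id <- integer()
    attr(out, "total_samples") <- total_samples
    return(out)
  }
  out <- do.call(rbind, parts)
  ord <- order(as.integer(out$chromosome), out$first_probe, out$state_class)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- seq_len(nrow(out))
  class(out) <- c("cnv_regions", "data.frame")
  attr(out, "total_samples") <- total_samples
  out
}

.track_states <- function(state) {
  if (state == "separate") c("loss", "gain") else "combined"
}

#' Identify common CNV regions with the COVER statistic
#'
#' Full COVER pipeline over all chromosomes: resolve the confidence cutoff
#' (if given as a percentile), compute per-chromosome tracks, and extract
#' maximal runs with \eqn{y_k >= u}. By default losses and gains are
#' analysed as separate tracks.
#'
#' @param calls a [cnv_calls] data frame.
#' @param probes a [probe_map]; derived from call breakpoints when NULL.
#' @param conf_cutoff absolute confidence threshold c. Exactly one of
#'   \code{conf_cutoff} / \code{conf_percentile} must be given.
#' @param conf_percentile percentile in \[0, 100\] resolved against the
#'   pooled confidence scores of all calls.
#' @param min_individuals threshold u >= 1: minimum number of overlapping
#'   reliable calls in a common region.
#' @param state "separate" (default, loss and gain tracks analysed
#'   independently) or "combined".
#' @param samples all sample identifiers (frequency denominator).
#' @return A \code{cnv_regions} data frame in genomic order.
#' @export
cover_regions <- function(calls, probes = NULL, conf_cutoff = NULL,
                          conf_percentile = NULL, min_individuals = 3,
                          state = c("separate", "combined"),
                          samples = unique(calls$sample_id)) {
  state <- match.arg(state)
  stopifnot(min_individuals >= 1)
  if (is.null(conf_cutoff) == is.null(conf_percentile)) {
    stop("give exactly one of conf_cutoff or conf_percentile")
  }
  if (is.null(conf_cutoff)) {
    conf_cutoff <- resolve_confidence_cutoff(calls, conf_percentile)
  }
  if (is.null(probes)) probes <- derive_probe_map(calls)
  parts <- list()
  for (chrom in intersect(.AUTOSOMES, unique(calls$chromosome))) {
    for (st in .track_states(state)) {
      tr <- cover_track(calls, probes, conf_cutoff, st, chrom)
      parts[[paste(chrom, st)]] <-
        extract_regions(tr, min_individuals, calls, samples, conf_cutoff)
    }
  }
  out <- .bind_regions(parts, length(samples))
  attr(out, "conf_cutoff") <- conf_cutoff
  out
}

#' Identify common CNV regions with the COMPOSITE statistic
#'
#' Full COMPOSITE pipeline: compute confidence-weighted tracks for every
#' chromosome, resolve the score threshold v (if given as a percentile,
#' against the pooled per-probe scores of all tracks, zeros included), and
#' extract maximal runs with \eqn{s_k >= v}.
#'
#' @inheritParams cover_regions
#' @param score_cutoff absolute score threshold v. Exactly one of
#'   \code{score_cutoff} / \code{score_percentile} must be given.
#' @param score_percentile percentile in \[0, 100\] of the pooled per-probe
#'   composite scores.
#' @return A \code{cnv_regions} data frame in genomic order.
#' @export
composite_regions <- function(calls, probes = NULL, score_cutoff = NULL,
                              score_percentile = NULL,
                              state = c("separate", "combined"),
                              samples = unique(calls$sample_id)) {
  state <- match.arg(state)
  if (is.null(score_cutoff) == is.null(score_percentile)) {
    stop("give exactly one of score_cutoff or score_percentile")
  }
  if (is.null(probes)) probes <- derive_probe_map(calls)
  chroms <- intersect(.AUTOSOMES, unique(calls$chromosome))
  tracks <- list()
  for (chrom in chroms) {
    for (st in .track_states(state)) {
      tracks[[paste(chrom, st)]] <- composite_track(calls, probes, st, chrom)
    }
  }
  if (is.null(score_cutoff)) {
    score_cutoff <- resolve_composite_threshold(tracks, score_percentile)
  }
  thr <- max(score_cutoff, .Machine$double.xmin)  # v = 0: any covered probe
  parts <- lapply(tracks, extract_regions, threshold = thr,
                  calls = calls, samples = samples, conf_cutoff = 0)
  out <- .bind_regions(parts, length(samples))
  attr(out, "score_cutoff") <- score_cutoff
  out
}
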