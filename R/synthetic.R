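#' Simulated segmented CNV call tables
#'
#' A seedable generator of per-individual CNV call tables with planted
#' recurrent loci, emulating what a per-sample SNP-array caller emits:
#' diallelic loci whose genotypes are drawn at Hardy-Weinberg equilibrium,
#' per-call breakpoint jitter, confidence scores that grow with region
#' length (log-linear, mirroring the tendency of short, probe-poor calls
#' to score low), and unplanted low-confidence noise calls. A truth table
#' links every emitted call to its locus (or flags it as noise), so
#' recovery, frequency and calibration can be measured exactly.
#'
#' @name synthetic
NULL

# deterministic substream seed: adding a locus never perturbs the draws
# of existing loci
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 59999 * 35317 + i * 9973) %% 2147483629)
}

.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (k in 1:20) {
    neg <- x <= 0
    if (!any(neg)) break
    x[neg] <- stats::rnorm(sum(neg), mean, sd)
  }
  pmax(x, 0.01)
}

#' Specify planted recurrent loci
#'
#' @param chromosome autosome labels.
#' @param start_bp,end_bp core locus boundaries (before jitter).
#' @param type "loss" or "gain".
#' @param maf minor (variant) allele frequency in (0, 0.5]; recycled.
#'   Per-group frequencies can be given as extra columns named
#'   \code{maf_<group>} on the returned data frame.
#' @param jitter_sd SD (bp) of the Gaussian breakpoint jitter; recycled.
#' @param conf_a,conf_b,conf_sd confidence model: scores are drawn from
#'   Normal(conf_a + conf_b * log(length_bp), conf_sd), truncated at 0.
#' @return A locus-specification data frame for [simulate_population].
#' @export
locus_spec <- function(chromosome, start_bp, end_bp, type = "loss",
                       maf = 0.2, jitter_sd = 1000,
                       conf_a = -50, conf_b = 8, conf_sd = 5) {
  data.frame(chromosome = .norm_chrom(chromosome),
             start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
             type = type, maf = maf, jitter_sd = jitter_sd,
             conf_a = conf_a, conf_b = conf_b, conf_sd = conf_sd,
             stringsAsFactors = FALSE)
}

#' Random locus specification
#'
#' Lays \code{n_loci} non-overlapping loci across the autosomes (round
#' robin, 5 Mb apart) with lengths and allele frequencies drawn uniformly
#' from the given ranges.
#'
#' @param n_loci number of loci.
#' @param seed integer seed.
#' @param maf_range,size_range uniform ranges for allele frequency and
#'   locus length (bp).
#' @param type "loss", "gain", or "both" (alternating).
#' @inheritParams locus_spec
#' @return A locus-specification data frame.
#' @export
random_locus_spec <- function(n_loci, seed = 1,
                              maf_range = c(0.15, 0.4),
                              size_range = c(20e3, 60e3),
                              type = "loss", jitter_sd = 1000,
                              conf_a = -50, conf_b = 8, conf_sd = 5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, 104729L))
  chrom <- rep(.AUTOSOMES, length.out = n_loci)
  within <- stats::ave(seq_len(n_loci), chrom, FUN = seq_along)
  start <- as.integer(10e6 + (within - 1) * 5e6)
  len <- as.integer(round(stats::runif(n_loci, size_range[1], size_range[2])))
  maf <- stats::runif(n_loci, maf_range[1], maf_range[2])
  ty <- switch(type,
               both = rep(c("loss", "gain"), length.out = n_loci),
               rep(type, n_loci))
  locus_spec(chrom, start, start + len - 1L, ty, maf, jitter_sd,
             conf_a, conf_b, conf_sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a population of segmented CNV calls
#'
#' For every locus, each sample's genotype (copies of the variant allele)
#' is drawn at HWE with probabilities ((1-q)^2, 2q(1-q), q^2). Carriers
#' emit one call: breakpoints are the locus core plus rounded Gaussian
#' jitter (clipped to keep at least 1 bp and stay on the chromosome),
#' copy number is 1/0 for heterozygous/homozygous losses and 3/4 for
#' gains, and confidence follows the locus model. Noise calls (count per
#' sample ~ Poisson(noise_rate)) are placed uniformly away from planted
#' loci with low confidence. All draws flow from \code{seed}, with
#' per-locus substreams, so the same seed reproduces the output exactly.
#'
#' @param loci a locus-specification data frame ([locus_spec]); loci on
#'   one chromosome must not overlap.
#' @param n_per_group named integer vector, samples per group, e.g.
#'   \code{c(POP1 = 50, POP2 = 50)}.
#' @param noise_rate expected noise calls per sample; default 0.5.
#' @param seed integer seed.
#' @param chrom_length chromosome length (bp) used for noise placement.
#' @param noise_conf_mean,noise_conf_sd confidence model of noise calls.
#' @param noise_size_range uniform range (bp) of noise-call lengths.
#' @return A list: \code{calls} ([cnv_calls]), \code{groups} (sample_id,
#'   group, unrelated), \code{truth} (per emitted call: sample, locus
#'   index or NA for noise, genotype, span, copy number) and \code{loci}.
#' @export
simulate_population <- function(loci, n_per_group, noise_rate = 0.5,
                                seed = 1, chrom_length = 1.5e8,
                                noise_conf_mean = 5, noise_conf_sd = 3,
                                noise_size_range = c(1e3, 10e3)) {
  stopifnot(nrow(loci) >= 1L, !is.null(names(n_per_group)))
  if (!all(loci$chromosome %in% .AUTOSOMES)) {
    stop("loci must be on autosomes")
  }
  for (chr in unique(loci$chromosome)) {
    x <- loci[loci$chromosome == chr, , drop = FALSE]
    x <- x[order(x$start_bp), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start_bp[-1L] <= x$end_bp[-nrow(x)])) {
      stop("overlapping locus specifications on chromosome ", chr)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  groups <- data.frame(
    sample_id = unlist(lapply(names(n_per_group), function(g) {
      sprintf("%s_%03d", g, seq_len(n_per_group[[g]]))
    })),
    group = rep(names(n_per_group), unname(n_per_group)),
    unrelated = TRUE, stringsAsFactors = FALSE
  )
  n <- nrow(groups)

  rows <- list()
  truth <- list()
  for (l in seq_len(nrow(loci))) {
    set.seed(.derive_seed(seed, l))
    spec <- loci[l, , drop = FALSE]
    q <- vapply(groups$group, function(g) {
      col <- paste0("maf_", g)
      if (col %in% names(spec)) spec[[col]] else spec$maf
    }, numeric(1))
    geno <- vapply(q, function(qi) {
      sample.int(3L, 1L, prob = c((1 - qi)^2, 2 * qi * (1 - qi), qi^2)) - 1L
    }, integer(1))
    carrier <- geno > 0L
    nc <- sum(carrier)
    truth[[l]] <- data.frame(sample_id = groups$sample_id, locus = l,
                             genotype = geno, stringsAsFactors = FALSE)
    if (nc == 0L) next
    j1 <- round(stats::rnorm(nc, 0, spec$jitter_sd))
    j2 <- round(stats::rnorm(nc, 0, spec$jitter_sd))
    start <- pmax(1, spec$start_bp + j1)
    end <- pmax(start, spec$end_bp + j2)
    len <- end - start + 1
    conf <- .rnorm_pos(nc, spec$conf_a + spec$conf_b * log(len), spec$conf_sd)
    cn <- if (spec$type == "loss") {
      ifelse(geno[carrier] == 1L, 1L, 0L)
    } else {
      ifelse(geno[carrier] == 1L, 3L, 4L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = groups$sample_id[carrier], chromosome = spec$chromosome,
      start_bp = start, end_bp = end, copy_number = cn, confidence = conf,
      locus = l, stringsAsFactors = FALSE)
  }

  set.seed(.derive_seed(seed, 0L))
  n_noise <- stats::rpois(n, noise_rate)
  for (i in which(n_noise > 0L)) {
    for (k in seq_len(n_noise[i])) {
      for (try in 1:50) {
        chr <- sample(.AUTOSOMES, 1L)
        len <- round(stats::runif(1, noise_size_range[1], noise_size_range[2]))
        start <- ceiling(stats::runif(1, 1, chrom_length - len))
        end <- start + len - 1
        planted <- loci[loci$chromosome == chr, , drop = FALSE]
        clear <- nrow(planted) == 0L ||
          all(end < planted$start_bp | start > planted$end_bp)
        if (clear) break
      }
      if (!clear) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = groups$sample_id[i], chromosome = chr,
        start_bp = start, end_bp = end,
        copy_number = sample(c(0L, 1L, 3L, 4L), 1L),
        confidence = .rnorm_pos(1, noise_conf_mean, noise_conf_sd),
        locus = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  raw <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chromosome = character(),
               start_bp = integer(), end_bp = integer(),
               copy_number = integer(), confidence = numeric(),
               locus = integer(), stringsAsFactors = FALSE)
  calls <- if (nrow(raw)) {
    new_cnv_calls(raw$sample_id, raw$chromosome, raw$start_bp, raw$end_bp,
                  raw$copy_number, raw$confidence)
  } else {
    validate_cnv_calls(raw[, names(raw) != "locus"])
  }
  list(calls = calls, groups = groups,
       truth = list(genotypes = do.call(rbind, truth), emitted = raw),
       loci = loci)
}

#' Hand-checkable toy fixtures
#'
#' \describe{
#'   \item{cover_toy}{Three loss calls over a five-probe grid (spans
#'     probes 1-4, 2-5 and 3, confidences 10, 5, 1): the worked example
#'     for the per-probe statistics.}
#'   \item{figure2}{Four calls inside one common region, two clustered to
#'     the left and two to the right with a small mutual overlap: the
#'     canonical two-subregion geometry for CLUSTER.}
#'   \item{hwe_grid}{2,000 diallelic genotype tables (n = 100 samples
#'     each) drawn exactly at HWE with allele frequencies uniform on
#'     (0.1, 0.5), for calibrating the HWE violation rate.}
#' }
#'
#' @param name one of "cover_toy", "figure2", "hwe_grid".
#' @param seed integer seed (used by hwe_grid).
#' @return cover_toy/figure2: a list with \code{calls} (and for cover_toy
#'   \code{probes}); hwe_grid: a data frame of genotype counts with the
#'   true allele frequency.
#' @export
make_toy_fixture <- function(name, seed = 1) {
  switch(
    name,
    cover_toy = list(
      calls = new_cnv_calls(
        sample_id = c("S1", "S2", "S3"), chromosome = "1",
        start_bp = c(100L, 200L, 300L), end_bp = c(400L, 500L, 300L),
        copy_number = 1L, confidence = c(10, 5, 1)),
      probes = new_probe_map(list(`1` = c(100L, 200L, 300L, 400L, 500L)))
    ),
    figure2 = list(
      calls = new_cnv_calls(
        sample_id = c("S1", "S2", "S3", "S4"), chromosome = "1",
        start_bp = c(1L, 500L, 4500L, 5000L),
        end_bp = c(5000L, 5500L, 10000L, 9500L),
        copy_number = 1L, confidence = 30),
      left_pair = c("S1", "S2"), right_pair = c("S3", "S4")
    ),
    hwe_grid = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(.derive_seed(seed, 424243L))
      n_loci <- 2000L
      n <- 100L
      q <- stats::runif(n_loci, 0.1, 0.5)
      counts <- t(vapply(q, function(qi) {
        drop(stats::rmultinom(1, n, c((1 - qi)^2, 2 * qi * (1 - qi), qi^2)))
      }, numeric(3)))
      data.frame(n_ref_hom = counts[, 1], n_het = counts[, 2],
                 n_var_hom = counts[, 3], maf = q)
    },
    stop("unknown fixture: ", name)
  )
}
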