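# Independent brute-force oracles used across the suite. Deliberately
# naive (per-probe / per-base double loops, plain factorials) so they
# share no code path with the implementation they check.

oracle_cover <- function(calls, positions, conf_cutoff, state_class) {
  cc <- calls
  if (state_class != "combined") cc <- cc[cc$state == state_class, ]
  cc <- cc[cc$confidence >= conf_cutoff, ]
  vapply(positions, function(p) {
    sum(cc$start_bp <= p & cc$end_bp >= p)
  }, numeric(1))
}

oracle_composite <- function(calls, positions, state_class) {
  cc <- calls
  if (state_class != "combined") cc <- cc[cc$state == state_class, ]
  vapply(positions, function(p) {
    sum(cc$confidence[cc$start_bp <= p & cc$end_bp >= p])
  }, numeric(1))
}

# maximal runs of indices with value >= threshold, as (first, last) pairs
oracle_runs <- function(values, threshold) {
  runs <- list()
  open <- NA
  for (k in seq_along(values)) {
    if (values[k] >= threshold) {
      if (is.na(open)) open <- k
    } else if (!is.na(open)) {
      runs[[length(runs) + 1]] <- c(open, k - 1L)
      open <- NA
    }
  }
  if (!is.na(open)) runs[[length(runs) + 1]] <- c(open, length(values))
  runs
}

# per-base (a, b, c, d) over the region span
oracle_pair_overlap <- function(sa, ea, sb, eb, rs, re) {
  bases <- rs:re
  inA <- bases >= sa & bases <= ea
  inB <- bases >= sb & bases <= eb
  list(a = sum(inA & inB), b = sum(inA & !inB), c = sum(!inA & inB),
       d = sum(!inA & !inB), L = length(bases))
}

# exact conditional HWE p-value by direct enumeration with plain
# factorials (valid for n <= ~80)
oracle_hwe_exact <- function(n_ref, n_het, n_var) {
  n <- n_ref + n_het + n_var
  n1 <- 2 * n_var + n_het
  if (n_het == 0 && (n_var == 0 || n_ref == 0)) return(1)
  hets <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  w <- vapply(hets, function(h) {
    nv <- (n1 - h) / 2
    nr <- n - h - nv
    factorial(n) / (factorial(nr) * factorial(h) * factorial(nv)) * 2^h
  }, numeric(1))
  p <- w / sum(w)
  obs <- p[hets == n_het]
  sum(p[p <= obs * (1 + 1e-9)])
}

# random small instance: calls over an explicit probe grid on one
# chromosome
random_instance <- function(seed, max_calls = 20, max_probes = 50) {
  set.seed(seed)
  n_probes <- sample(2:max_probes, 1)
  positions <- sort(sample.int(10000, n_probes))
  n_calls <- sample(1:max_calls, 1)
  start <- sample.int(10000, n_calls, replace = TRUE)
  len <- sample.int(3000, n_calls, replace = TRUE)
  calls <- suppressWarnings(new_cnv_calls(
    sample_id = sprintf("S%02d", sample.int(max(2, n_calls %/% 2), n_calls,
                                            replace = TRUE)),
    chromosome = "1", start_bp = start, end_bp = start + len,
    copy_number = sample(c(0L, 1L, 3L, 4L), n_calls, replace = TRUE),
    confidence = round(stats::runif(n_calls, 0, 50), 2)))
  list(calls = calls, probes = new_probe_map(list(`1` = positions)))
}

counts_vec <- function(n_ref, n_het, n_var) {
  c(n_ref_hom = n_ref, n_het = n_het, n_var_hom = n_var)
}
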