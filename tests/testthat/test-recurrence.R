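test_that("confidence percentile uses linear interpolation over pooled scores", {
  calls <- new_cnv_calls(sprintf("S%d", 1:10), "1", seq(100L, 1000L, 100L),
                         seq(150L, 1050L, 100L), 1L, 1:10)
  expect_equal(resolve_confidence_cutoff(calls, 0), 1)
  expect_equal(resolve_confidence_cutoff(calls, 60), 6.4)
  expect_equal(resolve_confidence_cutoff(calls, 100), 10)

  flat <- new_cnv_calls(sprintf("S%d", 1:5), "1", 1:5 * 100L, 1:5 * 100L + 10L,
                        1L, 7)
  for (p in c(0, 33, 50, 100)) {
    expect_equal(resolve_confidence_cutoff(flat, p), 7)
  }
  expect_error(resolve_confidence_cutoff(calls[0, ], 50), "no calls")
})

test_that("cover track counts reliable overlapping calls per probe", {
  toy <- make_toy_fixture("cover_toy")
  tr <- cover_track(toy$calls, toy$probes, conf_cutoff = 4, "loss", "1")
  expect_equal(tr$values, c(1, 2, 2, 2, 1))
  expect_equal(cover_track(toy$calls, toy$probes, 0, "loss", "1")$values,
               c(1, 2, 3, 2, 1))
  expect_equal(cover_track(toy$calls, toy$probes, 99, "loss", "1")$values,
               rep(0, 5))
  expect_equal(cover_track(toy$calls, toy$probes, 0, "gain", "1")$values,
               rep(0, 5))
})

test_that("composite track sums confidences of all overlapping calls", {
  toy <- make_toy_fixture("cover_toy")
  tr <- composite_track(toy$calls, toy$probes, "loss", "1")
  expect_equal(tr$values, c(10, 15, 16, 15, 5))
})

test_that("tracks match the per-probe brute-force double loop", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    pos <- inst$probes[["1"]]
    cutoff <- sample(c(0, 5, 20, 35), 1)
    st <- sample(c("loss", "gain", "combined"), 1)
    got <- suppressWarnings(
      cover_track(inst$calls, inst$probes, cutoff, st, "1"))$values
    expect_equal(got, oracle_cover(inst$calls, pos, cutoff, st),
                 info = paste("cover seed", seed))
    gotc <- suppressWarnings(
      composite_track(inst$calls, inst$probes, st, "1"))$values
    expect_equal(gotc, oracle_composite(inst$calls, pos, st),
                 info = paste("composite seed", seed))
  }
})

test_that("composite percentile pools per-probe scores with zeros included", {
  mk <- function(vals) {
    structure(list(chromosome = "1", state_class = "combined",
                   kind = "composite", positions = seq_along(vals),
                   values = vals), class = "probe_track")
  }
  tracks <- list(mk(c(0, 0, 0, 0, 0)), mk(c(0, 0, 0, 0, 5)))
  # 90% zeros: any percentile inside the zero mass interpolates strictly
  # below the smallest nonzero score, so no covered probe is filtered and
  # the composite pipeline reduces to COVER with u = 1, c = 0
  expect_equal(resolve_composite_threshold(tracks, 50), 0)
  expect_lt(resolve_composite_threshold(tracks, 90), 5)
  expect_equal(resolve_composite_threshold(tracks, 100), 5)
  expect_equal(resolve_composite_threshold(list(mk(rep(0, 4))), 50), 0)
  expect_error(resolve_composite_threshold(list(), 50), "no tracks")
})

test_that("extract_regions returns maximal runs of consecutive probes", {
  pos <- seq(100L, 700L, 100L)
  calls <- new_cnv_calls("S1", "1", 100L, 700L, 1L, 1)  # placeholder support
  tr <- structure(list(chromosome = "1", state_class = "combined",
                       kind = "cover", positions = pos,
                       values = c(0, 1, 3, 3, 2, 3, 0)),
                  class = "probe_track")
  r3 <- extract_regions(tr, 3, calls)
  expect_equal(r3$first_probe, c(3L, 6L))
  expect_equal(r3$last_probe, c(4L, 6L))
  expect_equal(r3$start_bp, c(300L, 600L))
  expect_equal(r3$end_bp, c(400L, 600L))

  r1 <- extract_regions(tr, 1, calls)
  expect_equal(r1$first_probe, 2L)
  expect_equal(r1$last_probe, 6L)

  expect_equal(nrow(extract_regions(tr, 10, calls)), 0L)
})

test_that("run extraction matches the run-length oracle on random tracks", {
  for (seed in 1:40) {
    set.seed(seed + 7000)
    vals <- sample(0:4, 30, replace = TRUE)
    thr <- sample(1:4, 1)
    tr <- structure(list(chromosome = "1", state_class = "combined",
                         kind = "cover", positions = 1:30 * 10L,
                         values = vals), class = "probe_track")
    calls <- new_cnv_calls("S1", "1", 1L, 400L, 1L, 1)
    got <- extract_regions(tr, thr, calls)
    want <- oracle_runs(vals, thr)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$first_probe, vapply(want, `[`, numeric(1), 1))
      expect_equal(got$last_probe, vapply(want, `[`, numeric(1), 2))
    }
  }
})

test_that("supporting calls overlap the region and pass the filter", {
  toy <- make_toy_fixture("cover_toy")
  regs <- cover_regions(toy$calls, toy$probes, conf_cutoff = 4,
                        min_individuals = 2)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start_bp, 200L)
  expect_equal(regs$end_bp, 400L)
  sup <- toy$calls[match(regs$support[[1]], toy$calls$call_id), ]
  expect_true(all(sup$confidence >= 4))       # confidence filter applies
  expect_true(all(sup$start_bp <= regs$end_bp & sup$end_bp >= regs$start_bp))
  expect_equal(regs$frequency, 2 / 3)
  expect_equal(regs$median_confidence, 7.5)
})

test_that("probe-weight conservation holds on random instances", {
  for (seed in 101:120) {
    inst <- random_instance(seed)
    pos <- inst$probes[["1"]]
    tr <- suppressWarnings(
      cover_track(inst$calls, inst$probes, 0, "combined", "1"))
    per_call <- vapply(seq_len(nrow(inst$calls)), function(i) {
      sum(pos >= inst$calls$start_bp[i] & pos <= inst$calls$end_bp[i])
    }, numeric(1))
    expect_equal(sum(tr$values), sum(per_call))
  }
})

test_that("raising the confidence cutoff never increases any y_k", {
  for (seed in 201:215) {
    inst <- random_instance(seed)
    lo <- suppressWarnings(
      cover_track(inst$calls, inst$probes, 5, "combined", "1"))$values
    hi <- suppressWarnings(
      cover_track(inst$calls, inst$probes, 20, "combined", "1"))$values
    expect_true(all(hi <= lo))
  }
})

test_that("regions at u+1 are nested within regions at u", {
  for (seed in 301:315) {
    inst <- random_instance(seed)
    tr <- suppressWarnings(
      cover_track(inst$calls, inst$probes, 0, "combined", "1"))
    r_lo <- extract_regions(tr, 2, inst$calls)
    r_hi <- extract_regions(tr, 3, inst$calls)
    for (i in seq_len(nrow(r_hi))) {
      inside <- r_lo$first_probe <= r_hi$first_probe[i] &
        r_lo$last_probe >= r_hi$last_probe[i]
      expect_equal(sum(inside), 1L)
    }
  }
})

test_that("unit confidences collapse COMPOSITE onto unfiltered COVER", {
  for (seed in 401:420) {
    inst <- random_instance(seed)
    unit <- inst$calls
    unit$confidence <- 1
    s <- suppressWarnings(
      composite_track(unit, inst$probes, "combined", "1"))$values
    y <- suppressWarnings(
      cover_track(unit, inst$probes, 0, "combined", "1"))$values
    expect_equal(s, y)
    u <- sample(1:3, 1)
    ra <- suppressWarnings(composite_regions(unit, inst$probes,
                                             score_cutoff = u,
                                             state = "combined"))
    rb <- suppressWarnings(cover_regions(unit, inst$probes, conf_cutoff = 0,
                                         min_individuals = u,
                                         state = "combined"))
    expect_equal(as.data.frame(ra)[c("start_bp", "end_bp", "n_support")],
                 as.data.frame(rb)[c("start_bp", "end_bp", "n_support")])
  }
})

test_that("identical inputs give identical outputs in genomic order", {
  inst <- random_instance(500)
  a <- suppressWarnings(cover_regions(inst$calls, inst$probes,
                                      conf_percentile = 40,
                                      min_individuals = 2))
  b <- suppressWarnings(cover_regions(inst$calls, inst$probes,
                                      conf_percentile = 40,
                                      min_individuals = 2))
  expect_identical(a, b)
  if (nrow(a) > 1L) {
    expect_true(all(diff(order(as.integer(a$chromosome), a$first_probe)) > 0))
  }
})

test_that("a same-sample overlap contributes twice and warns", {
  calls <- new_cnv_calls(c("S1", "S1", "S2"), "1", c(100L, 150L, 100L),
                         c(300L, 350L, 300L), 1L, 10)
  probes <- new_probe_map(list(`1` = c(100L, 200L, 300L, 350L)))
  expect_warning(tr <- cover_track(calls, probes, 0, "loss", "1"),
                 "overlapping calls")
  expect_equal(tr$values, c(2, 3, 3, 1))
})
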