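test_that("log2 ratios are zero for equal channels and scale-invariant", {
  raw <- data.frame(probe_id = sprintf("P%02d", 1:11), replicon = "chr",
                    start = seq(0, 1000, by = 100), length = 50L,
                    enriched = 100, input = 100)
  tr <- compute_log2_ratios(raw)
  expect_true(all(tr$log2r == 0))

  raw$enriched[6] <- 400  # one probe 4x enriched
  tr2 <- compute_log2_ratios(raw)
  expect_equal(tr2$log2r[tr2$probe_id == "P06"], 2)

  # multiplying the enriched channel everywhere cancels after centering
  raw3 <- raw; raw3$enriched <- raw$enriched * 7.5
  expect_equal(compute_log2_ratios(raw3)$log2r, tr2$log2r, tolerance = 1e-12)

  raw$input[2] <- 0
  expect_error(compute_log2_ratios(raw), "P02")
})

test_that("hypothetical maximum is mean plus six sample sds", {
  expect_equal(hypothetical_max(c(0, 2)), 1 + 6 * sqrt(2))
  expect_equal(hypothetical_max(rep(3.5, 10)), 3.5)
  expect_error(hypothetical_max(1), "at least 2")
  expect_equal(0.9 * hypothetical_max(c(0, 2)), 0.9 * (1 + 6 * sqrt(2)))
})

test_that("window detection follows the more-than-four-probes/500-bp rule", {
  # 5 qualifying probes spanning 400 bp -> one peak with exactly those probes
  tr <- make_track(c(0, 0, 3, 3, 3, 3, 3, 0, 0),
                   starts = c(0, 100, 200, 287, 375, 462, 550, 700, 800))
  det <- detect_peaks_at_cutoff(tr, 1)
  expect_equal(nrow(det), 1L)
  expect_equal(det$probes[[1]], sprintf("P%06d", 3:7))
  expect_equal(det$start, 200L)
  expect_equal(det$end, 600L)

  # only 4 qualifying probes -> nothing
  tr4 <- make_track(c(0, 3, 3, 3, 3, 0), starts = seq(0, 500, by = 100))
  expect_equal(nrow(detect_peaks_at_cutoff(tr4, 1)), 0L)

  # 5 qualifying probes spanning 600 bp -> window violated
  tr600 <- make_track(c(3, 3, 3, 3, 3), starts = c(0, 140, 280, 420, 550))
  expect_equal(nrow(detect_peaks_at_cutoff(tr600, 1)), 0L)
})

test_that("window detection matches the brute-force enumerator exactly", {
  for (seed in 1:40) {
    tr <- random_track(n = sample(20:200, 1), seed = seed)
    cutoff <- stats::quantile(tr$log2r, probs = runif(1, 0.4, 0.95))
    got <- detect_peaks_at_cutoff(tr, cutoff)
    want <- brute_force_peaks(tr, cutoff)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$start[i], want[[i]]$start)
      expect_equal(got$end[i], want[[i]]$end)
      expect_identical(got$probes[[i]], want[[i]]$probes)
    }
  }
})

test_that("peak scores take the fourth-highest member probe", {
  vals <- c(rep(0, 300), 5, 4, 3, 2, 1.5, rep(0, 300))
  starts <- c(seq(0, by = 200, length.out = 300),
              60100 + c(0, 60, 120, 180, 240),
              seq(61000, by = 200, length.out = 300))
  tr <- make_track(vals, starts = starts)
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$score, 2)
})

test_that("an isolated cluster above the 90% cutoff gets cutoff_p = 90", {
  vals <- c(rep(0, 400), rep(10, 5), rep(0, 400))
  starts <- c(seq(0, by = 300, length.out = 400),
              121000 + seq(0, by = 60, length.out = 5),
              122000 + seq(0, by = 300, length.out = 400))
  tr <- make_track(vals, starts = starts)
  expect_gt(10, 0.9 * hypothetical_max(tr))
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$cutoff_p, 90L)
})

test_that("constant tracks yield no peaks", {
  tr <- make_track(rep(1.7, 50))
  expect_equal(nrow(call_peaks(tr)), 0L)
})

test_that("detections are nested across the descending cutoff schedule", {
  cfg <- small_config(seed = 3L)
  ex <- simulate_experiment(cfg)
  hm <- hypothetical_max(ex$track)
  prev <- NULL
  for (p in seq(90, 15, by = -5)) {
    det <- detect_peaks_at_cutoff(ex$track, p / 100 * hm)
    if (!is.null(prev) && nrow(prev) > 0) {
      # every peak at the higher (more stringent) p is contained in one at p' < p
      for (i in seq_len(nrow(prev))) {
        container <- which(det$replicon == prev$replicon[i] &
                             det$start <= prev$start[i] &
                             det$end >= prev$end[i])
        expect_equal(length(container), 1L)
        expect_true(all(prev$probes[[i]] %in% det$probes[[container]]))
      }
    }
    prev <- det
  }
})

test_that("randomization FDR is zero for a dominant spike-in", {
  set.seed(4)
  vals <- rnorm(400, 0, 0.1)
  vals[200:207] <- 3
  tr <- make_track(vals, starts = seq(0, by = 60, length.out = 400))
  pk <- call_peaks(tr)
  expect_gte(nrow(pk), 1L)
  pk <- estimate_fdr(tr, pk, n_rand = 20L, seed = 1L)
  spike <- which(pk$start < 207 * 60 & pk$end > 199 * 60)
  expect_length(spike, 1L)
  expect_equal(pk$fdr[spike], 0)
  expect_equal(pk$confidence[spike], "high")
  # deterministic per seed
  pk2 <- estimate_fdr(tr, call_peaks(tr), n_rand = 20L, seed = 1L)
  expect_identical(pk$fdr, pk2$fdr)
  expect_error(estimate_fdr(tr, pk, n_rand = 0L), "n_rand")
})

test_that("empty peak sets pass through FDR estimation", {
  tr <- make_track(rep(0.2, 30))
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 0L)
  expect_equal(nrow(estimate_fdr(tr, pk, n_rand = 5L, seed = 1L)), 0L)
})

test_that("confidence bands follow the 0.05/0.2 FDR thresholds", {
  expect_equal(classify_confidence(c(0, 0.03, 0.05, 0.15, 0.2, 0.5)),
               c("high", "high", "high", "candidate", "candidate", "reject"))
})

test_that("peak tables round-trip through the tab-delimited writer", {
  tr <- make_track(c(rep(0, 100), rep(4, 6), rep(0, 100)),
                   starts = c(seq(0, by = 200, length.out = 100),
                              20100 + seq(0, by = 60, length.out = 6),
                              21000 + seq(0, by = 200, length.out = 100)))
  pk <- estimate_fdr(tr, call_peaks(tr), n_rand = 5L, seed = 2L)
  d <- withr::local_tempdir()
  f <- file.path(d, "peaks.tsv")
  write_peaks(pk, f)
  back <- read_peaks(f)
  expect_equal(back$start, pk$start)
  expect_equal(back$score, pk$score, tolerance = 1e-6)
  expect_identical(back$probes, pk$probes)
})
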