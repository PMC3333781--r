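palindromic_sites <- function() {
  # each site is its own reverse complement
  c("GGCATGCC", "GACATGTC", "GCCATGGC", "GTCATGAC")
}

test_that("PWM weights follow the regularized log-odds formula", {
  sites <- c("ACGT", "ACGA", "ACGT", "ACGT")
  pwm <- build_pwm(sites, pseudocount = 1)
  n <- 4; pc <- 1; bg <- 0.25
  # unobserved base at position 1 (C): count 0
  expect_equal(unname(pwm$weights["C", 1]), log2((0 + pc * bg) / (n + pc) / bg))
  # observed base A at position 1: count 4
  expect_equal(unname(pwm$weights["A", 1]), log2((4 + pc * bg) / (n + pc) / bg))
  # consensus scores the maximum; any mismatch strictly lowers it
  cons <- pwm_consensus(pwm)
  expect_equal(score_site(pwm, cons), pwm_max_score(pwm))
  expect_lt(score_site(pwm, "ACGA"), score_site(pwm, "ACGT"))
  expect_error(build_pwm(c("ACG", "ACGT")), "equal length")
  expect_error(build_pwm(character(0)), "at least 2")
})

test_that("a palindromic site set gives a strand-symmetric PWM", {
  pwm <- build_pwm(palindromic_sites())
  rc <- pwm_reverse_complement(pwm)
  expect_equal(pwm$weights, rc$weights)
})

test_that("hit scores reproduce exactly when rescoring extracted sequences", {
  set.seed(10)
  bgseq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  pwm <- build_pwm(c("GGCATTTTGCC", "GGCAGGGTGCC", "GGCACACTGCC"))
  hits <- scan_sequence(pwm, bgseq, threshold = -1e9)
  for (i in sample(nrow(hits), 25)) {
    s <- hits$sequence[i]
    if (hits$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_equal(score_site(pwm, s), hits$score[i], tolerance = 1e-12)
  }
})

test_that("scanning matches the all-window brute-force scorer exactly", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(100:2000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    sites <- replicate(4, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                                collapse = ""))
    pwm <- build_pwm(sites)
    got <- scan_sequence(pwm, s, threshold = -1e9)
    want <- brute_force_scan(pwm, s)
    want <- want[order(want$position, want$strand), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("a planted consensus is the top hit and palindromes are strand-symmetric", {
  set.seed(3)
  bg <- sample(c("A", "C", "G", "T"), 400, TRUE)
  bg[200:210] <- strsplit("GGCATTTTGCC", "")[[1]]
  s <- paste(bg, collapse = "")
  pwm <- build_pwm(c("GGCATTTTGCC", "GGCAGTTTGCC", "GGCATTCTGCC"))
  hits <- scan_sequence(pwm, s, threshold = 0.9 * pwm_max_score(pwm))
  expect_equal(hits$position[which.max(hits$score)], 199L)

  ppwm <- build_pwm(palindromic_sites())
  all_hits <- scan_sequence(ppwm, s, threshold = -1e9)
  fwd <- all_hits[all_hits$strand == "+", ]
  rev <- all_hits[all_hits$strand == "-", ]
  expect_equal(fwd$position, rev$position)
  expect_equal(fwd$score, rev$score, tolerance = 1e-12)
})

test_that("non-ACGT windows are skipped with a message", {
  pwm <- build_pwm(c("ACGTA", "ACGTA", "ACGTC"))
  expect_message(hits <- scan_sequence(pwm, "ACGTANNNACGTACGTA",
                                       threshold = -1e9),
                 "skipped")
  expect_false(any(grepl("N", hits$sequence)))
})

test_that("upstream scanning finds exactly the planted features", {
  cfg <- small_config(seed = 21L, noise_sd = 0)
  ex <- simulate_experiment(cfg)
  pwm <- build_pwm(ex$truth$motif_sites$sequence)
  thr <- min(vapply(ex$truth$motif_sites$sequence,
                    function(s) score_site(pwm, s), numeric(1)))
  hits <- scan_upstream_regions(pwm, ex$genome, ex$upstream_index, thr)
  planted <- unique(ex$truth$motif_sites$gene_id)
  expect_true(all(planted %in% hits$feature_id))
  # lowering the threshold never removes a feature
  hits_low <- scan_upstream_regions(pwm, ex$genome, ex$upstream_index, thr - 2)
  expect_true(all(unique(hits$feature_id) %in% unique(hits_low$feature_id)))
  # absurd threshold -> empty
  none <- scan_upstream_regions(pwm, ex$genome, ex$upstream_index,
                                pwm_max_score(pwm) + 1)
  expect_equal(nrow(none), 0L)
})

test_that("motif refinement pools new sites and fixes on its own sites", {
  sites <- c("GGCATTTTGCC", "GGCAGGGTGCC", "GGCACACTGCC")
  pwm <- build_pwm(sites)
  same <- refine_motif(pwm, sites)
  expect_equal(same$weights, pwm$weights)
  expect_equal(same$nsites, pwm$nsites)

  divergent <- "GGCATACTGCC"
  ref <- build_pwm(c(sites, divergent))
  got <- refine_motif(pwm, divergent)
  expect_equal(got$width, pwm$width)
  expect_equal(got$nsites, pwm$nsites + 1L)
  # counts shift by exactly one at the divergent positions
  counts <- function(p) p$probs * (p$nsites + p$pseudocount) -
    p$pseudocount * p$background
  expect_equal(counts(got), counts(ref), tolerance = 1e-12)
  expect_error(refine_motif(pwm, "ACGT"), "width")
})

test_that("sigma54 scanning is restricted to upstream regions on the gene strand", {
  cfg <- small_config(seed = 31L, noise_sd = 0)
  ex <- simulate_experiment(cfg)
  s54 <- ex$truth$sigma54_sites
  pwm <- build_pwm(s54$sequence)
  thr <- min(vapply(s54$sequence, function(s) score_site(pwm, s), numeric(1)))
  hits <- scan_sigma54(pwm, ex$genome, ex$upstream_index, thr)
  expect_true(all(s54$gene_id %in% hits$feature_id))
  # planted positions are recovered
  for (i in seq_len(nrow(s54))) {
    expect_true(any(hits$feature_id == s54$gene_id[i] &
                      hits$position == s54$position[i]))
  }
  # every hit lies inside its feature's upstream interval
  idx <- ex$upstream_index
  for (i in seq_len(nrow(hits))) {
    iv <- idx[idx$feature_id == hits$feature_id[i], ]
    expect_true(hits$position[i] >= iv$start && hits$position[i] < iv$end)
    expect_equal(hits$strand[i], iv$strand)
  }
  none <- scan_sigma54(pwm, ex$genome, ex$upstream_index,
                       pwm_max_score(pwm) + 1)
  expect_equal(nrow(none), 0L)
})

test_that("PWMs round-trip through the MEME minimal text format", {
  pwm <- build_pwm(c("GGCATTTTGCC", "GGCAGGGTGCC", "GGCACACTGCC"))
  d <- withr::local_tempdir()
  f <- file.path(d, "motif.meme")
  write_meme(pwm, f, name = "rr_site")
  back <- read_meme(f)
  expect_named(back, "rr_site")
  expect_equal(back$rr_site$width, pwm$width)
  expect_equal(back$rr_site$nsites, pwm$nsites)
  expect_equal(back$rr_site$weights, pwm$weights, tolerance = 1e-4)
})
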