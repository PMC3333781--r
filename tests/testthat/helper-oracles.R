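# Independent brute-force oracles and tiny fixture builders. The oracles are
# written as plain enumeration loops, deliberately sharing no code with the
# package implementations they check.

# Enumerate every min_probes-window explicitly and mark qualifying probes;
# peaks are maximal runs of marked probes.
brute_force_peaks <- function(track, cutoff, window = 500L, min_probes = 5L) {
  out <- list()
  for (rp in unique(track$replicon)) {
    tr <- track[track$replicon == rp, ]
    tr <- tr[order(tr$start), ]
    n <- nrow(tr)
    marked <- rep(FALSE, n)
    if (n >= min_probes) {
      for (i in seq_len(n - min_probes + 1L)) {
        idx <- i:(i + min_probes - 1L)
        if (all(tr$log2r[idx] >= cutoff)) {
          span <- tr$start[idx[min_probes]] + tr$length[idx[min_probes]] -
            tr$start[idx[1L]]
          if (span <= window) marked[idx] <- TRUE
        }
      }
    }
    i <- 1L
    while (i <= n) {
      if (marked[i]) {
        j <- i
        while (j < n && marked[j + 1L]) j <- j + 1L
        out[[length(out) + 1L]] <- list(
          replicon = rp, start = tr$start[i],
          end = tr$start[j] + tr$length[j],
          probes = tr$probe_id[i:j])
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  out
}

# Score every window on both strands by direct per-base lookup.
brute_force_scan <- function(pwm, s) {
  s <- toupper(s)
  w <- pwm$width
  n <- nchar(s) - w + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_one <- function(window) {
    bases <- strsplit(window, "")[[1L]]
    if (!all(bases %in% c("A", "C", "G", "T"))) return(NA_real_)
    tot <- 0
    for (j in seq_len(w)) tot <- tot + pwm$weights[bases[j], j]
    tot
  }
  rows <- list()
  for (p in seq_len(n)) {
    window <- substr(s, p, p + w - 1L)
    fwd <- score_one(window)
    bases <- rev(strsplit(window, "")[[1L]])
    rc <- paste(ifelse(bases %in% names(comp), comp[bases], "N"), collapse = "")
    rev_sc <- score_one(rc)
    if (!is.na(fwd)) {
      rows[[length(rows) + 1L]] <- data.frame(position = p - 1L, strand = "+",
                                              score = fwd)
    }
    if (!is.na(rev_sc)) {
      rows[[length(rows) + 1L]] <- data.frame(position = p - 1L, strand = "-",
                                              score = rev_sc)
    }
  }
  do.call(rbind, rows)
}

# A bare ratio track with given values; probes 50 bp at the given starts.
make_track <- function(log2r, starts = NULL, replicon = "chr", length = 50L) {
  n <- length(log2r)
  if (is.null(starts)) starts <- seq(0L, by = 100L, length.out = n)
  out <- data.frame(probe_id = sprintf("P%06d", seq_len(n)),
                    replicon = replicon, start = as.integer(starts),
                    length = as.integer(length), log2r = as.numeric(log2r),
                    stringsAsFactors = FALSE)
  class(out) <- c("ProbeRatioTrack", "data.frame")
  out
}

# Random tracks with mixed probe steps for the oracle-equivalence checks.
random_track <- function(n, seed) {
  set.seed(seed)
  steps <- sample(c(4L, 30L, 120L), n - 1L, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1))
  make_track(rnorm(n), starts = cumsum(c(0L, steps)))
}

# Tiny hand-built annotation used across target-mapping tests:
#   geneA + [1000,2000), geneB - [3000,4000), geneC + [4600,5600)
# geneB/geneC share a divergent gap [4000,4600).
tiny_annotation <- function() {
  GenomeAnnotation(
    c(chr = 10000L),
    data.frame(gene_id = c("geneA", "geneB", "geneC"),
               replicon = "chr",
               start = c(1000L, 3000L, 4600L),
               end = c(2000L, 4000L, 5600L),
               strand = c("+", "-", "+"),
               operon = c("opA", "opB", "opC"),
               stringsAsFactors = FALSE))
}

# One-row Peaks object for mapping tests.
tiny_peak <- function(start, end, score = 2, fdr = 0.01, replicon = "chr") {
  out <- data.frame(replicon = replicon, start = as.integer(start),
                    end = as.integer(end), n_probes = 5L, score = score,
                    cutoff_p = 50L, fdr = fdr,
                    confidence = ifelse(fdr <= 0.05, "high",
                                        ifelse(fdr <= 0.2, "candidate",
                                               "reject")),
                    stringsAsFactors = FALSE)
  out$probes <- list(sprintf("P%06d", 1:5))
  class(out) <- c("Peaks", "data.frame")
  out
}

# Small, fast pipeline configuration for non-acceptance tests.
small_config <- function(seed = 1L, noise_sd = 0.3, n_rand = 5L) {
  pipeline_config(
    sim = sim_params(genome_length = 40000L, n_operons = 15L,
                     n_bound_regions = 4L, noise_sd = noise_sd, seed = seed),
    n_rand = n_rand, n_sigma54 = 2L)
}
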