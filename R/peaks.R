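#' Compute scaled log2 ratios from two-channel intensities
#'
#' Computes `log2(enriched/input)` per probe and scales the track by
#' median-centering, so that a multiplicative offset between the channels
#' cancels out.
#'
#' @param raw data.frame with columns `probe_id`, `replicon`, `start`,
#'   `length`, `enriched`, `input` (both channels strictly positive).
#' @return `ProbeRatioTrack` sorted by (replicon, start).
#' @export
compute_log2_ratios <- function(raw) {
  required <- c("probe_id", "replicon", "start", "length", "enriched", "input")
  if (!all(required %in% names(raw))) {
    stop("raw intensities must have columns: ", paste(required, collapse = ", "))
  }
  bad <- which(!(raw$enriched > 0) | !(raw$input > 0))
  if (length(bad)) {
    stop("nonpositive intensity for probe(s): ",
         paste(head(raw$probe_id[bad], 5L), collapse = ", "))
  }
  log2r <- log2(raw$enriched / raw$input)
  log2r <- log2r - median(log2r)
  out <- data.frame(probe_id = raw$probe_id, replicon = raw$replicon,
                    start = raw$start, length = raw$length, log2r = log2r,
                    stringsAsFactors = FALSE)
  out <- out[order(out$replicon, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ProbeRatioTrack", "data.frame")
  out
}

#' Hypothetical maximum log2 ratio of a track
#'
#' The anchor of the peak-calling cutoff schedule: the track mean plus six
#' sample standard deviations of the log2 ratios.
#'
#' @param track `ProbeRatioTrack` (or numeric vector of log2 ratios).
#' @return single numeric value.
#' @export
hypothetical_max <- function(track) {
  x <- if (is.data.frame(track)) track$log2r else track
  if (length(x) < 2L) stop("hypothetical_max needs at least 2 probes")
  mean(x) + 6 * sd(x)
}

empty_peaks <- function() {
  out <- data.frame(replicon = character(0), start = integer(0),
                    end = integer(0), n_probes = integer(0),
                    score = numeric(0), cutoff_p = integer(0),
                    fdr = numeric(0), confidence = character(0),
                    stringsAsFactors = FALSE)
  out$probes <- list()
  class(out) <- c("Peaks", "data.frame")
  out
}

#' Detect peak intervals at a single cutoff value
#'
#' A probe qualifies when its log2 ratio is at least `cutoff_value`. Within a
#' replicon, every run of `min_probes` consecutive qualifying probes whose
#' genomic span (last probe end minus first probe start) is at most `window`
#' bp marks its probes as in-peak; maximal runs of in-peak probes become peak
#' intervals (overlapping windows merge).
#'
#' @param track `ProbeRatioTrack`, sorted by (replicon, start).
#' @param cutoff_value log2-ratio threshold.
#' @param window sliding-window width in bp.
#' @param min_probes probes required above the cutoff (default 5: "more than
#'   four").
#' @return data.frame (`replicon`, `start`, `end`, `n_probes`, list column
#'   `probes` of member probe ids); zero rows when nothing is detected.
#' @export
detect_peaks_at_cutoff <- function(track, cutoff_value, window = 500L,
                                   min_probes = 5L) {
  peaks <- list(); k <- 0L
  for (rp in unique(track$replicon)) {
    tr <- track[track$replicon == rp, , drop = FALSE]
    n <- nrow(tr)
    if (n < min_probes) next
    q <- tr$log2r >= cutoff_value
    cq <- c(0L, cumsum(q))
    idx <- seq_len(n - min_probes + 1L)
    all_q <- (cq[idx + min_probes] - cq[idx]) == min_probes
    span <- tr$start[idx + min_probes - 1L] + tr$length[idx + min_probes - 1L] -
      tr$start[idx]
    marked <- which(all_q & span <= window)
    if (!length(marked)) next
    delta <- integer(n + 1L)
    delta[marked] <- delta[marked] + 1L
    delta[marked + min_probes] <- delta[marked + min_probes] - 1L
    in_peak <- cumsum(delta[seq_len(n)]) > 0L
    r <- rle(in_peak)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      k <- k + 1L
      m <- starts[j]:ends[j]
      peaks[[k]] <- data.frame(
        replicon = rp,
        start = tr$start[m[1L]],
        end = tr$start[m[length(m)]] + tr$length[m[length(m)]],
        n_probes = length(m), stringsAsFactors = FALSE)
      peaks[[k]]$probes <- list(tr$probe_id[m])
    }
  }
  if (!length(peaks)) {
    out <- empty_peaks()
    return(out[, c("replicon", "start", "end", "n_probes", "probes")])
  }
  out <- do.call(rbind, peaks)
  out[order(out$replicon, out$start), , drop = FALSE]
}

#' Call peaks over the descending cutoff schedule
#'
#' Runs [detect_peaks_at_cutoff()] at every cutoff percentage of the
#' schedule (by default 90 down to 15 in steps of 1, as fractions of the
#' [hypothetical_max()]). The final peak set is the detection at the most
#' permissive percentage; each final peak's `cutoff_p` records the most
#' stringent percentage at which a detection overlapping it exists, and its
#' `score` is the log2 ratio of the peak's fourth-highest member probe.
#'
#' Tracks with no dispersion (zero variance) have a non-positive cutoff
#' anchor and yield no peaks.
#'
#' @param track `ProbeRatioTrack`.
#' @param window sliding-window width in bp.
#' @param min_probes probes required above the cutoff.
#' @param schedule integer cutoff percentages, descending.
#' @return `Peaks` data.frame: `replicon`, `start`, `end`, `n_probes`,
#'   `score`, `cutoff_p`, `fdr` (`NA` until [estimate_fdr()]), `confidence`,
#'   list column `probes`.
#' @export
call_peaks <- function(track, window = 500L, min_probes = 5L,
                       schedule = 90:15) {
  stopifnot(nrow(track) >= 2L, !is.unsorted(order(track$replicon, track$start)))
  schedule <- sort(unique(as.integer(schedule)), decreasing = TRUE)
  hm <- hypothetical_max(track)
  # zero dispersion means no enrichment signal (and, once centered, a
  # non-positive cutoff anchor): nothing can stand out, so no peaks
  if (sd(track$log2r) == 0 || hm <= 0) return(empty_peaks())
  p_min <- schedule[length(schedule)]
  final <- detect_peaks_at_cutoff(track, p_min / 100 * hm, window, min_probes)
  if (nrow(final) == 0L) return(empty_peaks())
  final$cutoff_p <- rep(p_min, nrow(final))
  for (p in schedule[-length(schedule)]) {
    det <- detect_peaks_at_cutoff(track, p / 100 * hm, window, min_probes)
    if (nrow(det) == 0L) next
    for (i in seq_len(nrow(det))) {
      hit <- which(final$replicon == det$replicon[i] &
                     final$start < det$end[i] & det$start[i] < final$end)
      if (length(hit)) final$cutoff_p[hit] <- pmax(final$cutoff_p[hit], p)
    }
  }
  lut <- setNames(track$log2r, track$probe_id)
  final$score <- vapply(final$probes, function(ids) {
    sort(lut[ids], decreasing = TRUE)[[4L]]
  }, numeric(1))
  final$fdr <- NA_real_
  final$confidence <- NA_character_
  final <- final[, c("replicon", "start", "end", "n_probes", "score",
                     "cutoff_p", "fdr", "confidence", "probes")]
  rownames(final) <- NULL
  class(final) <- c("Peaks", "data.frame")
  final
}

#' Estimate per-peak FDR by track randomization
#'
#' The log2 ratios are permuted uniformly over probe positions (within each
#' replicon, preserving coordinates) `n_rand` times; peaks are re-called on
#' each permuted track. For an observed peak of score `s`, each
#' randomization contributes the ratio of random peaks scoring at least `s`
#' to observed peaks scoring at least `s`; the FDR is the mean over
#' randomizations, clipped to `[0, 1]`.
#'
#' @param track the `ProbeRatioTrack` the peaks were called from.
#' @param peaks `Peaks` from [call_peaks()].
#' @param n_rand number of randomizations (default 20).
#' @param seed integer seed; fixes the permutations.
#' @param window,min_probes,schedule forwarded to [call_peaks()].
#' @return `peaks` with `fdr` and `confidence` filled in.
#' @export
estimate_fdr <- function(track, peaks, n_rand = 20L, seed = 1L,
                         window = 500L, min_probes = 5L, schedule = 90:15) {
  if (n_rand < 1L) stop("'n_rand' must be >= 1")
  if (nrow(peaks) == 0L) return(peaks)
  rand_scores <- with_seed(seed, {
    lapply(seq_len(n_rand), function(r) {
      perm <- track
      for (rp in unique(perm$replicon)) {
        sel <- perm$replicon == rp
        perm$log2r[sel] <- sample(perm$log2r[sel])
      }
      call_peaks(perm, window, min_probes, schedule)$score
    })
  })
  obs <- peaks$score
  peaks$fdr <- vapply(obs, function(s) {
    n_obs <- sum(obs >= s)
    ratios <- vapply(rand_scores, function(rs) sum(rs >= s) / n_obs, numeric(1))
    min(max(mean(ratios), 0), 1)
  }, numeric(1))
  peaks$confidence <- classify_confidence(peaks$fdr)
  peaks
}

#' Classify peak confidence from FDR
#'
#' FDR at most 0.05 is a high-confidence binding site; up to 0.2 is still a
#' candidate binding site; above that the peak is rejected.
#'
#' @param fdr numeric vector of per-peak FDR values (or a `Peaks` object).
#' @return character vector: `"high"`, `"candidate"` or `"reject"`.
#' @export
classify_confidence <- function(fdr) {
  if (is.data.frame(fdr)) fdr <- fdr$fdr
  ifelse(fdr <= 0.05, "high", ifelse(fdr <= 0.2, "candidate", "reject"))
}

## ---- I/O ------------------------------------------------------------------

#' Write peaks as a tab-delimited table
#' @param peaks `Peaks`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  flat <- as.data.frame(peaks[, setdiff(names(peaks), "probes")])
  flat$probes <- vapply(peaks$probes, paste, character(1), collapse = ",")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#' @param path tab-delimited peaks file.
#' @return `Peaks`.
#' @export
read_peaks <- function(path) {
  flat <- read.delim(path, stringsAsFactors = FALSE)
  flat$probes <- strsplit(flat$probes, ",", fixed = TRUE)
  class(flat) <- c("Peaks", "data.frame")
  flat
}

#' Write peaks as BED (score = 100 x peak score, capped at 1000)
#' @param peaks `Peaks`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$replicon,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    name = sprintf("peak%03d", seq_len(nrow(peaks))),
    score = pmin(pmax(round(peaks$score * 100), 0), 1000))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
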