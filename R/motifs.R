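DNA_BASES <- c("A", "C", "G", "T")

#' Build a log-odds position weight matrix from aligned binding sites
#'
#' Per position and base, the weight is
#' `log2((count + pseudocount * bg) / (n + pseudocount) / bg)`: observed
#' counts regularized by a total pseudocount mass distributed according to
#' the background (with the default uniform background and pseudocount 1,
#' 0.25 per base), converted to log2 odds against the background.
#'
#' @param sites character vector (or `DNAStringSet`) of >= 2 equal-length
#'   A/C/G/T sequences.
#' @param pseudocount total pseudocount mass added per column.
#' @param background named base frequencies (A, C, G, T); uniform by default.
#' @return object of class `PWM`: `width`, `weights` (4 x width log2-odds
#'   matrix), `probs` (regularized letter probabilities), `background`,
#'   `pseudocount`, `nsites`, and the source `sites`.
#' @export
build_pwm <- function(sites, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sites <- toupper(as.character(sites))
  if (length(sites) < 2L) stop("need at least 2 aligned sites")
  w <- unique(nchar(sites))
  if (length(w) != 1L || w == 0L) stop("sites must be non-empty and equal length")
  chars <- do.call(rbind, strsplit(sites, ""))
  if (!all(chars %in% DNA_BASES)) stop("sites must contain only A/C/G/T")
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4L)
  }, numeric(4))
  rownames(counts) <- DNA_BASES
  n <- length(sites)
  probs <- (counts + pseudocount * background) / (n + pseudocount)
  weights <- log2(probs / background)
  structure(list(width = w, weights = weights, probs = probs,
                 background = background, pseudocount = pseudocount,
                 nsites = n, sites = sites),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM: width %d, %d sites, consensus %s\n",
              x$width, x$nsites, pwm_consensus(x)))
  invisible(x)
}

#' Column-wise argmax consensus of a PWM
#' @param pwm `PWM`.
#' @return consensus string (maximum-scoring sequence).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 2L, which.max)], collapse = "")
}

#' Maximum attainable PWM score
#' @param pwm `PWM`.
#' @return sum of column maxima of the log2-odds weights.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$weights, 2L, max))

#' Reverse complement of a PWM
#' @param pwm `PWM`.
#' @return `PWM` scoring the opposite strand (columns reversed, bases
#'   complemented).
#' @export
pwm_reverse_complement <- function(pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- function(m) {
    m2 <- m[comp[DNA_BASES], rev(seq_len(ncol(m))), drop = FALSE]
    rownames(m2) <- DNA_BASES
    m2
  }
  out <- pwm
  out$weights <- flip(pwm$weights)
  out$probs <- flip(pwm$probs)
  out$sites <- vapply(pwm$sites, revcomp_chr, character(1), USE.NAMES = FALSE)
  out
}

#' Score one sequence against a PWM
#' @param pwm `PWM`.
#' @param seq character sequence of length `pwm$width`.
#' @return numeric log2-odds score.
#' @export
score_site <- function(pwm, seq) {
  codes <- match(strsplit(toupper(as.character(seq)), "")[[1L]], DNA_BASES)
  if (length(codes) != pwm$width || anyNA(codes)) {
    stop("sequence must be A/C/G/T of PWM width")
  }
  sum(pwm$weights[cbind(codes, seq_len(pwm$width))])
}

#' Sample one site from a PWM's letter probabilities
#' @param pwm `PWM`.
#' @return character sequence of length `pwm$width`.
#' @export
sample_pwm_site <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(j) {
    sample(DNA_BASES, 1L, prob = pwm$probs[, j])
  }, character(1)), collapse = "")
}

# score every window start on the forward reading of `codes` with `weights`;
# windows containing non-ACGT positions score NA
slide_scores <- function(weights, codes) {
  w <- ncol(weights)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    col <- weights[, j][codes[seq_len(n) + j - 1L]]
    sc <- sc + col  # NA codes propagate
  }
  sc
}

#' Scan a sequence for PWM hits
#'
#' Reports every position/strand whose window scores at least `threshold`.
#' Reverse-strand windows are scored on their reverse complement and
#' reported in forward coordinates (the hit's `position` is the 0-based
#' start of the forward-strand window). Windows containing non-ACGT
#' characters are skipped and counted in a message.
#'
#' @param pwm `PWM`.
#' @param sequence character, `DNAString`, or single-element `DNAStringSet`.
#' @param threshold minimum log2-odds score; see [pwm_max_score()] for the
#'   usual fraction-of-maximum anchoring.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param seq_id identifier recorded on the hits.
#' @return data.frame of class `MotifHits`: `seq_id`, `position` (0-based),
#'   `strand`, `score`, `sequence` (forward-strand window).
#' @export
scan_sequence <- function(pwm, sequence, threshold, both_strands = TRUE,
                          seq_id = "seq") {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("scan one sequence at a time")
  chars <- strsplit(s, "")[[1L]]
  if (length(chars) < pwm$width) stop("sequence shorter than PWM width")
  codes <- match(chars, DNA_BASES)
  fwd <- slide_scores(pwm$weights, codes)
  strands <- list("+" = fwd)
  if (both_strands) {
    strands[["-"]] <- slide_scores(pwm_reverse_complement(pwm)$weights, codes)
  }
  n_skipped <- sum(is.na(fwd))
  if (n_skipped > 0L) {
    message(sprintf("scan_sequence: skipped %d window(s) with non-ACGT bases in %s",
                    n_skipped, seq_id))
  }
  rows <- lapply(names(strands), function(st) {
    sc <- strands[[st]]
    # prefilter with slack for accumulation error, then rescore candidates
    # exactly so reported scores reproduce bit-for-bit on re-scoring
    hit <- which(!is.na(sc) & sc >= threshold - 1e-6)
    seqs <- if (length(hit)) substring(s, hit, hit + pwm$width - 1L)
            else character(0)
    exact <- vapply(seqs, function(win) {
      if (st == "-") win <- revcomp_chr(win)
      score_site(pwm, win)
    }, numeric(1), USE.NAMES = FALSE)
    keep <- exact >= threshold
    data.frame(seq_id = rep(seq_id, sum(keep)), position = hit[keep] - 1L,
               strand = rep(st, sum(keep)), score = exact[keep],
               sequence = seqs[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MotifHits", "data.frame")
  out
}

#' Scan the upstream regions of all features for PWM hits
#'
#' Extracts each interval of the upstream index from the genome, scans it,
#' and reports hits in genome coordinates tagged with the owning feature.
#' Features are ordered by their best hit score.
#'
#' @param pwm `PWM`.
#' @param genome `DNAStringSet`.
#' @param upstream_index from [build_upstream_index()].
#' @param threshold minimum log2-odds score.
#' @param both_strands scan both strands (default TRUE).
#' @return `MotifHits` data.frame with `feature_id`, `replicon`, `position`
#'   (genome 0-based), `strand`, `score`, `sequence`, ordered by descending
#'   per-feature best score.
#' @export
scan_upstream_regions <- function(pwm, genome, upstream_index, threshold,
                                  both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(upstream_index)), function(i) {
    iv <- upstream_index[i, ]
    if (iv$end - iv$start < pwm$width) return(NULL)
    subseq <- substr(as.character(genome[[iv$replicon]]), iv$start + 1L, iv$end)
    hits <- scan_sequence(pwm, subseq, threshold, both_strands,
                          seq_id = iv$feature_id)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(feature_id = hits$seq_id, replicon = iv$replicon,
               position = iv$start + hits$position, strand = hits$strand,
               score = hits$score, sequence = hits$sequence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), replicon = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  } else {
    best <- tapply(out$score, out$feature_id, max)
    out <- out[order(-best[out$feature_id], out$feature_id, -out$score), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("MotifHits", "data.frame")
  out
}

#' Refine a motif with sites recovered from DAP-chip targets
#'
#' Rebuilds the PWM from the pooled site set: the original aligned sites
#' plus every recovered site not already present (typically the best-scoring
#' window in each DAP-chip target's upstream region). Recovered sites that
#' duplicate original sites add no information and are dropped, so refining
#' with the original sites is a fixed point.
#'
#' @param pwm the initial `PWM`.
#' @param target_sites character vector of recovered sites (PWM width).
#' @return refined `PWM` of the same width.
#' @export
refine_motif <- function(pwm, target_sites) {
  target_sites <- toupper(as.character(target_sites))
  if (any(nchar(target_sites) != pwm$width)) {
    stop("recovered sites must match the PWM width")
  }
  new_sites <- setdiff(target_sites, pwm$sites)
  build_pwm(c(pwm$sites, new_sites), pseudocount = pwm$pseudocount,
            background = pwm$background)
}

#' Synthetic sigma54 (rpoN) promoter weight matrix
#'
#' A stand-in promoter matrix built from the published -24/-12 sigma54
#' consensus element (`TGGCACG-N4-TTGCA`/`T`) treated as one contiguous
#' motif with its fixed 4-bp spacer. It is constructed from a small
#' synthetic alignment of consensus variants, not from any downloaded
#' promoter collection, and is intended for simulations and method tests.
#'
#' @param pseudocount forwarded to [build_pwm()].
#' @return `PWM` of width 16.
#' @export
sigma54_default_pwm <- function(pseudocount = 1) {
  sites <- c("TGGCACGACTGTTGCA", "TGGCACGGATATTGCT", "TGGCACGCTAGTTGCA",
             "TGGCACGTGCATTGCT", "TGGCATGAGGCTTGCA", "TGGCACAGTTATTGCT",
             "CGGCACGATCGTTGCA", "TGGCACGCCGATTGCT")
  build_pwm(sites, pseudocount = pseudocount)
}

#' IUPAC consensus of the synthetic sigma54 promoter element
#' @return consensus string accepted by [plant_sigma54_promoters()].
#' @export
sigma54_consensus <- function() "TGGCACGNNNNTTGCW"

#' Scan upstream regions for sigma54 promoters
#'
#' Identical mechanics to [scan_upstream_regions()] with a promoter matrix;
#' promoters are orientation-specific, so only the strand matching each
#' feature's own strand is reported. Output rows are tagged as sigma54
#' predictions.
#'
#' @param rpoN_pwm promoter `PWM` (e.g. [sigma54_default_pwm()] or one read
#'   with [read_meme()]).
#' @param genome `DNAStringSet`.
#' @param upstream_index from [build_upstream_index()].
#' @param threshold minimum log2-odds score.
#' @return `MotifHits` data.frame with a `type = "sigma54"` column.
#' @export
scan_sigma54 <- function(rpoN_pwm, genome, upstream_index, threshold) {
  hits <- scan_upstream_regions(rpoN_pwm, genome, upstream_index, threshold,
                                both_strands = TRUE)
  strand_of <- setNames(upstream_index$strand, upstream_index$feature_id)
  hits <- hits[hits$strand == strand_of[hits$feature_id], , drop = FALSE]
  hits$type <- rep("sigma54", nrow(hits))
  rownames(hits) <- NULL
  class(hits) <- c("MotifHits", "data.frame")
  hits
}

## ---- MEME minimal motif text format ---------------------------------------

#' Write a PWM in MEME minimal motif text format
#'
#' @param pwm `PWM` (or named list of PWMs for a multi-motif file).
#' @param path output file.
#' @param name motif name for a single PWM.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif1") {
  pwms <- if (inherits(pwm, "PWM")) setNames(list(pwm), name) else pwm
  bg <- pwms[[1L]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), ""),
             con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         p$width, p$nsites)), con)
    writeLines(apply(p$probs, 2L, function(col) {
      paste(sprintf("%.6f", col), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif text file
#'
#' Letter probabilities are converted back to log2-odds weights against the
#' file's background frequencies. The site-level information of
#' [build_pwm()] is not recoverable from this format, so `sites` is empty.
#'
#' @param path MEME minimal format file.
#' @return named list of `PWM` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(toks[seq(2L, length(toks), by = 2L)])
    names(vals) <- toks[seq(1L, length(toks), by = 2L)]
    bg <- vals[DNA_BASES]
  }
  motif_at <- grep("^MOTIF\\s", lines)
  out <- list()
  for (m in motif_at) {
    nm <- strsplit(trimws(lines[m]), "\\s+")[[1L]][2L]
    hdr <- m + grep("letter-probability matrix", lines[(m + 1L):length(lines)])[1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    ns <- if (grepl("nsites=", lines[hdr])) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr]))
    } else NA_integer_
    rows <- lines[(hdr + 1L):(hdr + w)]
    probs <- t(vapply(rows, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }, numeric(4), USE.NAMES = FALSE))
    probs <- t(probs)  # 4 x w
    rownames(probs) <- DNA_BASES
    out[[nm]] <- structure(
      list(width = w, weights = log2(probs / bg), probs = probs,
           background = bg, pseudocount = NA_real_, nsites = ns,
           sites = character(0)),
      class = "PWM")
  }
  out
}

#' Write motif hits as a tab-delimited table
#' @param hits `MotifHits`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED
#' @param hits `MotifHits` with `replicon`/`position` columns.
#' @param pwm the `PWM` that produced the hits (for the interval width).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_motif_hits_bed <- function(hits, pwm, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$replicon,
    ranges = IRanges::IRanges(start = hits$position + 1L, width = pwm$width),
    strand = hits$strand,
    name = if ("feature_id" %in% names(hits)) hits$feature_id else hits$seq_id,
    score = pmin(pmax(round(hits$score * 10), 0), 1000))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
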