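peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$replicon,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Map peaks to gene and operon targets
#'
#' A peak overlapping one or more upstream intervals yields one
#' `upstream` call per overlapped feature (a peak between divergently
#' transcribed operons therefore calls both). A peak lying wholly within a
#' gene's coding span yields a `coding` call for that gene. Remaining peaks
#' are reported as `intergenic-unassigned`.
#'
#' @param peaks `Peaks` from [call_peaks()]/[estimate_fdr()].
#' @param index `UpstreamIndex` from [build_upstream_index()].
#' @param ann `GenomeAnnotation`.
#' @return data.frame of class `TargetCalls`: `peak_id`, `replicon`,
#'   `peak_start`, `peak_end`, `score`, `cutoff_p`, `fdr`, `confidence`,
#'   `feature_id`, `operon`, `genes`, `relation`.
#' @export
map_peaks_to_targets <- function(peaks, index, ann) {
  unknown <- setdiff(unique(peaks$replicon), names(ann$replicons))
  if (length(unknown)) {
    stop("peak replicon(s) not in annotation: ", paste(unknown, collapse = ", "))
  }
  base_cols <- function(i, peak_id) {
    data.frame(peak_id = peak_id, replicon = peaks$replicon[i],
               peak_start = peaks$start[i], peak_end = peaks$end[i],
               score = peaks$score[i], cutoff_p = peaks$cutoff_p[i],
               fdr = peaks$fdr[i], confidence = peaks$confidence[i],
               stringsAsFactors = FALSE)
  }
  g <- ann$genes
  leaders <- operon_leaders(ann)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(peaks))) {
    pid <- sprintf("peak%03d", i)
    ups <- which(index$replicon == peaks$replicon[i] &
                   index$start < peaks$end[i] & peaks$start[i] < index$end &
                   index$end > index$start)
    if (length(ups)) {
      for (u in ups) {
        k <- k + 1L
        rows[[k]] <- cbind(base_cols(i, pid),
                           data.frame(feature_id = index$feature_id[u],
                                      operon = index$operon[u],
                                      genes = index$genes[u],
                                      relation = "upstream",
                                      stringsAsFactors = FALSE))
      }
      next
    }
    inside <- which(g$replicon == peaks$replicon[i] &
                      g$start <= peaks$start[i] & peaks$end[i] <= g$end)
    if (length(inside) == 1L) {
      gene <- g$gene_id[inside]
      op <- leaders[leaders$feature_id == gene |
                      grepl(paste0("\\b", gene, "\\b"), leaders$genes), ]
      k <- k + 1L
      rows[[k]] <- cbind(base_cols(i, pid),
                         data.frame(feature_id = gene,
                                    operon = if (nrow(op)) op$operon[1L] else NA,
                                    genes = gene, relation = "coding",
                                    stringsAsFactors = FALSE))
      next
    }
    k <- k + 1L
    rows[[k]] <- cbind(base_cols(i, pid),
                       data.frame(feature_id = NA_character_,
                                  operon = NA_character_,
                                  genes = NA_character_,
                                  relation = "intergenic-unassigned",
                                  stringsAsFactors = FALSE))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_id = character(0), replicon = character(0),
               peak_start = integer(0), peak_end = integer(0),
               score = numeric(0), cutoff_p = integer(0), fdr = numeric(0),
               confidence = character(0), feature_id = character(0),
               operon = character(0), genes = character(0),
               relation = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("TargetCalls", "data.frame")
  out
}

#' Pool replicate DAP-chip experiments by common hits
#'
#' Keeps the targets whose feature id is called in every replicate (strict
#' intersection keyed by feature, not by peak coordinates, since replicate
#' peak boundaries jitter). Returns the first replicate's calls restricted
#' to the common features; a single replicate passes through unchanged.
#'
#' @param peak_call_lists list of `TargetCalls` (one per replicate).
#' @return `TargetCalls` for the pooled target set.
#' @export
pool_replicates <- function(peak_call_lists) {
  if (!length(peak_call_lists)) stop("need at least one replicate")
  if (length(peak_call_lists) == 1L) return(peak_call_lists[[1L]])
  ids <- lapply(peak_call_lists, function(x) unique(stats::na.omit(x$feature_id)))
  common <- Reduce(intersect, ids)
  out <- peak_call_lists[[1L]]
  out <- out[!is.na(out$feature_id) & out$feature_id %in% common, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count how many datasets share each peak interval
#'
#' For each peak of the focal dataset, counts the RR datasets (the focal one
#' included) with at least one overlapping peak — the "appears in multiple
#' DAP-chip sets" signal used to drop promiscuous (sticky-DNA) intervals.
#'
#' @param peaks focal `Peaks`.
#' @param other_peak_sets list of `Peaks` from other RR datasets.
#' @return integer vector, one count per focal peak.
#' @export
count_dataset_overlaps <- function(peaks, other_peak_sets = list()) {
  n <- rep(1L, nrow(peaks))
  for (other in other_peak_sets) {
    if (nrow(other) == 0L) next
    hit <- vapply(seq_len(nrow(peaks)), function(i) {
      any(other$replicon == peaks$replicon[i] &
            other$start < peaks$end[i] & peaks$start[i] < other$end)
    }, logical(1))
    n <- n + as.integer(hit)
  }
  n
}

#' Apply the mechanical curation rules to target calls
#'
#' A call is retained when it is an upstream call of high confidence
#' (FDR at most `fdr_max`) that is not promiscuous across datasets — or,
#' regardless of those rules, when a binding-site motif hit lies inside the
#' peak ("motif rescue"). Every dropped call carries a machine-readable
#' reason.
#'
#' @param calls `TargetCalls`.
#' @param motif_hits `MotifHits` in genome coordinates (or NULL).
#' @param n_datasets integer vector from [count_dataset_overlaps()], one per
#'   call (recycled scalar allowed); defaults to 1 (unique to this dataset).
#' @param fdr_max FDR bound for the confidence rule.
#' @param promiscuity_limit maximum datasets an interval may appear in
#'   before it is dropped as sticky DNA (default 2: three or more is
#'   "multiple DAP-chip sets").
#' @return `TargetCalls` with `motif_support`, `n_datasets`, `retained`,
#'   `reason` columns.
#' @export
curate_targets <- function(calls, motif_hits = NULL, n_datasets = 1L,
                           fdr_max = 0.05, promiscuity_limit = 2L) {
  n <- nrow(calls)
  n_datasets <- as.integer(rep(n_datasets, length.out = n))
  motif_support <- rep(FALSE, n)
  if (!is.null(motif_hits) && nrow(motif_hits) > 0L) {
    for (i in seq_len(n)) {
      motif_support[i] <- any(
        motif_hits$replicon == calls$replicon[i] &
          motif_hits$position >= calls$peak_start[i] &
          motif_hits$position < calls$peak_end[i])
    }
  }
  mech_ok <- calls$relation == "upstream" & !is.na(calls$fdr) &
    calls$fdr <= fdr_max & n_datasets <= promiscuity_limit
  retained <- mech_ok | motif_support
  reason <- character(n)
  for (i in seq_len(n)) {
    reason[i] <- if (mech_ok[i]) {
      "passes all rules"
    } else if (motif_support[i]) {
      "motif rescue"
    } else if (calls$relation[i] == "coding") {
      "coding region"
    } else if (calls$relation[i] != "upstream") {
      "unassigned location"
    } else if (n_datasets[i] > promiscuity_limit) {
      "promiscuous (multiple DAP-chip sets)"
    } else {
      "low confidence (score/FDR)"
    }
  }
  calls$motif_support <- motif_support
  calls$n_datasets <- n_datasets
  calls$retained <- retained
  calls$reason <- reason
  calls
}

#' Top peaks report for one DAP-chip dataset
#' @param peaks `Peaks`.
#' @param n number of peaks to report (default 20).
#' @return `Peaks` rows sorted by descending score, at most `n` of them.
#' @export
top_peaks_report <- function(peaks, n = 20L) {
  out <- peaks[order(-peaks$score), , drop = FALSE]
  out <- head(out, n)
  rownames(out) <- NULL
  out
}

#' Write target calls as a tab-delimited table
#' @param calls `TargetCalls` (curated or not).
#' @param path output file.
#' @param rr_id RR dataset identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_targets <- function(calls, path, rr_id = "RR") {
  out <- cbind(rr_id = rep(rr_id, nrow(calls)), as.data.frame(calls))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
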