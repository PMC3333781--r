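#' qPCR measurement of one target
#'
#' Holds replicate threshold-cycle (Ct) values of the input and enriched
#' DNA fractions for a single locus.
#'
#' @param target locus identifier.
#' @param input_ct numeric Ct replicates of the input fraction (cycles).
#' @param enriched_ct numeric Ct replicates of the enriched fraction.
#' @param negative_control TRUE for a non-specific control locus.
#' @return object of class `QpcrMeasurement`.
#' @export
qpcr_measurement <- function(target, input_ct, enriched_ct,
                             negative_control = FALSE) {
  if (length(input_ct) < 1L || length(enriched_ct) < 1L) {
    stop("need at least one Ct replicate per fraction")
  }
  if (any(input_ct <= 0) || any(enriched_ct <= 0)) {
    stop("Ct values must be positive")
  }
  structure(list(target = target, input_ct = as.numeric(input_ct),
                 enriched_ct = as.numeric(enriched_ct),
                 negative_control = isTRUE(negative_control)),
            class = "QpcrMeasurement")
}

#' Fold enrichment from qPCR Ct values
#'
#' Delta Ct is the mean input Ct minus the mean enriched Ct (an enriched
#' template crosses threshold earlier, so enrichment gives positive delta
#' Ct); fold enrichment is `2^deltaCt`.
#'
#' @param m `QpcrMeasurement`.
#' @return list with `delta_ct` and `fold`.
#' @export
fold_enrichment <- function(m) {
  stopifnot(inherits(m, "QpcrMeasurement"))
  delta_ct <- mean(m$input_ct) - mean(m$enriched_ct)
  list(delta_ct = delta_ct, fold = 2^delta_ct)
}

#' Decide whether an enriched sample proceeds to hybridization
#'
#' An enriched negative control means the pull-down is non-specific and is
#' flagged; an unenriched target means the affinity-purification and
#' amplification are repeated (typically with a different protein amount);
#' otherwise the sample proceeds to labeling and hybridization.
#'
#' @param target_fold fold enrichment of the target locus.
#' @param negcontrol_fold fold enrichment of the negative-control locus.
#' @param min_fold minimum fold counted as enrichment (default 2).
#' @return one of `"proceed"`, `"repeat"`, `"flag_nonspecific"`.
#' @export
enrichment_decision <- function(target_fold, negcontrol_fold, min_fold = 2) {
  if (negcontrol_fold >= min_fold) return("flag_nonspecific")
  if (target_fold < min_fold) return("repeat")
  "proceed"
}

#' Relative fluorescence units of a reporter assay
#'
#' RFU is reporter fluorescence normalized by cell growth (optical
#' density).
#'
#' @param fluorescence reporter fluorescence reading(s).
#' @param od optical-density reading(s), strictly positive.
#' @return `fluorescence / od`.
#' @export
rfu <- function(fluorescence, od) {
  if (any(od <= 0)) stop("OD must be positive")
  fluorescence / od
}

#' Read qPCR Ct measurements from a tab-delimited table
#'
#' Expects columns `target`, `fraction` (`input`/`enriched`), `replicate`,
#' `ct`, and optionally `negative_control` (logical).
#'
#' @param path tab-delimited file.
#' @return named list of `QpcrMeasurement` objects, one per target.
#' @export
read_ct_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("target", "fraction", "replicate", "ct")
  if (!all(required %in% names(tab))) {
    stop("Ct table must have columns: ", paste(required, collapse = ", "))
  }
  out <- lapply(split(tab, tab$target), function(d) {
    qpcr_measurement(
      d$target[1L],
      input_ct = d$ct[d$fraction == "input"],
      enriched_ct = d$ct[d$fraction == "enriched"],
      negative_control = isTRUE(as.logical(d$negative_control[1L])))
  })
  out
}
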