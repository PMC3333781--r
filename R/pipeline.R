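#' Pipeline configuration
#'
#' Collects every stage constant of the DAP-chip analysis in one validated
#' object. Defaults are the method's standard settings: a 500-bp sliding
#' window requiring more than four probes above the cutoff, a cutoff
#' schedule descending from 90% to 15% of the hypothetical maximum in steps
#' of one percentage point, 20 track randomizations, and FDR confidence
#' bands at 0.05 and 0.2.
#'
#' @param sim [sim_params()] for synthetic mode.
#' @param window sliding-window width (bp).
#' @param min_probes probes required above the cutoff.
#' @param schedule cutoff percentages, descending.
#' @param n_rand track randomizations for FDR estimation.
#' @param fdr_high,fdr_candidate FDR bands for high-confidence and candidate
#'   peaks.
#' @param motif_score_frac motif-scan threshold as a fraction of the PWM
#'   maximum score.
#' @param min_fold minimum qPCR fold counted as enrichment.
#' @param motif_consensus IUPAC consensus planted and scanned for in
#'   synthetic mode (default the palindromic `GGCANNNNTGCC` element: 4-bp
#'   inverted repeats with a 4-bp spacer).
#' @param n_sigma54 sigma54 promoters planted in synthetic mode.
#' @param bound_region_width width (bp) of planted bound regions.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(), window = 500L,
                            min_probes = 5L, schedule = 90:15,
                            n_rand = 20L, fdr_high = 0.05,
                            fdr_candidate = 0.2, motif_score_frac = 0.8,
                            min_fold = 2, motif_consensus = "GGCANNNNTGCC",
                            n_sigma54 = 5L, bound_region_width = 300L) {
  cfg <- list(sim = sim, window = as.integer(window),
              min_probes = as.integer(min_probes),
              schedule = as.integer(schedule), n_rand = as.integer(n_rand),
              fdr_high = fdr_high, fdr_candidate = fdr_candidate,
              motif_score_frac = motif_score_frac, min_fold = min_fold,
              motif_consensus = motif_consensus,
              n_sigma54 = as.integer(n_sigma54),
              bound_region_width = as.integer(bound_region_width))
  stopifnot(cfg$window > 0, cfg$min_probes > 0, cfg$n_rand >= 1,
            cfg$fdr_high > 0, cfg$fdr_candidate > cfg$fdr_high,
            cfg$motif_score_frac > 0, cfg$motif_score_frac <= 1,
            cfg$min_fold > 0, length(cfg$schedule) >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the `sim:` mapping
#' maps to [sim_params()] arguments. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- if (!is.null(y$sim)) y$sim else list()
  y$sim <- do.call(sim_params, sim_args)
  do.call(pipeline_config, y)
}

# leaders eligible as planted targets: upstream long enough for planting and
# isolated — no other promoter interval within `buffer` bp. Sheared-fragment
# enrichment bleeds about one fragment length beyond a bound region, so a
# region planted next to a second promoter would legitimately map to both
# flanking operons (divergent promoters are resolved manually in practice);
# ground truth is only well defined for isolated promoters.
eligible_target_leaders <- function(ann, index, min_len = 50L, buffer = 500L) {
  ok <- logical(nrow(index))
  for (i in seq_len(nrow(index))) {
    iv <- index[i, ]
    if (iv$end - iv$start < min_len) next
    near <- any(index$feature_id != iv$feature_id &
                  index$replicon == iv$replicon &
                  index$start < iv$end + buffer &
                  iv$start - buffer < index$end)
    ok[i] <- !near
  }
  index$feature_id[ok]
}

#' Simulate a complete synthetic DAP-chip experiment
#'
#' Generates genome + annotation, plants one binding-site motif instance in
#' the upstream region of each of `sim$n_bound_regions` sampled operon
#' leaders (avoiding divergent promoters, which are inherently ambiguous to
#' map), plants sigma54 promoter elements upstream of a disjoint set of
#' leaders, designs the tiling probes, and simulates the enrichment track
#' over bound regions centred on the motif-carrying upstream intervals.
#'
#' @param config `pipeline_config`.
#' @return list with `annotation`, `genome`, `probes`, `upstream_index`,
#'   `track`, and `truth` (`target_genes`, `bound_regions`, `motif_sites`,
#'   `sigma54_sites`).
#' @export
simulate_experiment <- function(config = pipeline_config()) {
  sim <- config$sim
  gen <- generate_genome(sim)
  ann <- gen$annotation
  index <- build_upstream_index(ann, cap = sim$upstream_cap)
  pool <- eligible_target_leaders(ann, index,
                                  min_len = nchar(config$motif_consensus) +
                                    nchar(sigma54_consensus()),
                                  buffer = sim$fragment_length)
  if (length(pool) < sim$n_bound_regions + config$n_sigma54) {
    stop(sprintf("only %d eligible upstream regions for %d planted sites",
                 length(pool), sim$n_bound_regions + config$n_sigma54))
  }
  picks <- with_seed(sim$seed + 1L, sample(pool,
                                           sim$n_bound_regions + config$n_sigma54))
  targets <- picks[seq_len(sim$n_bound_regions)]
  s54_targets <- picks[sim$n_bound_regions + seq_len(config$n_sigma54)]

  genome <- gen$genome
  planted <- plant_motif_sites(genome, ann, config$motif_consensus, targets,
                               seed = sim$seed + 2L, cap = sim$upstream_cap)
  genome <- planted$genome
  s54 <- plant_sigma54_promoters(genome, ann, sigma54_consensus(),
                                 s54_targets, seed = sim$seed + 3L,
                                 cap = sim$upstream_cap)
  genome <- s54$genome

  probes <- design_probes(ann)
  bound <- bound_regions_for_targets(ann, targets, sim,
                                     width = config$bound_region_width)
  track <- simulate_dapchip_track(probes, bound, sim, seed = sim$seed + 4L)
  list(annotation = ann, genome = genome, probes = probes,
       upstream_index = index, track = track,
       truth = list(target_genes = targets, bound_regions = bound,
                    motif_sites = planted$sites, sigma54_sites = s54$sites))
}

#' Run the full DAP-chip analysis pipeline in synthetic mode
#'
#' simulate -> call peaks -> randomization FDR -> map peaks to targets ->
#' curate -> motif scan -> sigma54 scan. The binding-site PWM is built from
#' the planted (aligned) sites, standing in for the externally discovered
#' motif alignment; the sigma54 matrix likewise. When `outdir` is given,
#' every stage output is written in its standard format together with a
#' deterministic manifest (config, seed, versions, file checksums).
#'
#' @param config `pipeline_config`.
#' @param outdir output directory (created if needed), or NULL to skip
#'   writing.
#' @param verbose log stage progress to standard error.
#' @return result bundle: everything from [simulate_experiment()] plus
#'   `peaks`, `target_calls`, `curated`, `pwm`, `motif_hits`, `sigma54_pwm`,
#'   `sigma54_hits`, `top_peaks`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-10s %6.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  sim <- config$sim
  bundle <- stage("simulate", simulate_experiment(config))
  bundle$config <- config

  bundle$peaks <- stage("callpeaks", {
    pk <- call_peaks(bundle$track, config$window, config$min_probes,
                     config$schedule)
    estimate_fdr(bundle$track, pk, n_rand = config$n_rand,
                 seed = sim$seed + 5L, window = config$window,
                 min_probes = config$min_probes, schedule = config$schedule)
  })
  bundle$top_peaks <- top_peaks_report(bundle$peaks, 20L)

  bundle$target_calls <- stage("maptargets", {
    map_peaks_to_targets(bundle$peaks, bundle$upstream_index,
                         bundle$annotation)
  })

  bundle$pwm <- stage("buildpwm", {
    build_pwm(bundle$truth$motif_sites$sequence)
  })
  bundle$motif_hits <- stage("scanmotif", {
    scan_upstream_regions(bundle$pwm, bundle$genome, bundle$upstream_index,
                          threshold = config$motif_score_frac *
                            pwm_max_score(bundle$pwm))
  })
  bundle$curated <- stage("curate", {
    curate_targets(bundle$target_calls, motif_hits = bundle$motif_hits,
                   fdr_max = config$fdr_high)
  })

  bundle$sigma54_pwm <- stage("sigma54pwm", {
    if (nrow(bundle$truth$sigma54_sites) >= 2L) {
      build_pwm(bundle$truth$sigma54_sites$sequence)
    } else sigma54_default_pwm()
  })
  bundle$sigma54_hits <- stage("scan54", {
    scan_sigma54(bundle$sigma54_pwm, bundle$genome, bundle$upstream_index,
                 threshold = config$motif_score_frac *
                   pwm_max_score(bundle$sigma54_pwm))
  })

  if (!is.null(outdir)) stage("write", write_bundle(bundle, outdir))
  bundle
}

#' Write every pipeline output in its standard format, with a manifest
#'
#' @param bundle from [run_pipeline()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_genome_fasta(bundle$genome, fp("genome.fasta"))
  write_annotation_gff3(bundle$annotation, fp("annotation.gff3"))
  write_probes_bed(bundle$probes, fp("probes.bed"))
  write_ratio_track(bundle$track, fp("ratios.tsv"))
  write_ratio_wig(bundle$track, fp("ratios.wig"))
  write_peaks(bundle$peaks, fp("peaks.tsv"))
  write_peaks_bed(bundle$peaks, fp("peaks.bed"))
  write_peaks(bundle$top_peaks, fp("top_peaks.tsv"))
  write_targets(bundle$curated, fp("targets.tsv"))
  write_meme(bundle$pwm, fp("motif.meme"), name = "binding_site")
  write_meme(bundle$sigma54_pwm, fp("sigma54.meme"), name = "sigma54")
  write_motif_hits(bundle$motif_hits, fp("motif_hits.tsv"))
  write_motif_hits(bundle$sigma54_hits, fp("sigma54_hits.tsv"))
  write.table(bundle$truth$bound_regions, fp("truth_bound_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$motif_sites, fp("truth_motif_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$sigma54_sites, fp("truth_sigma54_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  cfg <- bundle$config
  manifest <- list(
    package = "dapmap",
    version = as.character(packageVersion("dapmap")),
    seed = cfg$sim$seed,
    config = cfg[setdiff(names(cfg), "sim")],
    sim = unclass(cfg$sim),
    files = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

overlaps_any <- function(replicon, start, end, regions) {
  vapply(seq_along(start), function(i) {
    any(regions$replicon == replicon[i] &
          regions$start < end[i] & start[i] < regions$end)
  }, logical(1))
}

prec_rec <- function(stage, truth_ids, called_ids) {
  tp <- length(intersect(truth_ids, called_ids))
  data.frame(stage = stage, n_truth = length(truth_ids),
             n_called = length(called_ids), tp = tp,
             fp = length(called_ids) - tp,
             precision = if (length(called_ids)) tp / length(called_ids)
                         else NA_real_,
             recall = if (length(truth_ids)) tp / length(truth_ids)
                      else NA_real_,
             stringsAsFactors = FALSE)
}

#' Recovery of planted truth by each pipeline stage
#'
#' Compares high-confidence peaks against planted bound regions (by
#' overlap), curated retained targets against planted target operons, and
#' motif / sigma54 scan hits against the planted sites (by feature).
#' Precision or recall is `NA` where the corresponding set is empty.
#'
#' @param bundle from [run_pipeline()].
#' @return data.frame: `stage`, `n_truth`, `n_called`, `tp`, `fp`,
#'   `precision`, `recall`.
#' @export
recovery_report <- function(bundle) {
  truth <- bundle$truth
  high <- bundle$peaks[!is.na(bundle$peaks$confidence) &
                         bundle$peaks$confidence == "high", , drop = FALSE]
  region_hit <- if (nrow(truth$bound_regions)) {
    overlaps_any(truth$bound_regions$replicon, truth$bound_regions$start,
                 truth$bound_regions$end,
                 data.frame(replicon = high$replicon, start = high$start,
                            end = high$end))
  } else logical(0)
  peak_tp <- if (nrow(high)) {
    sum(overlaps_any(high$replicon, high$start, high$end,
                     truth$bound_regions))
  } else 0L
  peaks_row <- data.frame(
    stage = "peaks", n_truth = nrow(truth$bound_regions),
    n_called = nrow(high), tp = sum(region_hit), fp = nrow(high) - peak_tp,
    precision = if (nrow(high)) peak_tp / nrow(high) else NA_real_,
    recall = if (nrow(truth$bound_regions))
      sum(region_hit) / nrow(truth$bound_regions) else NA_real_,
    stringsAsFactors = FALSE)

  curated_ids <- unique(bundle$curated$feature_id[bundle$curated$retained])
  rows <- rbind(
    peaks_row,
    prec_rec("targets", truth$target_genes, curated_ids),
    prec_rec("motif_sites", unique(truth$motif_sites$gene_id),
             unique(bundle$motif_hits$feature_id)),
    prec_rec("sigma54_sites", unique(truth$sigma54_sites$gene_id),
             unique(bundle$sigma54_hits$feature_id)))
  rownames(rows) <- NULL
  rows
}
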