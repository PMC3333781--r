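#' Simulation parameters for a synthetic DAP-chip experiment
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' benchmark conditions used throughout the package: a 100 kb genome carrying
#' ~40 operons, DNA sheared to a mean fragment length of 500 bp, fourfold
#' enrichment at bound regions and log2-scale channel noise of sd 0.3.
#'
#' @param genome_length genome length in bp.
#' @param n_operons number of operons to place.
#' @param operon_size integer range (length 2) of genes per operon.
#' @param gene_length integer range (length 2) of gene lengths in bp.
#' @param min_intergenic minimum intergenic gap in bp; gaps also host the
#'   upstream regions, so it should comfortably exceed typical motif widths.
#' @param upstream_cap maximum upstream-region length in bp.
#' @param fragment_length mean sheared-fragment length in bp; also the
#'   half-width of the triangular enrichment kernel.
#' @param noise_sd additive Gaussian noise sd on the log2-ratio scale.
#' @param enrichment_fold expected enrichment fold over bound regions (>= 1).
#' @param n_bound_regions number of bound regions planted by the pipeline's
#'   synthetic mode.
#' @param gc_fraction background GC content of the genome sequence.
#' @param replicon_name name of the single simulated replicon.
#' @param seed integer seed fixing all randomness.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100000L, n_operons = 40L,
                       operon_size = c(1L, 3L), gene_length = c(400L, 1000L),
                       min_intergenic = 200L, upstream_cap = 300L,
                       fragment_length = 500L, noise_sd = 0.3,
                       enrichment_fold = 4, n_bound_regions = 10L,
                       gc_fraction = 0.5, replicon_name = "chr",
                       seed = 1L) {
  p <- list(genome_length = as.integer(genome_length),
            n_operons = as.integer(n_operons),
            operon_size = as.integer(operon_size),
            gene_length = as.integer(gene_length),
            min_intergenic = as.integer(min_intergenic),
            upstream_cap = as.integer(upstream_cap),
            fragment_length = as.integer(fragment_length),
            noise_sd = noise_sd, enrichment_fold = enrichment_fold,
            n_bound_regions = as.integer(n_bound_regions),
            gc_fraction = gc_fraction, replicon_name = replicon_name,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  assert_scalar_pos(p$genome_length, "genome_length")
  if (p$n_operons < 0L) stop("'n_operons' must be >= 0")
  stopifnot(length(p$operon_size) == 2L, p$operon_size[1L] >= 1L,
            p$operon_size[2L] >= p$operon_size[1L],
            length(p$gene_length) == 2L, p$gene_length[1L] >= 50L,
            p$gene_length[2L] >= p$gene_length[1L])
  assert_scalar_pos(p$min_intergenic, "min_intergenic")
  assert_scalar_pos(p$upstream_cap, "upstream_cap")
  assert_scalar_pos(p$fragment_length, "fragment_length")
  if (p$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (p$enrichment_fold < 1) stop("'enrichment_fold' must be >= 1")
  if (p$gc_fraction <= 0 || p$gc_fraction >= 1) stop("'gc_fraction' in (0,1)")
  p
}

#' Design tiling probes over a genome annotation
#'
#' Tiles 50-mer probes over every coding span and every intergenic region:
#' intergenic probes overlap by 46 bp (step 4), coding probes by 20 bp
#' (step 30). Within a region probes advance at the exact step; when the
#' regular grid does not reach the region boundary one final probe is shifted
#' left so that it ends exactly at the boundary. Regions shorter than the
#' probe length get no probes. A probe spanning a region boundary is classed
#' by the region it was tiled from (equivalently, by its start position).
#'
#' @param ann `GenomeAnnotation`.
#' @param probe_length probe length in bp.
#' @param intergenic_overlap,coding_overlap overlap between adjacent probes.
#' @return data.frame of class `ProbeDesign`: `probe_id`, `replicon`,
#'   `start` (0-based), `length`, `context` (`"intergenic"`/`"coding"`),
#'   sorted by (replicon, start).
#' @export
design_probes <- function(ann, probe_length = 50L,
                          intergenic_overlap = 46L, coding_overlap = 20L) {
  steps <- c(intergenic = probe_length - intergenic_overlap,
             coding = probe_length - coding_overlap)
  regions <- list()
  k <- 0L
  for (rep in names(ann$replicons)) {
    L <- ann$replicons[[rep]]
    g <- ann$genes[ann$genes$replicon == rep, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(g$start, g$end)), L)
    types <- rep(c("intergenic", "coding"), length.out = length(bounds) - 1L)
    for (i in seq_len(length(bounds) - 1L)) {
      rs <- bounds[i]; re <- bounds[i + 1L]
      if (re - rs < probe_length) next
      step <- steps[[types[i]]]
      starts <- seq.int(rs, re - probe_length, by = step)
      if (utils::tail(starts, 1L) != re - probe_length) {
        starts <- c(starts, re - probe_length)
      }
      k <- k + 1L
      regions[[k]] <- data.frame(replicon = rep, start = starts,
                                 length = probe_length, context = types[i],
                                 stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(replicon = character(0), start = integer(0),
               length = integer(0), context = character(0))
  out <- out[order(out$replicon, out$start), , drop = FALSE]
  out <- cbind(probe_id = sprintf("P%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ProbeDesign", "data.frame")
  out
}

iupac_sample <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(chars %in% names(map))) {
    stop("consensus contains non-IUPAC characters: ", consensus)
  }
  vapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "")[[1L]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Write `site` into `genome` at [pos, pos+w) on `strand`; returns genome.
splice_site <- function(genome, replicon, pos, strand, site) {
  w <- nchar(site)
  inserted <- if (strand == "+") site else revcomp_chr(site)
  seqs <- as.character(genome)
  s <- seqs[[replicon]]
  seqs[[replicon]] <- paste0(substr(s, 1L, pos), inserted,
                             substr(s, pos + w + 1L, nchar(s)))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  out
}

#' Plant instantiated motif sites into upstream regions
#'
#' For each target gene, draws one instantiation of `motif_spec` (an IUPAC
#' consensus such as `"GGCANNNNTGCC"`, or a `PWM` to sample from), writes it
#' into the genome at a random position and strand inside the gene's upstream
#' region, and records the planted coordinates.
#'
#' @param genome `DNAStringSet`.
#' @param ann `GenomeAnnotation`.
#' @param motif_spec IUPAC consensus string or a [build_pwm()] object.
#' @param target_genes character vector of gene ids.
#' @param seed integer seed.
#' @param cap upstream cap in bp.
#' @return list with the edited `genome` and `sites`, a data.frame
#'   (`gene_id`, `replicon`, `position` 0-based, `strand`, `sequence`).
#' @export
plant_motif_sites <- function(genome, ann, motif_spec, target_genes,
                              seed = 1L, cap = 300L) {
  if (nrow(ann$genes) == 0L || length(target_genes) == 0L) {
    stop("cannot plant motif sites: no target genes available")
  }
  with_seed(seed, {
    rows <- vector("list", length(target_genes))
    for (i in seq_along(target_genes)) {
      gene <- target_genes[i]
      iv <- upstream_interval(ann, gene, cap = cap)
      site <- if (inherits(motif_spec, "PWM")) sample_pwm_site(motif_spec)
              else paste(iupac_sample(motif_spec), collapse = "")
      w <- nchar(site)
      if (iv$end - iv$start < w) {
        stop(sprintf("upstream region of %s (%d bp) shorter than motif (%d bp)",
                     gene, iv$end - iv$start, w))
      }
      pos <- iv$start + sample.int(iv$end - iv$start - w + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      genome <- splice_site(genome, iv$replicon, pos, strand, site)
      rows[[i]] <- data.frame(gene_id = gene, replicon = iv$replicon,
                              position = pos, strand = strand,
                              sequence = site, stringsAsFactors = FALSE)
    }
    list(genome = genome, sites = do.call(rbind, rows))
  })
}

#' Plant sigma54 promoter sites into upstream regions
#'
#' Same mechanics as [plant_motif_sites()] but sites are written on the coding
#' strand of the target gene (promoters are orientation-specific) and the
#' position is additionally reported relative to the translational start
#' (negative, i.e. upstream).
#'
#' @inheritParams plant_motif_sites
#' @param consensus IUPAC consensus of the promoter, e.g. the -24/-12
#'   sigma54 element with its fixed spacer.
#' @return list with `genome` and `sites` (`gene_id`, `replicon`, `position`,
#'   `offset` relative to the start codon, `strand`, `sequence`).
#' @export
plant_sigma54_promoters <- function(genome, ann, consensus, target_genes,
                                    seed = 1L, cap = 300L) {
  if (length(target_genes) == 0L) {
    return(list(genome = genome,
                sites = data.frame(gene_id = character(0),
                                   replicon = character(0),
                                   position = integer(0), offset = integer(0),
                                   strand = character(0),
                                   sequence = character(0))))
  }
  with_seed(seed, {
    rows <- vector("list", length(target_genes))
    for (i in seq_along(target_genes)) {
      gene <- target_genes[i]
      iv <- upstream_interval(ann, gene, cap = cap)
      site <- paste(iupac_sample(consensus), collapse = "")
      w <- nchar(site)
      if (iv$end - iv$start < w) {
        stop(sprintf("upstream region of %s (%d bp) shorter than promoter (%d bp)",
                     gene, iv$end - iv$start, w))
      }
      pos <- iv$start + sample.int(iv$end - iv$start - w + 1L, 1L) - 1L
      genome <- splice_site(genome, iv$replicon, pos, iv$strand, site)
      gi <- match(gene, ann$genes$gene_id)
      offset <- if (iv$strand == "+") pos + w - ann$genes$start[gi]
                else ann$genes$end[gi] - pos
      rows[[i]] <- data.frame(gene_id = gene, replicon = iv$replicon,
                              position = pos, offset = as.integer(offset),
                              strand = iv$strand, sequence = site,
                              stringsAsFactors = FALSE)
    }
    list(genome = genome, sites = do.call(rbind, rows))
  })
}

#' Triangular fragment-coverage weight of a probe over a bound region
#'
#' With DNA sheared to fragments of mean length `frag`, a probe at distance
#' `d` from a bound region is covered by a fraction of region-overlapping
#' fragments that decays linearly to zero at `d = frag`: `w = max(0, 1 -
#' d/frag)`, and `w = 1` when the probe midpoint lies inside the region.
#'
#' @param probe_mid probe midpoint (bp).
#' @param region_start,region_end bound region (0-based half-open).
#' @param frag mean fragment length (bp).
#' @return weight in `[0, 1]`.
#' @export
fragment_weight <- function(probe_mid, region_start, region_end, frag = 500) {
  d <- pmax(0, pmax(region_start - probe_mid, probe_mid - region_end))
  pmax(0, 1 - d / frag)
}

#' Simulate a DAP-chip probe ratio track
#'
#' Each probe's expected log2 ratio is `log2(1 + (fold - 1) * w)` where `w`
#' is the triangular fragment-coverage weight over the nearest bound region
#' (maximum effect across regions when several are close). Gaussian noise of
#' sd `params$noise_sd` is added on the log2 scale and the track is
#' median-centered, mirroring the scaling applied to real arrays.
#'
#' @param probes `ProbeDesign`.
#' @param bound_regions data.frame (`replicon`, `start`, `end`, `fold`);
#'   may have zero rows for a null track.
#' @param params [sim_params()].
#' @param seed integer seed.
#' @param center median-center the track (default TRUE).
#' @return data.frame of class `ProbeRatioTrack`: probe columns plus `log2r`.
#' @export
simulate_dapchip_track <- function(probes, bound_regions, params,
                                   seed = 1L, center = TRUE) {
  if (nrow(bound_regions) > 0 && any(bound_regions$fold < 1)) {
    stop("enrichment folds must be >= 1")
  }
  mids <- probes$start + probes$length / 2
  effect <- rep(0, nrow(probes))
  for (i in seq_len(nrow(bound_regions))) {
    r <- bound_regions[i, ]
    on_rep <- probes$replicon == r$replicon
    w <- fragment_weight(mids[on_rep], r$start, r$end, params$fragment_length)
    effect[on_rep] <- pmax(effect[on_rep], (r$fold - 1) * w)
  }
  log2r <- log2(1 + effect)
  if (params$noise_sd > 0) {
    log2r <- log2r + with_seed(seed, rnorm(length(log2r), 0, params$noise_sd))
  }
  if (center) log2r <- log2r - median(log2r)
  out <- cbind(as.data.frame(probes), log2r = log2r)
  class(out) <- c("ProbeRatioTrack", "data.frame")
  out
}

#' Choose bound regions over upstream intervals of target genes
#'
#' Places one bound region per target, centred on the gene's upstream
#' interval and widened to `width` bp, at the configured enrichment fold.
#'
#' @param ann `GenomeAnnotation`.
#' @param target_genes gene ids.
#' @param params [sim_params()].
#' @param width region width in bp.
#' @return data.frame (`replicon`, `start`, `end`, `fold`, `gene_id`).
#' @export
bound_regions_for_targets <- function(ann, target_genes, params, width = 400L) {
  rows <- lapply(target_genes, function(gene) {
    iv <- upstream_interval(ann, gene, cap = params$upstream_cap)
    mid <- (iv$start + iv$end) %/% 2L
    data.frame(replicon = iv$replicon,
               start = max(0L, mid - width %/% 2L),
               end = min(ann$replicons[[iv$replicon]], mid + width %/% 2L),
               fold = params$enrichment_fold, gene_id = gene,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate triplicate qPCR Ct values for an enriched target
#'
#' Input-fraction Cts are drawn around `base_ct`; enriched-fraction Cts are
#' shifted down by `log2(fold)` (each doubling of template advances detection
#' by one cycle). Per-replicate Gaussian noise is added to both fractions.
#'
#' @param fold true enrichment fold (>= 1 for enrichment; 1 = none).
#' @param noise_sd per-replicate Ct noise sd (cycles).
#' @param n_replicates replicates per fraction.
#' @param seed integer seed.
#' @param base_ct expected input-fraction Ct.
#' @param target id recorded on the measurement.
#' @param negative_control logical flag.
#' @return a [qpcr_measurement()] object.
#' @export
simulate_qpcr <- function(fold, noise_sd = 0.2, n_replicates = 3L, seed = 1L,
                          base_ct = 25, target = "target",
                          negative_control = FALSE) {
  if (fold <= 0) stop("'fold' must be positive")
  with_seed(seed, {
    input <- base_ct + rnorm(n_replicates, 0, noise_sd)
    enriched <- base_ct - log2(fold) + rnorm(n_replicates, 0, noise_sd)
    qpcr_measurement(target, input, enriched,
                     negative_control = negative_control)
  })
}

## ---- track / truth I/O ----------------------------------------------------

#' Write a probe ratio track as tab-delimited text
#' @param track `ProbeRatioTrack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ratio_track <- function(track, path) {
  write.table(track[, c("probe_id", "replicon", "start", "length", "log2r")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe ratio track written by [write_ratio_track()]
#' @param path tab-delimited file.
#' @return `ProbeRatioTrack`.
#' @export
read_ratio_track <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("probe_id", "replicon", "start", "length", "log2r")
  if (!all(required %in% names(out))) {
    stop("ratio track must have columns: ", paste(required, collapse = ", "))
  }
  if (any(!is.finite(out$log2r))) stop("non-finite log2r values in track")
  out <- out[order(out$replicon, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ProbeRatioTrack", "data.frame")
  out
}

#' Write probe design as BED
#' @param probes `ProbeDesign`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_probes_bed <- function(probes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = probes$replicon,
    ranges = IRanges::IRanges(start = probes$start + 1L,
                              width = probes$length),
    name = probes$probe_id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a ratio track as fixed-step-free WIG
#'
#' Emits `variableStep` WIG (one span per probe length) so genome browsers
#' can display the enrichment profile.
#'
#' @param track `ProbeRatioTrack`.
#' @param path output WIG file.
#' @return `path`, invisibly.
#' @export
write_ratio_wig <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$replicon,
    ranges = IRanges::IRanges(start = track$start + 1L, width = track$length),
    score = track$log2r)
  # probes overlap; collapse to per-start point values for WIG validity
  gr <- GenomicRanges::resize(gr, width = 1L, fix = "start")
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}
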