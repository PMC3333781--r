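#' Genome annotation container
#'
#' A `GenomeAnnotation` bundles replicon lengths, gene coordinates and operon
#' membership for a bacterial genome. All coordinates are 0-based half-open
#' (`[start, end)`), the convention used throughout the package; conversion to
#' the 1-based GFF3/GRanges convention happens only at the I/O boundary.
#'
#' @param replicons named integer vector of replicon lengths in bp.
#' @param genes data.frame with columns `gene_id`, `replicon`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and `operon` (operon id, `NA` for monocistronic
#'   genes outside any operon).
#' @return object of class `GenomeAnnotation`.
#' @export
GenomeAnnotation <- function(replicons, genes) {
  stopifnot(is.numeric(replicons), length(names(replicons)) == length(replicons))
  genes <- as.data.frame(genes)
  required <- c("gene_id", "replicon", "start", "end", "strand", "operon")
  if (!all(required %in% names(genes))) {
    stop("genes must have columns: ", paste(required, collapse = ", "))
  }
  genes <- genes[order(genes$replicon, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  obj <- structure(list(replicons = replicons, genes = genes),
                   class = "GenomeAnnotation")
  validate_annotation(obj)
  obj
}

#' Validate a GenomeAnnotation against its invariants
#'
#' Checks that genes lie within replicon bounds, do not overlap within a
#' replicon, and that the genes of each operon are contiguous and co-stranded.
#'
#' @param ann a `GenomeAnnotation`.
#' @return the annotation, invisibly; errors on violation.
#' @export
validate_annotation <- function(ann) {
  g <- ann$genes
  if (nrow(g) == 0L) return(invisible(ann))
  if (any(!g$replicon %in% names(ann$replicons))) {
    stop("gene replicon not found among replicons")
  }
  if (any(g$start < 0) || any(g$end > ann$replicons[g$replicon]) ||
      any(g$end <= g$start)) {
    stop("gene coordinates out of replicon bounds or empty")
  }
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (rep in unique(g$replicon)) {
    gr <- g[g$replicon == rep, ]
    gr <- gr[order(gr$start), ]
    if (nrow(gr) > 1L && any(gr$start[-1L] < gr$end[-nrow(gr)])) {
      stop("overlapping genes on replicon ", rep)
    }
  }
  for (op in unique(g$operon[!is.na(g$operon)])) {
    go <- g[!is.na(g$operon) & g$operon == op, ]
    if (length(unique(go$strand)) != 1L || length(unique(go$replicon)) != 1L) {
      stop("operon ", op, " mixes strands or replicons")
    }
    # contiguity: no foreign gene interleaves the operon's span
    gr <- g[g$replicon == go$replicon[1L], ]
    inside <- gr$start >= min(go$start) & gr$end <= max(go$end)
    if (!all(is.element(gr$gene_id[inside], go$gene_id))) {
      stop("operon ", op, " interrupted by a foreign gene")
    }
  }
  invisible(ann)
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$replicons), "replicon(s),",
      nrow(x$genes), "genes,",
      length(unique(stats::na.omit(x$genes$operon))), "operons\n")
  invisible(x)
}

#' Generate a synthetic operon-structured genome
#'
#' Draws a random genome sequence and places non-overlapping operons of
#' co-stranded genes separated by intergenic gaps of at least
#' `min_intergenic` bp. Gene counts per operon, gene lengths and the small
#' within-operon spacers are drawn uniformly from the configured ranges;
#' leftover sequence is distributed randomly over the intergenic gaps. The
#' result is bit-reproducible for a given `params$seed`.
#'
#' @param params a [sim_params()] list.
#' @return list with `annotation` (a `GenomeAnnotation`) and `genome`
#'   (a [Biostrings::DNAStringSet] with one sequence per replicon).
#' @export
generate_genome <- function(params) {
  params <- validate_sim_params(params)
  with_seed(params$seed, {
    L <- params$genome_length
    n_op <- params$n_operons
    gene_counts <- if (n_op > 0L) {
      sample(seq(params$operon_size[1L], params$operon_size[2L]),
             n_op, replace = TRUE)
    } else integer(0)
    op_layout <- lapply(gene_counts, function(k) {
      lens <- sample(seq(params$gene_length[1L], params$gene_length[2L]),
                     k, replace = TRUE)
      gaps <- if (k > 1L) sample(10:40, k - 1L, replace = TRUE) else integer(0)
      list(lens = lens, gaps = gaps, span = sum(lens) + sum(gaps))
    })
    spans <- vapply(op_layout, `[[`, numeric(1), "span")
    required <- sum(spans) + (n_op + 1L) * params$min_intergenic
    if (required > L) {
      stop(sprintf(
        "genome of %d bp cannot hold %d operons (need >= %d bp)",
        L, n_op, required))
    }
    slack <- L - required
    extra <- if (n_op > 0L && slack > 0) {
      parts <- sort(sample.int(slack + 1L, n_op, replace = TRUE) - 1L)
      diff(c(0L, parts, slack))
    } else rep(0L, n_op + 1L)
    gaps <- params$min_intergenic + extra

    genes <- list()
    pos <- 0L
    gid <- 0L
    for (i in seq_len(n_op)) {
      pos <- pos + gaps[i]
      strand <- sample(c("+", "-"), 1L)
      lay <- op_layout[[i]]
      op_id <- sprintf("opn%03d", i)
      for (j in seq_along(lay$lens)) {
        gid <- gid + 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("DVX%04d", gid), replicon = params$replicon_name,
          start = pos, end = pos + lay$lens[j], strand = strand,
          operon = op_id, stringsAsFactors = FALSE)
        pos <- pos + lay$lens[j]
        if (j < length(lay$lens)) pos <- pos + lay$gaps[j]
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), replicon = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 operon = character(0))
    ann <- GenomeAnnotation(setNames(L, params$replicon_name), genes)

    gc <- params$gc_fraction
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seq_chars <- sample(names(base_probs), L, replace = TRUE, prob = base_probs)
    genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
    names(genome) <- params$replicon_name
    list(annotation = ann, genome = genome)
  })
}

#' Compute the upstream regulatory interval of one gene
#'
#' The upstream region extends at most `cap` bp 5' of the translational
#' start and is truncated at the nearest neighbouring gene (strand-aware:
#' left of the start for `+` genes, right of the end for `-` genes).
#'
#' @param ann `GenomeAnnotation`.
#' @param gene_id gene identifier.
#' @param cap maximum upstream length in bp (default 300).
#' @return list with `replicon`, `start`, `end` (0-based half-open; possibly
#'   empty, `start == end`) and `strand`.
#' @export
upstream_interval <- function(ann, gene_id, cap = 300L) {
  g <- ann$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  gr <- g[g$replicon == g$replicon[i], ]
  if (g$strand[i] == "+") {
    prev_end <- suppressWarnings(max(gr$end[gr$end <= g$start[i] &
                                              gr$gene_id != gene_id]))
    lo <- max(if (is.finite(prev_end)) prev_end else 0L,
              g$start[i] - cap, 0L)
    hi <- g$start[i]
  } else {
    rep_len <- ann$replicons[[g$replicon[i]]]
    next_start <- suppressWarnings(min(gr$start[gr$start >= g$end[i] &
                                                  gr$gene_id != gene_id]))
    lo <- g$end[i]
    hi <- min(if (is.finite(next_start)) next_start else rep_len,
              g$end[i] + cap, rep_len)
  }
  list(replicon = g$replicon[i], start = as.integer(lo),
       end = as.integer(max(lo, hi)), strand = g$strand[i])
}

#' Identify the operon-leading gene of each operon
#'
#' The leading gene is the first gene transcribed: smallest start for a `+`
#' operon, largest end for a `-` operon. Genes outside any operon lead
#' themselves.
#'
#' @param ann `GenomeAnnotation`.
#' @return data.frame with `feature_id` (the leading gene), `operon`, and the
#'   ids of all member `genes` (comma-separated).
#' @export
operon_leaders <- function(ann) {
  g <- ann$genes
  if (nrow(g) == 0L) {
    return(data.frame(feature_id = character(0), operon = character(0),
                      genes = character(0), stringsAsFactors = FALSE))
  }
  key <- ifelse(is.na(g$operon), g$gene_id, g$operon)
  out <- lapply(split(seq_len(nrow(g)), key), function(idx) {
    go <- g[idx, ]
    lead <- if (go$strand[1L] == "+") go$gene_id[which.min(go$start)]
            else go$gene_id[which.max(go$end)]
    data.frame(feature_id = lead,
               operon = if (is.na(go$operon[1L])) go$gene_id[1L] else go$operon[1L],
               genes = paste(go$gene_id[order(go$start)], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the upstream-region index used for peak-to-target mapping
#'
#' One interval per operon (keyed by its leading gene), each at most `cap` bp
#' and truncated at the adjacent feature, never overlapping the feature's own
#' coding span.
#'
#' @param ann `GenomeAnnotation`.
#' @param cap maximum upstream length (bp).
#' @return data.frame of class `UpstreamIndex`: `feature_id`, `operon`,
#'   `genes`, `replicon`, `start`, `end`, `strand`.
#' @export
build_upstream_index <- function(ann, cap = 300L) {
  leaders <- operon_leaders(ann)
  rows <- lapply(seq_len(nrow(leaders)), function(i) {
    iv <- upstream_interval(ann, leaders$feature_id[i], cap = cap)
    data.frame(feature_id = leaders$feature_id[i], operon = leaders$operon[i],
               genes = leaders$genes[i], replicon = iv$replicon,
               start = iv$start, end = iv$end, strand = iv$strand,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), operon = character(0),
               genes = character(0), replicon = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  class(out) <- c("UpstreamIndex", "data.frame")
  out
}

## ---- I/O ------------------------------------------------------------------

#' Write genome sequence as FASTA
#' @param genome `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read genome sequence from FASTA
#' @param path FASTA file.
#' @return `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write annotation as GFF3
#'
#' Genes are emitted as `gene` features with `ID` and (when set) `operon`
#' attributes; coordinates are converted to the 1-based inclusive GFF3
#' convention.
#'
#' @param ann `GenomeAnnotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(g)) g$replicon else character(0),
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = if (nrow(g)) g$strand else character(0))
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$type <- rep("gene", nrow(g))
  S4Vectors::mcols(gr)$operon <- g$operon
  GenomeInfoDb::seqlengths(gr) <- ann$replicons[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read annotation from GFF3
#'
#' Inverse of [write_annotation_gff3()]; replicon lengths are taken from the
#' `##sequence-region` directives when present, otherwise from the maximum
#' feature end.
#'
#' @param path GFF3 file.
#' @return `GenomeAnnotation`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  lens <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(lens))) {
    obs <- vapply(GenomeInfoDb::seqlevels(gr), function(s) {
      max(GenomicRanges::end(gr[GenomicRanges::seqnames(gr) == s]))
    }, numeric(1))
    lens[is.na(lens)] <- obs[is.na(lens)]
  }
  mc <- S4Vectors::mcols(gr)
  genes <- data.frame(
    gene_id = as.character(mc$ID),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    operon = if ("operon" %in% names(mc)) as.character(mc$operon) else NA_character_,
    stringsAsFactors = FALSE)
  GenomeAnnotation(lens, genes)
}
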