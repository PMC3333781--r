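test_that("generated genomes satisfy the annotation invariants", {
  res <- generate_genome(sim_params(genome_length = 10000L, n_operons = 5L,
                                    seed = 1L))
  ann <- res$annotation
  expect_equal(length(res$genome[[1]]), 10000L)
  expect_equal(length(unique(ann$genes$operon)), 5L)
  # validator enforces non-overlap, bounds, co-stranded contiguous operons
  expect_silent(validate_annotation(ann))
  for (op in unique(ann$genes$operon)) {
    expect_length(unique(ann$genes$strand[ann$genes$operon == op]), 1L)
  }
  expect_true(all(ann$genes$start >= 0 & ann$genes$end <= 10000L))
})

test_that("zero operons give an empty gene list and full-length sequence", {
  res <- generate_genome(sim_params(genome_length = 10000L, n_operons = 0L,
                                    seed = 3L))
  expect_equal(nrow(res$annotation$genes), 0L)
  expect_equal(length(res$genome[[1]]), 10000L)
})

test_that("an oversized request raises a sizing error", {
  expect_error(generate_genome(sim_params(genome_length = 3000L,
                                          n_operons = 10L, seed = 1L)),
               "cannot hold")
})

test_that("genome generation is byte-reproducible per seed", {
  p <- sim_params(genome_length = 20000L, n_operons = 8L, seed = 42L)
  a <- generate_genome(p)
  b <- generate_genome(p)
  d <- withr::local_tempdir()
  fa <- c(file.path(d, "a.fasta"), file.path(d, "b.fasta"))
  gf <- c(file.path(d, "a.gff3"), file.path(d, "b.gff3"))
  write_genome_fasta(a$genome, fa[1]); write_genome_fasta(b$genome, fa[2])
  write_annotation_gff3(a$annotation, gf[1])
  write_annotation_gff3(b$annotation, gf[2])
  expect_identical(readLines(fa[1]), readLines(fa[2]))
  expect_identical(readLines(gf[1]), readLines(gf[2]))
})

test_that("probe steps are 4 bp intergenic and 30 bp coding", {
  # one all-intergenic replicon
  ann <- GenomeAnnotation(c(chr = 1000L),
                          data.frame(gene_id = character(0),
                                     replicon = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0),
                                     operon = character(0)))
  pr <- design_probes(ann)
  expect_true(all(pr$context == "intergenic"))
  expect_equal(pr$start[1:3], c(0L, 4L, 8L))
  steps <- diff(pr$start)
  expect_true(all(head(steps, -1) == 4L))
  expect_lte(tail(steps, 1), 4L)  # boundary probe may be shifted left

  # one gene spanning a whole region -> coding step 30
  ann2 <- GenomeAnnotation(c(chr = 1000L),
                           data.frame(gene_id = "g1", replicon = "chr",
                                      start = 0L, end = 1000L, strand = "+",
                                      operon = NA_character_))
  pr2 <- design_probes(ann2)
  cod <- pr2[pr2$context == "coding", ]
  expect_true(all(head(diff(cod$start), -1) == 30L))
})

test_that("regions shorter than one probe get no probes", {
  ann <- GenomeAnnotation(c(chr = 40L),
                          data.frame(gene_id = character(0),
                                     replicon = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0),
                                     operon = character(0)))
  expect_equal(nrow(design_probes(ann)), 0L)
})

test_that("planted motif sites re-extract to sequences matching the consensus", {
  res <- generate_genome(sim_params(genome_length = 30000L, n_operons = 10L,
                                    seed = 5L))
  leaders <- operon_leaders(res$annotation)$feature_id[1:3]
  planted <- plant_motif_sites(res$genome, res$annotation, "GGCANNNNTGCC",
                               leaders, seed = 9L)
  expect_equal(nrow(planted$sites), 3L)
  pat <- "^GGCA[ACGT]{4}TGCC$"
  for (i in 1:3) {
    st <- planted$sites[i, ]
    extracted <- substr(as.character(planted$genome[[st$replicon]]),
                        st$position + 1L, st$position + 12L)
    if (st$strand == "-") {
      extracted <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(extracted)))
    }
    expect_identical(extracted, st$sequence)
    expect_match(st$sequence, pat)
  }
  # determinism
  planted2 <- plant_motif_sites(res$genome, res$annotation, "GGCANNNNTGCC",
                                leaders, seed = 9L)
  expect_identical(planted$sites, planted2$sites)
})

test_that("planting into a geneless genome fails", {
  res <- generate_genome(sim_params(genome_length = 5000L, n_operons = 0L,
                                    seed = 1L))
  expect_error(plant_motif_sites(res$genome, res$annotation, "GGCANNNNTGCC",
                                 character(0)),
               "no target genes")
})

test_that("sigma54 planting records upstream (negative) offsets", {
  res <- generate_genome(sim_params(genome_length = 30000L, n_operons = 10L,
                                    seed = 6L))
  leaders <- operon_leaders(res$annotation)$feature_id[1:2]
  s54 <- plant_sigma54_promoters(res$genome, res$annotation,
                                 sigma54_consensus(), leaders, seed = 2L)
  expect_equal(nrow(s54$sites), 2L)
  expect_true(all(s54$sites$offset < 0))
  empty <- plant_sigma54_promoters(res$genome, res$annotation,
                                   sigma54_consensus(), character(0))
  expect_equal(nrow(empty$sites), 0L)
})

test_that("the noise-free track equals the closed-form enrichment profile", {
  probes <- make_track(rep(0, 9), starts = seq(0, 800, by = 100))
  probes$log2r <- NULL
  p <- sim_params(noise_sd = 0, seed = 1L)
  # no bound regions -> all zero after centering
  null_tr <- simulate_dapchip_track(
    probes, data.frame(replicon = character(0), start = integer(0),
                       end = integer(0), fold = numeric(0)), p)
  expect_true(all(null_tr$log2r == 0))

  # probe fully inside a fold-4 region: log2r = 2 before centering
  region <- data.frame(replicon = "chr", start = 0L, end = 900L, fold = 4)
  tr <- simulate_dapchip_track(probes, region, p, center = FALSE)
  expect_equal(tr$log2r, rep(2, 9))

  # probe midpoint 250 bp beyond the region edge: w = 0.5
  expect_equal(fragment_weight(1150, 0, 900, frag = 500), 0.5)
  region2 <- data.frame(replicon = "chr", start = 0L, end = 100L, fold = 4)
  far <- make_track(0, starts = 325)  # midpoint 350, 250 bp past the edge
  far$log2r <- NULL
  tr2 <- simulate_dapchip_track(far, region2, p, center = FALSE)
  expect_equal(tr2$log2r, log2(1 + 3 * 0.5), tolerance = 1e-12)
  expect_equal(tr2$log2r, 1.3219, tolerance = 1e-4)
})

test_that("track simulation rejects sub-unity folds and is seed-stable", {
  probes <- make_track(rep(0, 5)); probes$log2r <- NULL
  bad <- data.frame(replicon = "chr", start = 0L, end = 100L, fold = 0.5)
  expect_error(simulate_dapchip_track(probes, bad, sim_params()), ">= 1")
  ok <- data.frame(replicon = "chr", start = 0L, end = 100L, fold = 4)
  t1 <- simulate_dapchip_track(probes, ok, sim_params(noise_sd = 0.3), seed = 11L)
  t2 <- simulate_dapchip_track(probes, ok, sim_params(noise_sd = 0.3), seed = 11L)
  expect_identical(t1, t2)
})

test_that("simulated qPCR reproduces the planted fold", {
  m <- simulate_qpcr(fold = 8, noise_sd = 0, n_replicates = 3L, seed = 1L)
  fe <- fold_enrichment(m)
  expect_equal(fe$delta_ct, 3)
  expect_equal(fe$fold, 8)
  m1 <- simulate_qpcr(fold = 1, noise_sd = 0, seed = 1L)
  expect_equal(fold_enrichment(m1)$delta_ct, 0)
  # Monte Carlo: mean delta Ct within 3 standard errors of log2(fold)
  mc <- simulate_qpcr(fold = 4, noise_sd = 0.2, n_replicates = 1000L, seed = 2L)
  se <- sqrt(2 * 0.2^2 / 1000)
  expect_lt(abs(fold_enrichment(mc)$delta_ct - 2), 3 * se)
})
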