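# ATAC coverage, Tn5 shifts, aggregate footprints, neighborhoods.

test_that("shifted 2-bp coverage lands where the worked examples say", {
  lens <- c(chr1 = 300L)
  fw <- data.frame(chrom = "chr1", start = 100L, end = 150L, strand = "+")
  cov <- atac_coverage(fw, lens)
  expect_equal(which(cov$chr1 == 1) - 1L, c(104L, 105L))
  rv <- data.frame(chrom = "chr1", start = 100L, end = 150L, strand = "-")
  cov <- atac_coverage(rv, lens)
  expect_equal(which(cov$chr1 == 1) - 1L, c(144L, 145L))
  expect_error(atac_coverage(data.frame(chrom = "chr1", start = 1, end = 5,
                                        strand = "*"), lens),
               "strand")
})

test_that("coverage mass is twice the read count, modulo edge clipping", {
  set.seed(3)
  n <- 200
  reads <- data.frame(chrom = "chr1",
                      start = sample(0:500, n, TRUE),
                      end = 0L, strand = sample(c("+", "-"), n, TRUE))
  reads$end <- reads$start + 50L
  cov <- atac_coverage(reads, c(chr1 = 560L))
  expect_equal(sum(cov$chr1), 2L * n)
  # clipping: a reverse read at the chromosome start
  edge <- data.frame(chrom = "chr1", start = 0L, end = 4L, strand = "-")
  cov2 <- atac_coverage(edge, c(chr1 = 100L))
  expect_lte(sum(cov2$chr1), 2L)
  empty <- atac_coverage(reads[0, ], c(chr1 = 100L))
  expect_equal(sum(empty$chr1), 0L)
})

test_that("a protected motif leaves a central dip; the element-center control does not", {
  sim <- small_sim(seed = 51, n_per = 150, L = 300, mu = 0, sharing = 0,
                   reads = 400, depletion = 0.2, hw = 15)
  rd <- generate_atac_reads(sim$config, sim$elements, sim$planted)
  cov <- atac_coverage(rd$reads, sim$genome)
  prof <- footprint_profile(cov, sim$elements, "cttatc|gataag",
                            sim$genome, W = 100, mode = "codeword")
  liver_n <- sum(vapply(sim$elements$tissues,
                        function(a) "liver" %in% a, TRUE))
  expect_gt(attr(prof, "n_anchors"), 0.5 * liver_n)
  ctr <- mean(prof$mean[abs(prof$offset) <= 5])
  flank <- mean(prof$mean[abs(prof$offset) >= 50 & abs(prof$offset) <= 100])
  expect_lt(ctr, 0.6 * flank)
  ctrl <- footprint_profile(cov, sim$elements, "cttatc|gataag",
                            sim$genome, W = 100, mode = "element-center")
  expect_equal(attr(ctrl, "n_anchors"), attr(prof, "n_anchors"))
  c0 <- ctrl$mean[ctrl$offset == 0]
  cf <- ctrl$mean[abs(ctrl$offset) >= 50]
  expect_lt(abs(c0 - mean(cf)), 2 * sd(cf) + 2 * ctrl$band[ctrl$offset == 0])
})

test_that("profiles on uniform coverage are flat with vanishing bands", {
  genome <- c(chr1 = strrep("acgt", 2500))
  track <- structure(list(chr1 = rep(7L, 10000L)), class = "coverage_track")
  el <- element_table(data.frame(chrom = "chr1",
                                 start = seq(1000L, 8000L, by = 1000L),
                                 end = seq(1000L, 8000L, by = 1000L) + 500L,
                                 id = sprintf("e%d", 1:8)),
                      tissues = rep(list("t"), 8))
  prof <- footprint_profile(track, el, "acgt|acgt", genome, W = 50,
                            mode = "codeword")
  expect_true(all(prof$mean == 7))
  expect_true(all(prof$band == 0))
})

test_that("elements without the code word are omitted; none matching gives n = 0", {
  genome <- c(chr1 = paste0(strrep("a", 500), "gataag", strrep("a", 494)))
  track <- structure(list(chr1 = rep(1L, 1000L)), class = "coverage_track")
  el <- element_table(data.frame(chrom = "chr1", start = c(400L, 0L),
                                 end = c(600L, 200L), id = c("has", "not")),
                      tissues = list("t", "t"))
  prof <- footprint_profile(track, el, "cttatc|gataag", genome, W = 20,
                            mode = "codeword")
  expect_equal(attr(prof, "n_anchors"), 1L)
  none <- footprint_profile(track, el, "cccgcgc", genome, W = 20,
                            mode = "codeword")
  expect_equal(attr(none, "n_anchors"), 0L)
  expect_true(all(is.na(none$mean)))
})

test_that("the first occurrence is the leftmost match in either orientation", {
  s <- paste0(strrep("t", 30), "cttatc", strrep("t", 20), "gataag",
              strrep("t", 30))
  expect_equal(klrseq:::first_occurrence(s, "cttatc|gataag"), 30L)
  # gapped patterns match through the wildcard
  expect_equal(klrseq:::first_occurrence("ttttcannttttt", "anntg|cannt"), 4L)
  expect_true(is.na(klrseq:::first_occurrence("aaaa", "cg")))
})

test_that("the mitochondrial control anchors at every chrM occurrence", {
  sim <- small_sim(seed = 53, n_per = 10, reads = 50)
  cfg <- sim$config
  cfg$chrm_words <- c("gataag", "gataag")  # ensure presence
  sim2 <- c(list(config = cfg), generate_elements(cfg))
  rd <- generate_atac_reads(cfg, sim2$elements, sim2$planted)
  cov <- atac_coverage(rd$reads, sim2$genome)
  prof <- footprint_profile(cov, NULL, "cttatc|gataag", sim2$genome,
                            W = 50, mode = "mito")
  occ <- klrseq:::all_occurrences(sim2$genome[["chrM"]], "cttatc|gataag")
  in_range <- sum(occ + 2 >= 50 & occ + 2 < nchar(sim2$genome[["chrM"]]) - 50)
  expect_equal(attr(prof, "n_anchors"), in_range)
})

test_that("neighborhood frequencies are one-hot for a single sequence", {
  genome <- c(chr1 = "aacgtaaaa")
  anchors <- data.frame(chrom = "chr1", pos = 4L)  # 't'
  fr <- neighborhood_frequency(genome, anchors, W = 2)
  expect_equal(dim(fr), c(4L, 5L))
  expect_true(all(colSums(fr) == 1))
  expect_equal(unname(fr[, "0"]), c(0, 0, 0, 1))       # t at the anchor
  expect_equal(unname(fr[, "-2"]), c(0, 1, 0, 0))      # c at offset -2
})

test_that("planted motifs dominate neighborhood frequencies at the anchor", {
  sim <- small_sim(seed = 55, n_per = 80, L = 200, mu = 0, sharing = 0)
  liver <- sim$planted[sim$planted$tissue == "liver", ]
  anchors <- data.frame(chrom = liver$chrom, pos = liver$center)
  fr <- neighborhood_frequency(sim$genome, anchors, W = 30)
  # center column (motif position 3 of gataag / 4 of cttatc) is a/t only
  expect_gt(fr["a", "0"] + fr["t", "0"], 0.99)
  # flank columns stay near the background composition (gc = 0.41)
  flank <- fr[, abs(as.integer(colnames(fr))) > 10]
  p_gc <- mean(flank["c", ] + flank["g", ])
  expect_lt(abs(p_gc - 0.41), 3 * sqrt(0.41 * 0.59 / nrow(anchors)))
})

test_that("coverage tracks export as bedGraph runs", {
  track <- structure(list(chr1 = c(0L, 2L, 2L, 0L, 1L)),
                     class = "coverage_track")
  f <- tempfile()
  write_coverage_bedgraph(track, f)
  bg <- read.table(f, sep = "\t")
  expect_equal(bg$V2, c(1L, 4L))
  expect_equal(bg$V3, c(3L, 5L))
  expect_equal(bg$V4, c(2, 1))
  unlink(f)
})
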