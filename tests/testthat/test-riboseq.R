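rpf_granges <- function(tx, start, end, mismatches = 0L) {
  GenomicRanges::GRanges(
    seqnames = tx,
    ranges = IRanges::IRanges(start = start, end = end),
    read_id = sprintf("r%03d", seq_along(start)),
    mismatches = rep_len(mismatches, length(start))
  )
}

test_that("footprint filtering applies length and mismatch bounds", {
  r <- rpf_granges(rep("t1", 4), start = c(1, 1, 1, 1),
                   end = c(24, 30, 30, 33),
                   mismatches = c(0L, 1L, 2L, 0L))
  kept <- filterRPFs(r)
  expect_equal(length(kept), 1L)  # 24 nt too short, 33 too long, 2 mm
  expect_equal(GenomicRanges::width(kept), 30L)
  rej <- attr(kept, "rejects")
  expect_equal(unname(rej["length"]), 2L)
  expect_equal(unname(rej["mismatch"]), 1L)
})

test_that("filtering matches an independent predicate scan on simulated reads", {
  cfg <- simConfig(seed = 19, n_transcripts = 40, family_length = 60,
                   rpf = list(error_rate = 0.02))
  sim <- simulateTranscriptome(cfg)
  rp <- simulateRPFs(sim)
  kept <- filterRPFs(rp, 25, 32, 1)
  w <- GenomicRanges::width(rp)
  keep <- logical(length(rp))
  for (i in seq_along(rp))
    keep[i] <- w[i] >= 25 && w[i] <= 32 && rp$mismatches[i] <= 1
  expect_equal(kept$read_id, rp$read_id[keep])
})

test_that("frame distribution recovers simulated 3'-end bias", {
  cfg <- simConfig(seed = 23, n_transcripts = 150, family_length = 80,
                   rpf = list(elong_depth = 40, stop_depth = 0,
                              frame3_prob = 0.8,
                              readthrough = 0, error_rate = 0))
  sim <- simulateTranscriptome(cfg)
  rp <- simulateRPFs(sim)
  fd <- frameDistribution(rp, sim$transcripts)
  pooled <- sum(fd$end_frame3 * fd$n) / sum(fd$n)
  se <- sqrt(0.8 * 0.2 / sum(fd$n))
  expect_lt(abs(pooled - 0.8), 4 * se)
  ## degenerate case: everything placed in frame 3
  cfg1 <- simConfig(seed = 24, n_transcripts = 40, family_length = 60,
                    rpf = list(elong_depth = 20, stop_depth = 0,
                               frame3_prob = 1, readthrough = 0,
                               error_rate = 0))
  sim1 <- simulateTranscriptome(cfg1)
  fd1 <- frameDistribution(simulateRPFs(sim1), sim1$transcripts)
  expect_true(all(fd1$end_frame3 == 1))
})

test_that("metaprofile offsets follow the positions-1-3 anchor convention", {
  ## a single footprint ending 11 nt after the stop 3' nt: offset 14
  tx <- transcriptSet(c(t1 = paste0(strrep("GCT", 20), "TAA",
                                    strrep("GTC", 10))), frame = 0)
  stop_start <- 61L
  r <- rpf_granges("t1", start = stop_start + 2L + 11L - 29L,
                   end = stop_start + 2L + 11L)
  prof <- endMetaprofile(r, data.frame(transcript_id = "t1",
                                       anchor_start = stop_start),
                         tx, anchor_class = "stop")
  expect_equal(sum(prof@counts), 1L)
  expect_equal(prof@offsets[which(rowSums(prof@counts) == 1L)], 14L)
  term <- classifyTermination(prof)
  expect_equal(term$modal_offsets, 11L)
  expect_equal(term$modal_fraction, 1)
  ## no footprints: all-zero profile, classification errors
  empty <- endMetaprofile(r[0], data.frame(transcript_id = "t1",
                                           anchor_start = stop_start), tx)
  expect_equal(sum(empty@counts), 0L)
  expect_error(classifyTermination(empty), "empty")
  ## out-of-bounds anchors are skipped with a count
  oob <- endMetaprofile(r, data.frame(transcript_id = "t1",
                                      anchor_start = 1000L), tx)
  expect_equal(attr(oob, "skipped_anchors"), 1L)
})

test_that("metaprofile equals an independent per-anchor tally", {
  cfg <- simConfig(seed = 31, n_transcripts = 60, family_length = 60)
  sim <- simulateTranscriptome(cfg)
  rp <- simulateRPFs(sim)
  anchors <- data.frame(transcript_id = sim$truth$transcript_id,
                        anchor_start = sim$truth$stop_start)
  prof <- endMetaprofile(rp, anchors, sim$transcripts, flank = 30)
  ends <- GenomicRanges::end(rp)
  txn <- as.character(GenomicRanges::seqnames(rp))
  expected <- integer(length(prof@offsets))
  names(expected) <- as.character(prof@offsets)
  for (k in seq_len(nrow(anchors))) {
    o <- ends[txn == anchors$transcript_id[k]] - anchors$anchor_start[k] + 1L
    o <- o[o >= min(prof@offsets) & o <= max(prof@offsets)]
    for (x in o) expected[as.character(x)] <- expected[as.character(x)] + 1L
  }
  expect_equal(unname(rowSums(prof@counts)), unname(expected))
  ## totals conserve contributing footprint ends
  expect_equal(sum(prof@counts), sum(expected))
})

test_that("readthrough estimation counts signatures and extensions", {
  ## 100 terminating footprints, none downstream: rate 0
  tx_id <- "t1"
  stop_start <- 61L
  ends <- rep(stop_start + 2L + c(11L, 12L), 50)
  r <- rpf_granges(rep(tx_id, 100), start = ends - 29L, end = ends)
  stops <- data.frame(transcript_id = tx_id, stop_start = stop_start)
  est <- estimateReadthrough(r, stops)
  expect_equal(est$per_transcript$rate, 0)
  expect_true(est$per_transcript$covered)
  expect_equal(est$summary$fraction_zero, 1)
  ## add 10 downstream extensions (>= 13 nt past the stop 3' nt)
  ends2 <- c(ends, rep(stop_start + 2L + 15L, 10))
  r2 <- rpf_granges(rep(tx_id, 110), start = ends2 - 29L, end = ends2)
  est2 <- estimateReadthrough(r2, stops)
  expect_equal(est2$per_transcript$n_stop, 100L)
  expect_equal(est2$per_transcript$n_downstream, 10L)
  expect_equal(est2$per_transcript$rate, 10 / 110)
  ## 12 nt past the stop is termination, not readthrough
  e3 <- rep(stop_start + 2L + 12L, 30)
  r3 <- rpf_granges(rep(tx_id, 30), start = e3 - 29L, end = e3)
  est3 <- estimateReadthrough(r3, stops)
  expect_equal(est3$per_transcript$n_downstream, 0L)
  ## coverage filter is strict: exactly 20 footprints is not covered
  e4 <- rep(stop_start + 2L + 11L, 20)
  r4 <- rpf_granges(rep(tx_id, 20), start = e4 - 29L, end = e4)
  expect_false(estimateReadthrough(r4, stops)$per_transcript$covered)
  ## density-ratio alternative responds to the same extensions
  estd <- estimateReadthrough(r2, stops, method = "density")
  expect_gt(estd$per_transcript$rate, 0)
})

test_that("coverage track equals brute-force interval stabbing", {
  r <- rpf_granges(rep("t1", 2), start = c(5, 25), end = c(34, 54))
  cov <- coverageTrack(r, "t1", 60)
  expect_equal(sum(cov == 1), 40)
  expect_equal(sum(cov == 2), 10)  # 10-nt overlap plateau
  expect_equal(cov[1:4], rep(0L, 4))
  set.seed(9)
  s <- sample(1:70, 40, TRUE); e <- s + sample(24:31, 40, TRUE)
  rr <- rpf_granges(rep("t1", 40), start = s, end = pmin(e, 100))
  expect_equal(coverageTrack(rr, "t1", 100),
               oracle_coverage(s, pmin(e, 100), 100))
})

test_that("SAM round trip preserves footprints and feeds the filter", {
  cfg <- simConfig(seed = 41, n_transcripts = 30, family_length = 60,
                   rpf = list(error_rate = 0.01))
  sim <- simulateTranscriptome(cfg)
  f <- tempfile(fileext = ".sam")
  rp <- simulateRPFs(sim, sam = f)
  back <- readRPFs(f, sim$transcripts)
  key <- function(g) sort(paste(as.character(GenomicRanges::seqnames(g)),
                                GenomicRanges::start(g),
                                GenomicRanges::end(g), g$mismatches))
  expect_equal(key(back), key(rp))
  expect_equal(attr(back, "rejects"),
               c(unmapped = 0L, secondary = 0L))
})

test_that("upstream sense stop-set codons show no coverage drop", {
  ## fully translated sense "stop" codons 24-66 nt upstream of the stop
  ## are tiled by elongating footprints like any other codon
  cfg <- simConfig(seed = 71, n_transcripts = 300, family_length = 80,
                   sense_usage = 0.01,
                   rpf = list(elong_depth = 60, stop_depth = 0,
                              readthrough = 0, error_rate = 0))
  sim <- simulateTranscriptome(cfg)
  rp <- filterRPFs(simulateRPFs(sim))
  ss <- stopSet(cfg$code)
  ratios <- c()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    p <- tr$stop_start - seq(66, 24, by = -3)
    cods <- substring(as.character(sim$transcripts[[i]]), p, p + 2L)
    hit <- which(cods %in% ss)
    if (!length(hit)) next
    cov <- coverageTrack(rp, tr$transcript_id, tr$length)
    for (h in hit) {
      at <- mean(cov[p[h]:(p[h] + 2L)])
      flank <- mean(cov[(p[h] - 12L):(p[h] - 1L)])
      if (flank > 0) ratios <- c(ratios, at / flank)
    }
  }
  expect_gt(length(ratios), 20)
  expect_gt(mean(ratios), 0.9)  # no systematic dip at the codon
})
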