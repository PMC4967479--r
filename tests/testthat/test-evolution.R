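test_that("NG86 handles identity, forced synonymy and undefined ratios", {
  same <- ng86Dnds("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(same$Nd, 0)
  expect_equal(same$Sd, 0)
  expect_false(same$ratio_defined)
  ## one codon pair TTT <-> TTC (F <-> F): one synonymous difference
  fs <- ng86Dnds("TTT", "TTC")
  expect_equal(fs$Sd, 1)
  expect_equal(fs$Nd, 0)
  ## N + S = 3 * codon count under the site-averaging convention
  expect_equal(fs$N + fs$S, 3)
  expect_error(ng86Dnds("ATG", "ATGAAA"), "equal-length")
  expect_error(ng86Dnds("TAAGCT", "CAAGCT"), "internal stop")
  ## reassignment awareness: TGA is sense under the ambiguous code
  amb <- ciliateGeneticCode("ambiguous")
  res <- ng86Dnds("TGATGG", "TGGTGG", code = amb)
  expect_equal(res$Nd + res$Sd, 1)
})

test_that("NG86 counts match recursive pathway enumeration on random pairs", {
  map <- codonAssignments(standardGeneticCode())
  sense <- names(map)[map != "*"]
  set.seed(17)
  for (rep in 1:50) {
    c1 <- sample(sense, 8, TRUE); c2 <- sample(sense, 8, TRUE)
    res <- ng86Dnds(paste(c1, collapse = ""), paste(c2, collapse = ""))
    S_o <- (sum(vapply(c1, oracle_ng86_sites, numeric(1), map = map)) +
            sum(vapply(c2, oracle_ng86_sites, numeric(1), map = map))) / 2
    d_o <- rowSums(vapply(seq_along(c1), function(i)
      oracle_ng86_diffs(c1[i], c2[i], map), numeric(2)))
    expect_equal(res$S, S_o, tolerance = 1e-9)
    expect_equal(res$N, 24 - S_o, tolerance = 1e-9)
    expect_equal(res$Sd, unname(d_o["sd"]), tolerance = 1e-9)
    expect_equal(res$Nd, unname(d_o["nd"]), tolerance = 1e-9)
  }
})

test_that("codon alignment reader drops gap columns before dN/dS", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATG---GCTTGG", ">b", "ATGAAAGCC---"), f)
  aln <- readCodonAlignment(f)
  expect_equal(aln$seq1, "ATGGCT")
  expect_equal(aln$seq2, "ATGGCC")
  res <- ng86Dnds(aln$seq1, aln$seq2)
  expect_equal(res$Sd, 1)
})

test_that("stop codon usage summarises fractions above the species floor", {
  calls <- data.frame(stop_codon = c(rep("TAA", 91), rep("TAG", 5),
                                     rep("TGA", 4)))
  u <- stopCodonUsage(calls)
  expect_equal(u$frac_TAA, 0.91)
  expect_equal(u$frac_TAA + u$frac_TAG + u$frac_TGA, 1)
  ## below the floor: excluded
  small <- data.frame(stop_codon = rep("TAA", 49))
  expect_error(stopCodonUsage(small), "min_stops")
  multi <- stopCodonUsage(list(big = calls, small = small))
  expect_equal(multi$species, "big")
  all_taa <- stopCodonUsage(data.frame(stop_codon = rep("TAA", 60)))
  expect_equal(c(all_taa$frac_TAA, all_taa$frac_TAG, all_taa$frac_TGA),
               c(1, 0, 0))
})

test_that("blepharisma-like stop sets concentrate usage on UAA", {
  cfg <- simConfig(seed = 55, n_transcripts = 150, family_length = 60,
                   code = ciliateGeneticCode("UGA=W"),
                   stop_probs = c(TAA = 0.91, TAG = 0.09))
  sim <- simulateTranscriptome(cfg)
  pa <- detectPolyA(sim$transcripts, max_mismatch = 0)
  st <- findPrimaryStop(sim$transcripts, pa, stopSet(cfg$code))
  u <- stopCodonUsage(st)
  expect_gt(u$frac_TAA, 0.8)
  expect_equal(u$count_TGA, 0L)
})

test_that("fourfold-site identification follows the code", {
  tx <- transcriptSet(c(a = "GGAGGCGGTGGG"), frame = 0,
                      cds_start = 1, cds_end = 12)
  fc <- fourfoldComposition(tx)
  expect_equal(fc$n_sites, 4L)  # every Gly third position counts
  expect_equal(sum(fc$fractions), 1)
  tx2 <- transcriptSet(c(b = "ATGTGGATGTGG"), frame = 0,
                       cds_start = 1, cds_end = 12)
  expect_error(fourfoldComposition(tx2), "fourfold")
  ## reassignment changes degeneracy only in the affected codon boxes:
  ## under UGA=W the TGN box is still not fourfold (TGG=W vs TGC=C), and
  ## the standard fourfold boxes persist
  amb <- ciliateGeneticCode("UGA=W")
  fc2 <- fourfoldComposition(tx, code = amb)
  expect_equal(fc2$n_sites, 4L)
})

test_that("programmed linear relation between UAA usage and A composition is recovered", {
  set.seed(88)
  slope <- 1.2; intercept <- 0.35
  rows <- lapply(1:8, function(j) {
    a4 <- 0.15 + 0.05 * j
    ## CDS of Gly codons with programmed third-base A fraction
    third <- sample(c("A", "C", "G", "T"), 4000, TRUE,
                    prob = c(a4, (1 - a4) / 3, (1 - a4) / 3, (1 - a4) / 3))
    cds <- paste(paste0("GG", third), collapse = "")
    tx <- transcriptSet(stats::setNames(cds, "t"), frame = 0,
                        cds_start = 1, cds_end = nchar(cds))
    fc <- fourfoldComposition(tx)
    u <- min(1, max(0, intercept + slope * a4 + stats::rnorm(1, 0, 0.02)))
    n <- 300
    calls <- data.frame(stop_codon = sample(
      c("TAA", "TAG", "TGA"), n, TRUE, prob = c(u, (1 - u) / 2, (1 - u) / 2)))
    su <- stopCodonUsage(calls)
    data.frame(species = paste0("sp", j),
               uaa_fraction = su$frac_TAA,
               a4_fraction = unname(fc$fractions["A"]))
  })
  fit <- uaaCompositionFit(do.call(rbind, rows))
  expect_lt(fit$p_value, 0.01)
  expect_gt(fit$r, 0.8)
  se <- summary(fit$fit)$coefficients[2, 2]
  expect_lt(abs(fit$slope - slope), 4 * se)
})

test_that("fourfold-site sets coincide between standard and reassigned codes", {
  ## UGA=W changes only the TGN codon box, which is not fourfold under
  ## either code (TGC/TGT stay Cys), so the fourfold tallies agree on a
  ## CDS enumerating all 64 codons
  cds <- paste(CODONS, collapse = "")
  tx <- transcriptSet(c(a = cds), frame = 0, cds_start = 1,
                      cds_end = nchar(cds))
  f_std <- fourfoldComposition(tx, standardGeneticCode())
  f_var <- fourfoldComposition(tx, ciliateGeneticCode("UGA=W"))
  expect_identical(f_std$n_sites, f_var$n_sites)
  expect_identical(f_std$fractions, f_var$fractions)
  ## and the fully ambiguous code likewise adds no new fourfold box
  f_amb <- fourfoldComposition(tx, ciliateGeneticCode("ambiguous"))
  expect_identical(f_std$n_sites, f_amb$n_sites)
})
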