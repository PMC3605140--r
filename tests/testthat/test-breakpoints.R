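# Breakpoint-interval calling, heterozygote decomposition, haplotype
# counting and distribution tables.

cfgBp <- simConfig(seed = 101)
simBp <- simulateLCRPair(cfgBp)

# direct construction of a single-allele call vector with a crossover at
# position bp (deletion: proximal = LCR1)
alleleCalls <- function(markers, bp, kind = "DELETION") {
  prox <- if (kind == "DELETION") markers$lcr1_allele else markers$lcr2_allele
  dist <- if (kind == "DELETION") markers$lcr2_allele else markers$lcr1_allele
  calls <- ifelse(markers$position < bp, prox, dist)
  names(calls) <- markers$marker_id
  calls
}

test_that("the maximal interval brackets the allele-origin switch", {
  mk <- simBp$markers
  spc <- mk[mk$klass == "LCR_SPECIFIC", ]
  # crossover between specific markers 18 and 24 -> BP2
  bp <- mean(mk$position[mk$marker_id %in% c(18, 24)])
  cl <- callBreakpoint(alleleCalls(mk, bp), mk)
  expect_equal(cl$left_marker, 18L)
  expect_equal(cl$right_marker, 24L)
  expect_equal(cl$bin, "BP2")
  expect_equal(cl$max_region_bp,
               diff(mk$position[mk$marker_id %in% c(18, 24)]))
  # a genotype matching one repeat throughout: breakpoint outside window
  all1 <- setNames(mk$lcr1_allele, mk$marker_id)
  expect_equal(callBreakpoint(all1, mk)$bin, "OUTSIDE")
  all2 <- setNames(mk$lcr2_allele, mk$marker_id)
  expect_equal(callBreakpoint(all2, mk)$bin, "OUTSIDE")
})

test_that("shared SNPs and missing calls never tighten the interval", {
  mk <- simBp$markers
  bp <- mean(mk$position[mk$marker_id %in% c(18, 24)])
  calls <- alleleCalls(mk, bp)
  # scrambling every SNP call leaves the interval untouched
  snpIds <- as.character(mk$marker_id[mk$klass == "SHARED_SNP"])
  calls2 <- calls
  calls2[snpIds] <- "A/T"
  expect_equal(callBreakpoint(calls2, mk)[, 1:4],
               callBreakpoint(calls, mk)[, 1:4])
  # a missing flanking specific call widens the interval to the next
  # called marker
  calls3 <- calls
  calls3["18"] <- NA
  cl <- callBreakpoint(calls3, mk)
  expect_equal(cl$left_marker, 17L)
  expect_equal(cl$right_marker, 24L)
})

test_that("non-monotone and malformed genotypes are diagnosed", {
  mk <- simBp$markers
  bp <- mean(mk$position[mk$marker_id %in% c(18, 24)])
  calls <- alleleCalls(mk, bp)
  calls["28"] <- mk$lcr1_allele[mk$marker_id == 28]  # proximal reappears
  cl <- callBreakpoint(calls, mk)
  expect_equal(cl$bin, "UNRESOLVED")
  expect_match(cl$note, "non-monotone")
  calls2 <- alleleCalls(mk, bp)
  calls2["17"] <- "X"
  expect_error(callBreakpoint(calls2, mk), "marker 17")
  het <- alleleCalls(mk, bp)
  het["24"] <- paste(sort(c(mk$lcr1_allele[mk$marker_id == 24],
                            mk$lcr2_allele[mk$marker_id == 24])),
                     collapse = "/")
  expect_error(callBreakpoint(het, mk), "decomposeHeterozygote")
})

test_that("called intervals always contain the generator's true crossover", {
  coh <- simulateCohort(cfgBp, simBp, nAlleles = 200)
  calls <- callBreakpoints(allelesAsGenotypes(coh), simBp$markers)
  expect_equal(nrow(calls), 200L)
  expect_equal(calls$bin, coh$bin_true)
  expect_true(all(calls$left_pos < coh$breakpoint_pos &
                  coh$breakpoint_pos < calls$right_pos))
})

test_that("reciprocal deletion/duplication junctions give the same bin", {
  mk <- simBp$markers
  for (b in c("BP1", "BP2", "BP3")) {
    iv <- defaultBinMap()[defaultBinMap()$bin == b, ]
    bp <- mean(mk$position[mk$marker_id %in% c(iv$left, iv$right)])
    delBin <- callBreakpoint(alleleCalls(mk, bp, "DELETION"), mk,
                             kind = "DELETION")$bin
    dupBin <- callBreakpoint(alleleCalls(mk, bp, "DUPLICATION"), mk,
                             kind = "DUPLICATION")$bin
    expect_equal(delBin, b)
    expect_equal(dupBin, b)
  }
})

test_that("compound heterozygotes decompose into the unique monotone pair", {
  mk <- simBp$markers
  # two deleted alleles, BP2 and BP3: heterozygous exactly at the
  # specific markers separating the two crossovers
  coh <- simulateCohort(cfgBp, simBp, binCounts = c(BP2 = 1, BP3 = 1),
                        kind = "DELETION", source = "SOMATIC")
  g <- assembleGenotypes(coh, matrix(c(1, 2), nrow = 1))
  mcols <- grep("^m[0-9]+$", names(g), value = TRUE)
  calls <- setNames(as.character(g[1, mcols]), sub("^m", "", mcols))
  pair <- decomposeHeterozygote(calls, mk)
  expect_setequal(pair$bin, c("BP2", "BP3"))
  # homozygous input is rejected
  solo <- simulateCohort(cfgBp, simBp, binCounts = c(BP2 = 2),
                         kind = "DELETION", source = "SOMATIC")
  gHom <- assembleGenotypes(solo, matrix(c(1, 1), nrow = 1))
  callsHom <- setNames(as.character(gHom[1, mcols]), sub("^m", "", mcols))
  expect_error(decomposeHeterozygote(callsHom, mk), "no heterozygous")
  # non-contiguous heterozygosity has no consistent monotone pair
  bad <- calls
  spc <- mk[mk$klass == "LCR_SPECIFIC", ]
  a17 <- paste(sort(c(mk$lcr1_allele[mk$marker_id == 17],
                      mk$lcr2_allele[mk$marker_id == 17])), collapse = "/")
  bad["17"] <- a17  # het at 17 while 18 is homozygous
  res <- decomposeHeterozygote(bad, mk)
  expect_true(all(res$bin == "UNRESOLVED"))
})

test_that("simulated two-allele mixtures are fully recovered", {
  mk <- simBp$markers
  mcols <- paste0("m", mk$marker_id)
  combos <- utils::combn(c("BP1", "BP2", "BP3", "BP4", "BP5"), 2)
  for (j in seq_len(ncol(combos))) {
    bc <- setNames(c(1, 1), combos[, j])
    coh <- simulateCohort(cfgBp, simBp, binCounts = bc,
                          kind = "DELETION", source = "SOMATIC",
                          streamOffset = 50L + j)
    g <- assembleGenotypes(coh, matrix(c(1, 2), nrow = 1))
    calls <- setNames(as.character(g[1, mcols]), mk$marker_id)
    pair <- decomposeHeterozygote(calls, mk)
    expect_setequal(pair$bin, combos[, j])
  }
})

test_that("founder structure yields the expected distinct-haplotype counts", {
  # somatic cohort emulating 15 patients: 14 + 13 + 3 alleles over
  # BP1-BP3 with 3/2/2 founders
  coh <- simulateCohort(cfgBp, simBp,
                        binCounts = c(BP1 = 14, BP2 = 13, BP3 = 3),
                        kind = "DELETION", source = "SOMATIC")
  calls <- callBreakpoints(allelesAsGenotypes(coh), simBp$markers)
  hap <- countHaplotypes(data.frame(bin = calls$bin,
                                    snp_vector = coh$snp_vector))
  expect_equal(hap$perBin[c("BP1", "BP2", "BP3")],
               c(BP1 = 3L, BP2 = 2L, BP3 = 2L))
  expect_equal(hap$total, 7L)
  # single founder: one haplotype
  one <- countHaplotypes(data.frame(bin = "BP1",
                                    snp_vector = rep("AAAA", 5)))
  expect_equal(one$total, 1L)
  # empty input: zero counts
  expect_equal(countHaplotypes(data.frame(bin = character(),
                                          snp_vector = character()))$total,
               0L)
  # k founders -> k haplotypes whenever every founder is drawn
  coh2 <- simulateCohort(cfgBp, simBp, binCounts = c(BP2 = 9),
                         foundersPerBin = c(BP2 = 4L), streamOffset = 9L)
  expect_equal(length(unique(coh2$snp_vector)), 4L)
  expect_error(countHaplotypes(data.frame(bin = "UNRESOLVED",
                                          snp_vector = "A")), "resolved")
})

test_that("distribution tables reproduce the observed percentages", {
  mkCalls <- function(counts, kind, source)
    data.frame(bin = rep(names(counts), counts), allele_kind = kind,
               source = source, stringsAsFactors = FALSE)
  somDel <- mkCalls(c(BP1 = 14, BP2 = 16, BP3 = 4), "DELETION", "SOMATIC")
  tab <- tabulateDistribution(somDel)
  expect_equal(tab$pooled$pct, c(41.2, 47.1, 11.8))
  spermDel <- mkCalls(c(BP1 = 2, BP2 = 56, BP3 = 10, BP4 = 2, BP5 = 4),
                      "DELETION", "SPERM")
  expect_equal(tabulateDistribution(spermDel)$pooled$pct,
               c(2.7, 75.7, 13.5, 2.7, 5.4))
  # one allele: 100% in its bin
  expect_equal(tabulateDistribution(mkCalls(c(BP2 = 1), "DELETION",
                                            "SPERM"))$pooled$pct, 100)
  # groups are tabulated separately and percentages sum to ~100
  both <- rbind(somDel, spermDel)
  tb <- tabulateDistribution(both)
  expect_equal(nrow(unique(tb$byGroup[, c("allele_kind", "source")])), 2L)
  sums <- tapply(tb$byGroup$pct, paste(tb$byGroup$allele_kind,
                                       tb$byGroup$source), sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("genotype tables and breakpoint reports round-trip through TSV", {
  coh <- simulateCohort(cfgBp, simBp, nAlleles = 5)
  g <- allelesAsGenotypes(coh)
  tsv <- tempfile(fileext = ".tsv")
  write.table(g, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- readGenotypeTable(tsv)
  expect_equal(names(g2), names(g))
  calls <- callBreakpoints(g2, simBp$markers)
  expect_equal(calls$bin, coh$bin_true)
  out <- tempfile(fileext = ".tsv")
  writeBreakpointReport(calls, out)
  back <- read.delim(out)
  expect_equal(back$bin, calls$bin)
  unlink(c(tsv, out))
})
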