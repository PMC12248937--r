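# Private-SNP calling and marker triage.

test_that("private-SNP caller agrees with a brute-force oracle", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_toy_matrix(sample(3:8, 1), sample(50:200, 1),
                           indels = i %% 3 == 0)
    for (md in c(0L, 50L)) {
      got <- call_private_snps(m, md)
      want <- oracle_private(m, md)
      expect_identical(nrow(got), nrow(want))
      expect_setequal(paste(got$strain, got$chrom, got$pos),
                      paste(want$strain, want$chrom, want$pos))
    }
  }
})

test_that("caller applies the definitional filters", {
  loci <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                     ref = c("A", "A", "A", "A", "A"),
                     alt = c("G", "G", "AT", "G", "G"))
  geno <- rbind(
    c("hom_ref", "het", "hom_ref", "hom_ref"),   # private to S2
    c("hom_ref", "het", "hom_alt", "hom_ref"),   # shared by two -> excluded
    c("hom_ref", "hom_alt", "hom_ref", "hom_ref"), # insertion -> excluded
    c("hom_ref", "hom_alt", "hom_ref", "missing"), # missing -> excluded
    c("hom_ref", "hom_ref", "hom_alt", "hom_ref")) # low depth -> excluded
  depth <- matrix(60L, 5, 4); depth[5, 1] <- 30L
  m <- genotype_matrix(paste0("S", 1:4), loci, geno, depth)
  got <- call_private_snps(m, 50L)
  expect_identical(got$pos, 10L)
  expect_identical(got$strain, "S2")
  expect_identical(got$zygosity, "het")
  # with min_depth 0 the low-depth locus comes back, the rest stay excluded
  expect_setequal(call_private_snps(m, 0L)$pos, c(10L, 50L))
})

test_that("raising min_depth never adds a reported SNP (monotonicity)", {
  set.seed(12)
  for (i in 1:10) {
    m <- random_toy_matrix(5, 100)
    prev <- call_private_snps(m, 0L)
    for (md in c(40L, 60L, 90L)) {
      cur <- call_private_snps(m, md)
      expect_true(all(paste(cur$chrom, cur$pos, cur$strain) %in%
                        paste(prev$chrom, prev$pos, prev$strain)))
      prev <- cur
    }
  }
})

test_that("planted private SNPs are recovered exactly (sensitivity = specificity = 1)", {
  truth <- collection28()
  got <- call_private_snps(truth$matrix, 50L)
  planted <- do.call(rbind, truth$private)
  expect_identical(nrow(got), nrow(planted))
  expect_setequal(paste(got$strain, got$chrom, got$pos, got$alt),
                  paste(planted$strain, planted$chrom, planted$pos,
                        planted$alt))
})

test_that("marker criteria flag polymorphic, repetitive, masked and GC-extreme flanks", {
  set.seed(13)
  base <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  # plant a homopolymer next to position 2000
  seqs <- c(chr1 = base, chr2 = base)
  substr(seqs[["chr1"]], 2005, 2016) <- "AAAAAAAAAAAA"
  # GC-extreme stretch (no homopolymer/dinucleotide run) around chr2:2520
  substr(seqs[["chr2"]], 2400, 2639) <- strrep("GGCACC", 40)
  mask <- list(chr1 = rep(FALSE, 3000), chr2 = rep(FALSE, 3000))
  mask$chr2[1495:1505] <- TRUE
  ref <- reference_genome(seqs, mask)
  where <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                      pos = c(1000L, 1005L, 2000L, 1500L, 2520L))
  loci <- data.frame(
    chrom = where$chrom, pos = where$pos,
    ref = vapply(seq_len(nrow(where)), function(i)
      substr(seqs[[where$chrom[i]]], where$pos[i], where$pos[i]), character(1)),
    alt = NA_character_)
  loci$alt <- chartr("ACGT", "TGCA", loci$ref)
  geno <- rbind(c("hom_alt", "hom_ref", "hom_ref"),
                c("hom_ref", "het", "hom_ref"),
                c("hom_alt", "hom_ref", "hom_ref"),
                c("hom_ref", "hom_ref", "hom_alt"),
                c("hom_ref", "hom_alt", "hom_ref"))
  m <- genotype_matrix(c("S1", "S2", "S3"), loci, geno,
                       matrix(60L, 5, 3))
  snps <- call_private_snps(m, 50L)
  cand <- apply_marker_criteria(snps, ref, m)
  flag_of <- function(pos) cand$flags[cand$pos == pos]
  expect_match(flag_of(1000), "polymorphic_flank")  # variant 5 bp away
  expect_match(flag_of(1005), "polymorphic_flank")
  expect_match(flag_of(2000), "repetitive")         # A x12 homopolymer
  expect_match(flag_of(1500), "masked")
  expect_match(flag_of(2520), "gc_extreme")
})

test_that("clean unique-anchor candidates pass and rank across chromosomes", {
  truth <- collection28()
  snps <- call_private_snps(truth$matrix, 50L)
  cand <- apply_marker_criteria(snps, truth$reference, truth$matrix)
  # planted flanks are vetted, so nearly all candidates pass
  expect_gt(mean(cand$pass), 0.9)
  expect_true(all(cand$flags[cand$pass] == ""))
  # per strain, the top-ranked picks sit on distinct chromosomes
  for (s in unique(cand$strain)) {
    cc <- cand[cand$strain == s & cand$pass, ]
    k <- min(nrow(cc), 2L)
    if (k >= 2L)
      expect_identical(anyDuplicated(cc$chrom[order(cc$rank)][1:k]), 0L)
  }
  # ranking is deterministic
  cand2 <- apply_marker_criteria(snps, truth$reference, truth$matrix)
  expect_identical(cand, cand2)
})

test_that("criteria reject SNPs at bad coordinates", {
  ref <- reference_genome(c(chr1 = strrep("ACGT", 100)))
  m <- genotype_matrix(c("A", "B"),
                       data.frame(chrom = "chr1", pos = 50L, ref = "A",
                                  alt = "T"),
                       rbind(c("hom_alt", "hom_ref")), matrix(60L, 1, 2))
  snps <- call_private_snps(m, 0L)
  snps$pos <- 9999L
  expect_error(apply_marker_criteria(snps, ref, m), "outside")
})
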