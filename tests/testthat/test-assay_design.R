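# Allele-specific primer/assay design, panels and the thermal protocol.

# one clean designable SNP on a seeded toy reference
design_fixture <- function() {
  if (is.null(.fixture_env$design)) {
    truth <- collection28()
    snps <- call_private_snps(truth$matrix, 50L)
    cands <- apply_marker_criteria(snps, truth$reference, truth$matrix)
    .fixture_env$design <- list(truth = truth, cands = cands[cands$pass, ])
  }
  .fixture_env$design
}

test_that("AS primers carry the allele at -1 and the engineered -2 mismatch", {
  fx <- design_fixture()
  ref <- fx$truth$reference
  cfg <- design_config()
  for (i in 1:4) {
    snp <- fx$cands[i, ]
    seqc <- ref$seq[[snp$chrom]]
    for (dir in c("forward", "reverse")) {
      p_alt <- design_as_primer(ref, snp, "alt", dir, cfg)
      p_ref <- design_as_primer(ref, snp, "ref", dir, cfg)
      L <- nchar(p_alt$sequence)
      # identical footprint; only terminal (-1) base differs between alleles
      expect_identical(c(p_alt$start0, p_alt$end0), c(p_ref$start0, p_ref$end0))
      expect_identical(substr(p_alt$sequence, 1, L - 1),
                       substr(p_ref$sequence, 1, L - 1))
      last <- function(p) substr(p$sequence, L, L)
      if (dir == "forward") {
        expect_identical(last(p_alt), snp$alt)
        expect_identical(last(p_ref), snp$ref)
      } else {
        expect_identical(last(p_alt), chartr("ACGT", "TGCA", snp$alt))
        expect_identical(last(p_ref), chartr("ACGT", "TGCA", snp$ref))
      }
      # -2 base differs from the plain template complement on BOTH haplotypes
      # (ref and alt templates differ only at the SNP itself)
      tpl <- if (dir == "forward") substr(seqc, snp$pos - L + 1, snp$pos)
             else snptracer:::revcomp(substr(seqc, snp$pos, snp$pos + L - 1))
      expect_true(substr(p_alt$sequence, L - 1, L - 1) !=
                    substr(tpl, L - 1, L - 1))
      expect_identical(p_alt$mismatch_offsets, c(-1L, -2L))
      # everything else matches the template
      same <- mapply(function(a, b) a == b,
                     strsplit(p_alt$sequence, "")[[1]],
                     strsplit(tpl, "")[[1]])
      expect_identical(sum(!same), 2L)   # -1 allele + -2 destabilizer
    }
  }
})

test_that("primer design fails cleanly near contig ends and cold flanks", {
  ref <- reference_genome(c(chr1 = strrep("ACGT", 500)))
  snp <- data.frame(strain = "S", chrom = "chr1", pos = 10L, ref = "C",
                    alt = "A", zygosity = "hom_alt")
  expect_error(design_as_primer(ref, snp, "alt", "forward"),
               "insufficient flank")
  # AT-only flank cannot reach the Tm window at any legal length
  at <- reference_genome(c(chr1 = strrep("ATTA", 500)))
  snp2 <- data.frame(strain = "S", chrom = "chr1", pos = 1000L, ref = "A",
                     alt = "C", zygosity = "hom_alt")
  expect_error(design_as_primer(at, snp2, "alt", "forward"),
               "design failure")
  expect_error(design_assay(at, snp2), "design failure|assay design")
})

test_that("designed assays respect the size-gap and product-range contracts", {
  fx <- design_fixture()
  assays <- design_assays(fx$truth$reference, head(fx$cands, 12),
                          matrix = fx$truth$matrix)
  expect_gte(length(assays), 10)
  cfg <- design_config()
  for (a in assays) {
    expect_gte(abs(a$wt_size - a$as_size), cfg$min_size_gap)
    expect_true(all(c(a$wt_size, a$as_size) >= cfg$product_min))
    expect_true(all(c(a$wt_size, a$as_size) <= cfg$product_max))
    # both products contain the SNP position
    for (pair in list(c("as_fwd", "as_rev"), c("wt_fwd", "wt_rev"))) {
      lo <- a[[pair[1]]]$start0; hi <- a[[pair[2]]]$end0
      expect_true(lo < a$snp$pos && a$snp$pos <= hi)
    }
    # converging orientation
    expect_identical(a$as_fwd$strand, "+")
    expect_identical(a$as_rev$strand, "-")
    # product sizes are footprint arithmetic
    expect_identical(a$as_rev$end0 - a$as_fwd$start0, a$as_size)
    expect_identical(a$wt_rev$end0 - a$wt_fwd$start0, a$wt_size)
  }
})

test_that("panels count primers, validate spacing/Tm and reject dimers", {
  fx <- design_fixture()
  panel <- panel_c1()
  expect_identical(panel$primer_count, 12L)          # six assays, 12 primers
  expect_identical(build_multiplex_panel(panel$assays[[1]])$primer_count, 2L)
  tms <- vapply(panel_primers(panel), function(p) p$tm, numeric(1))
  expect_lte(diff(range(tms)), design_config()$tm_spread_max)
  # nine designed assays carry 18 allele-specific primers in total
  nine <- design_assays(fx$truth$reference, head(fx$cands, 12),
                        matrix = fx$truth$matrix)[1:9]
  expect_identical(sum(vapply(nine, function(a)
    length(panel_primers(build_multiplex_panel(list(a)))), integer(1))), 18L)
  # within-strain band separation: two assays 5 bp apart for one strain
  a1 <- panel$assays[[1]]
  a2 <- a1; a2$as_size <- a1$as_size + 5L
  expect_error(build_multiplex_panel(list(a1, a2)), "gel resolution")
  # panel size bounds
  expect_error(build_multiplex_panel(rep(panel$assays[1], 7)), "1 to 6")
  # Tm spread guard
  a3 <- panel$assays[[2]]; a3$as_fwd$tm <- a3$as_fwd$tm + 10
  expect_error(build_multiplex_panel(list(a1, a3)), "Tm spread")
})

test_that("3'-dimer screen detects end-on-end complementarity", {
  expect_true(snptracer:::dimerizes_3prime("ACGTACGTGGCAT", "TTTTTTTTATGCC", 5))
  expect_false(snptracer:::dimerizes_3prime("ACGTACGTGGCAT", "TTTTTTTTTTTTT", 5))
})

test_that("touch-down protocol arithmetic matches its closed form", {
  # default program: 69.5 -> 61.5 by 1 C = 9 touch-down cycles, 34 total
  p <- touchdown_protocol(69.5, 61.5, 1, 25L)
  expect_identical(p$touchdown_cycles, 9L)
  expect_identical(p$total_cycles, 34L)
  expect_equal(p$touchdown$anneal_temp, seq(69.5, 61.5, by = -1))
  expect_true(all(diff(p$touchdown$anneal_temp) < 0))
  # zero-range: one touch-down cycle
  p2 <- touchdown_protocol(60, 60, 1, 10L)
  expect_identical(p2$touchdown_cycles, 1L)
  expect_identical(p2$total_cycles, 11L)
  # step not dividing the range: stop at last temperature >= end
  p3 <- touchdown_protocol(70, 65, 2, 0L)
  expect_equal(p3$touchdown$anneal_temp, c(70, 68, 66))
  expect_identical(p3$total_cycles, 3L)
  # closed form on a grid
  for (st in c(65, 70)) for (en in c(60, 62.5)) for (sp in c(0.5, 1, 2)) {
    p <- touchdown_protocol(st, en, sp, 7L)
    expect_identical(p$touchdown_cycles, as.integer(floor((st - en) / sp)) + 1L)
    expect_identical(p$total_cycles, p$touchdown_cycles + 7L)
  }
  expect_error(touchdown_protocol(60, 65, 1, 5L), "end_temp")
  expect_error(touchdown_protocol(65, 60, 0, 5L), "step")
})
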