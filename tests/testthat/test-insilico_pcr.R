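# In-silico PCR, gel rendering, fingerprints, assignment, tallies.

test_that("the binding rule enforces 3'-terminal identity", {
  tmpl <- paste0(strrep("T", 50), "ACGTACGTACGTACGTACGA", strrep("T", 50))
  # perfect match primer binds; 3' mismatch does not; internal mismatch does
  p_ok <- "ACGTACGTACGTACGTACGA"
  p_3p <- "ACGTACGTACGTACGTACGC"   # terminal mismatch
  p_in <- "ACGTACGTACTTACGTACGA"   # one internal mismatch
  expect_identical(nrow(snptracer:::find_binding_sites(tmpl, p_ok, 1L)), 1L)
  expect_identical(nrow(snptracer:::find_binding_sites(tmpl, p_3p, 1L)), 0L)
  expect_identical(nrow(snptracer:::find_binding_sites(tmpl, p_in, 1L)), 1L)
  expect_identical(nrow(snptracer:::find_binding_sites(tmpl, p_in, 0L)), 0L)
  expect_error(snptracer:::find_binding_sites(tmpl, "ACGT", 0L), "seed")
})

test_that("assay amplicons appear only on allele-carrying templates", {
  truth <- collection28()
  panel <- panel_c1()
  primers <- panel_primers(panel)
  cfg <- sim_config()
  planned <- lapply(panel$assays, function(a)
    c(strain = a$strain, size = a$as_size))
  for (s in c("C1.A", "C1.B", "C1.C", "C1.D")) {
    amps <- predict_amplicons(truth$genomes[[s]], primers, cfg)
    want <- sort(as.integer(vapply(
      panel$assays[vapply(panel$assays, function(a) a$strain == s, logical(1))],
      function(a) a$as_size, integer(1))))
    expect_identical(sort(amps$length), want)
  }
  # strains lacking the target alleles yield no product at all
  for (s in c("C1.E", "C1.F", "C2.A", "U1")) {
    amps <- predict_amplicons(truth$genomes[[s]], primers, cfg)
    expect_identical(nrow(amps), 0L)
  }
  # the AS pair on the reference haplotype gives no amplicon
  amps_ref <- predict_amplicons(truth$reference, primers, cfg)
  expect_identical(nrow(amps_ref), 0L)
})

test_that("unrelated primer pairs never change an assay's product set", {
  truth <- collection28()
  panel <- panel_c1()
  all_primers <- panel_primers(panel)
  own <- panel$assays[[1]]                 # a C1.A assay (4 primers -> 12)
  base <- predict_amplicons(truth$genomes[["C1.A"]],
                            list(F1 = own$as_fwd, R1 = own$as_rev))
  full <- predict_amplicons(truth$genomes[["C1.A"]], all_primers)
  expect_true(all(paste(base$chrom, base$start0, base$end0) %in%
                    paste(full$chrom, full$start0, full$end0)))
  # the added primers contribute no product involving this assay's locus
  at_locus <- full[full$chrom == own$snp$chrom &
                     full$start0 == own$as_fwd$start0, ]
  expect_identical(nrow(at_locus), nrow(base))
})

test_that("gel_pattern merges by single linkage and is idempotent", {
  expect_length(gel_pattern(numeric(0)), 0L)
  expect_equal(as.numeric(gel_pattern(c(300, 310), 25)), 305)
  expect_equal(as.numeric(gel_pattern(c(203, 430), 25)), c(203, 430))
  # single-linkage chain merges transitively
  expect_equal(as.numeric(gel_pattern(c(100, 120, 140), 25)), 120)
  set.seed(41)
  for (i in 1:20) {
    sizes <- sample(100:1200, sample(1:12, 1))
    p <- gel_pattern(sizes, 25)
    expect_equal(as.numeric(gel_pattern(p, 25)), as.numeric(p))
    if (length(p) > 1) expect_true(all(diff(p) >= 25))
  }
})

test_that("inter-delta fingerprints follow planted site arithmetic", {
  set.seed(42)
  bg <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  d12 <- snptracer:::DELTA12; d21 <- snptracer:::DELTA21
  # two convergent sites 400 bp apart (outer edge to outer edge)
  s <- bg
  substr(s, 1001, 1000 + nchar(d12)) <- d12
  substr(s, 1401 - nchar(d21) + 1, 1401) <- snptracer:::revcomp(d21)
  g <- reference_genome(c(chr1 = s))
  expect_equal(as.numeric(interdelta_fingerprint(g)), 401)
  # zero delta sites -> empty pattern
  expect_length(interdelta_fingerprint(reference_genome(c(chr1 = bg))), 0L)
  # identical planted layouts -> identical patterns (determinism)
  expect_identical(interdelta_fingerprint(g), interdelta_fingerprint(g))
})

test_that("fingerprint clustering partitions strains by pattern", {
  pats <- list(a = band_pattern(c(200, 400)), b = band_pattern(c(200, 400)),
               c = band_pattern(300), d = band_pattern(c(200, 401)))
  cls <- cluster_fingerprints(pats, gel_resolution = 25)
  expect_identical(cls[[1]], c("a", "b", "d"))   # 401 matches 400 within 25
  expect_identical(cls[[2]], "c")
  one <- cluster_fingerprints(list(x = band_pattern(100), y = band_pattern(100)))
  expect_length(one, 1L)
})

test_that("colony assignment handles exact, empty, foreign and mixed patterns", {
  panel <- panel_c1()
  sigB <- panel$signatures[["C1.B"]]
  expect_identical(assign_colony(sigB, panel)$call, "C1.B")
  expect_identical(assign_colony(band_pattern(), panel)$call, "unassigned")
  expect_identical(assign_colony(band_pattern(c(999, 1500)), panel)$call,
                   "unassigned")
  mixed <- band_pattern(c(unclass(panel$signatures[["C1.A"]]),
                          unclass(panel$signatures[["C1.C"]])))
  asg <- assign_colony(mixed, panel)
  expect_identical(asg$call, "ambiguous")
  expect_setequal(asg$matched, c("C1.A", "C1.C"))
})

test_that("frequency tallies use round-half-away percentages over all colonies", {
  calls <- c(rep("C1.B", 8), rep("C1.A", 6), rep("U1", 5), rep("U2", 5),
             rep("unassigned", 2))
  grouping <- c(C1.A = "cluster1", C1.B = "cluster1", U1 = "U1", U2 = "U2")
  tl <- tally_frequencies(calls, grouping)
  expect_identical(tl$total, 26L)
  # 14 of 26 cluster-1 colonies -> 54%
  expect_identical(tl$per_cluster$percent[tl$per_cluster$cluster == "cluster1"],
                   54)
  expect_identical(tl$per_strain$percent[tl$per_strain$strain == "C1.B"], 31)
  expect_identical(tally_frequencies(rep("X", 7))$per_strain$percent, 100)
  expect_error(tally_frequencies(character(0)), "no assignments")
  expect_identical(snptracer:::round_half_away(53.5), 54)
  expect_identical(snptracer:::round_half_away(52.5), 53)
})
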