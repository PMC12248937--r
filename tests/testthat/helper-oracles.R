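# Independent oracles and shared fixtures. Oracles are deliberately written
# as naive enumerations, separate from any package code path they check.

# --- brute-force private-SNP oracle ---------------------------------------
# Triple loop over loci and strains, restating the definition verbatim.
oracle_private <- function(m, min_depth) {
  hits <- list()
  for (i in seq_len(nrow(m$loci))) {
    if (nchar(m$loci$ref[i]) != 1L || nchar(m$loci$alt[i]) != 1L) next
    owners <- character(0)
    disqualified <- FALSE
    for (s in m$strains) {
      g <- m$geno[i, s]
      if (g == "missing") disqualified <- TRUE
      if (m$depth[i, s] < min_depth) disqualified <- TRUE
      if (g %in% c("het", "hom_alt")) owners <- c(owners, s)
    }
    if (!disqualified && length(owners) == 1L)
      hits[[length(hits) + 1L]] <- data.frame(
        strain = owners, chrom = m$loci$chrom[i], pos = m$loci$pos[i],
        stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(strain = character(0), chrom = character(0), pos = integer(0))
}

# --- random toy genotype matrices -----------------------------------------
random_toy_matrix <- function(n_strains, n_loci, p_missing = 0.03,
                              indels = FALSE) {
  strains <- paste0("S", seq_len(n_strains))
  alt <- sample(c("C", "G", "T"), n_loci, replace = TRUE)
  ref <- rep("A", n_loci)
  if (indels) {
    ins <- sample(n_loci, max(1L, n_loci %/% 10))
    alt[ins] <- paste0(alt[ins], "T")
  }
  loci <- data.frame(chrom = "chr1", pos = seq_len(n_loci) * 10L,
                     ref = ref, alt = alt)
  geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                        n_loci * n_strains, replace = TRUE,
                        prob = c(0.75, 0.1, 0.1, p_missing)),
                 n_loci, n_strains)
  depth <- matrix(sample(c(30L, 60L, 80L), n_loci * n_strains, replace = TRUE,
                         prob = c(0.1, 0.6, 0.3)), n_loci, n_strains)
  genotype_matrix(strains, loci, geno, depth)
}

# --- hand-summed nearest-neighbor Tm oracle -------------------------------
# Same published unified table, separate code path: explicit per-step loop.
oracle_tm <- function(seq, na_M = 0.05 + 0.120 * sqrt(2.0 - 0.8),
                      ct_M = 0.5e-6) {
  tab <- list(
    AA = c(-7.9, -22.2), TT = c(-7.9, -22.2), AT = c(-7.2, -20.4),
    TA = c(-7.2, -21.3), CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
    GT = c(-8.4, -22.4), AC = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    AG = c(-7.8, -21.0), GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
    CG = c(-10.6, -27.2), GC = c(-9.8, -24.4), GG = c(-8.0, -19.9),
    CC = c(-8.0, -19.9))
  dh <- 0; ds <- 0
  n <- nchar(seq)
  for (i in 1:(n - 1)) {
    v <- tab[[substr(seq, i, i + 1)]]
    dh <- dh + v[1]; ds <- ds + v[2]
  }
  for (i in c(1, n)) {
    if (substr(seq, i, i) %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_M)
  dh * 1000 / (ds + 1.98722 * log(ct_M / 4)) - 273.15
}

# --- tiny VCF writer for parser tests -------------------------------------
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  head <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">')
  writeLines(c(head, lines), path)
  path
}

# --- shared synthetic collections (built once per test run) ---------------
.fixture_env <- new.env(parent = emptyenv())

collection28 <- function() {
  if (is.null(.fixture_env$c28))
    .fixture_env$c28 <- generate_collection(collection_spec(seed = 101L))
  .fixture_env$c28
}

collection_small <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- collection_spec(
      clusters = data.frame(name = c("C1", "C2", "U1"),
                            members = c(3L, 2L, 1L),
                            shared = c(8L, 8L, 0L), layout = 1:3),
      chrom_count = 4L, chrom_len = 30000L, private_range = c(1L, 2L),
      seed = 7L)
    .fixture_env$small <- generate_collection(spec)
  }
  .fixture_env$small
}

# cluster-1 panel on the 28-strain collection (C1.A x2, C1.B x2, C1.C, C1.D)
panel_c1 <- function() {
  if (is.null(.fixture_env$panel)) {
    truth <- collection28()
    snps <- call_private_snps(truth$matrix, 50L)
    cands <- apply_marker_criteria(snps, truth$reference, truth$matrix)
    pick <- function(s, n) head(cands[cands$strain == s & cands$pass, ], n)
    sel <- rbind(pick("C1.A", 2), pick("C1.B", 2), pick("C1.C", 1),
                 pick("C1.D", 1))
    assays <- design_assays(truth$reference, sel, matrix = truth$matrix)
    .fixture_env$panel <- build_multiplex_panel(assays)
  }
  .fixture_env$panel
}
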