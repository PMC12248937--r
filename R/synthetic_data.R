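# Seeded synthetic strain collections.
#
# The generator emulates the structure of a clustered wine-yeast collection:
# a toy reference genome; clusters whose members share a SNP backbone and a
# delta-element layout (so inter-delta fingerprints are identical within a
# cluster and differ between clusters); and per-strain private SNPs planted
# in clean, assay-designable flanks. The default specification mirrors a
# 28-strain collection: one 6-strain cluster, four 2-strain clusters and 14
# singleton strains -- 19 distinct fingerprints, 5 of them multi-strain.
#
# Delta layouts are realized by planting, for every layout, one convergent
# delta-12 / delta-21 site pair (a layout-specific amplicon size) into the
# reference; a strain NOT carrying a layout has each of that layout's sites
# inactivated by a single SNP at the primer's 3'-anchor base. Layout
# membership is therefore encoded purely in SNP records, so the truth VCF
# alone converts the reference into any strain genome (truth round-trip),
# and the genotype matrix stays strictly biallelic-SNP.

#' Specification of a synthetic strain collection
#'
#' @param clusters data.frame with columns `name`, `members`, `shared`
#'   (backbone SNPs per cluster) and `layout` (delta layout id; `NA` = no
#'   delta sites). Default: the 28-strain structure (C1 x 6, C2-C5 x 2,
#'   U1-U14 singletons), 19 layouts.
#' @param chrom_count,chrom_len reference shape (default 10 x 60 kb; a
#'   scaled-down stand-in for the 16-chromosome, 12 Mb yeast genome).
#' @param gc reference GC fraction (default 0.40, close to the yeast genome).
#' @param private_range integer range (lo, hi) of private SNPs per strain.
#' @param depth depth model: `list(model = "constant", value = 60)` (the
#'   default clears the 50x filter) or `list(model = "range", min =, max =)`
#'   for a per-locus/strain uniform draw (low-depth mode exercises filter
#'   rejection).
#' @param seed mandatory integer seed; every draw is derived from it.
#' @return a list of class `collection_spec`.
#' @export
collection_spec <- function(clusters = NULL,
                            chrom_count = 10L, chrom_len = 60000L,
                            gc = 0.40,
                            private_range = c(2L, 4L),
                            depth = list(model = "constant", value = 60L),
                            seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(clusters)) {
    clusters <- data.frame(
      name = c(paste0("C", 1:5), paste0("U", 1:14)),
      members = c(6L, 2L, 2L, 2L, 2L, rep(1L, 14)),
      shared = c(rep(25L, 5), rep(0L, 14)),
      layout = 1:19)
  }
  stopifnot(all(clusters$members >= 1L), all(clusters$shared >= 0L),
            chrom_count >= 1L, chrom_len >= 10000L, gc >= 0, gc <= 1,
            length(private_range) == 2L, private_range[1] >= 0L,
            private_range[2] >= private_range[1])
  structure(list(clusters = clusters, chrom_count = as.integer(chrom_count),
                 chrom_len = as.integer(chrom_len), gc = gc,
                 private_range = as.integer(private_range), depth = depth,
                 seed = as.integer(seed)),
            class = "collection_spec")
}

#' Generate a seeded random reference genome
#'
#' i.i.d. sequence at the target GC fraction, no Ns, deterministic per seed.
#'
#' @param spec a [collection_spec()].
#' @return a [reference_genome()] with chromosomes `chr01`, `chr02`, ...
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "collection_spec"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  seqs <- vapply(seq_len(spec$chrom_count), function(i) {
    paste(sample(DNA_BASES, spec$chrom_len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("chr%02d", seq_len(spec$chrom_count))
  reference_genome(seqs)
}

# deterministic transversion used for planted alternate alleles
ALT_MAP <- c(A = "T", T = "A", C = "G", G = "C")

#' Derive a strain collection (truth set) from a reference
#'
#' Plants delta-site pairs per layout into a copy of the reference, places
#' cluster-backbone and per-strain private SNPs (private positions are
#' vetted for clean, designable flanks), builds every strain genome by
#' applying its carried alternate alleles, and emits the truth genotype
#' matrix with depths from the depth model. Strain names are `<cluster>.<X>`
#' for multi-member clusters (C1.A, C1.B, ...) and the cluster name itself
#' for singletons.
#'
#' @param reference output of [generate_reference()] (the same spec).
#' @param spec the [collection_spec()].
#' @return a list of class `truth_set`: `reference` (the delta-augmented
#'   reference all coordinates refer to), `genomes` (named list of strain
#'   genomes), `matrix` (truth [genotype_matrix()]), `private` (map strain ->
#'   planted private-SNP data.frame), `layout_of` (strain -> layout id),
#'   `cluster_of` (strain -> cluster name), `layout_sizes` (layout id ->
#'   expected inter-delta band size) and `spec`.
#' @export
derive_strains <- function(reference, spec) {
  stopifnot(inherits(reference, "ref_genome"), inherits(spec, "collection_spec"))
  set.seed(spec$seed + 1L)
  seqs <- reference$seq
  nchrom <- length(seqs)
  chroms <- names(seqs)
  cursors <- setNames(rep(500L, nchrom), chroms)
  limit <- vapply(seqs, nchar, integer(1)) - 500L

  alloc <- function(chrom, len, gap) {
    # reserve [cursor + gap, cursor + gap + len) on chrom; NA if full
    at <- cursors[[chrom]] + gap
    if (at + len > limit[[chrom]]) return(NA_integer_)
    cursors[[chrom]] <<- at + len
    at
  }
  alloc_any <- function(len, gap, prefer) {
    order_try <- c(prefer, setdiff(chroms, prefer))
    for (ch in order_try) {
      at <- alloc(ch, len, gap)
      if (!is.na(at)) return(list(chrom = ch, at = at))
    }
    stop("collection spec demands more loci than placeable on the reference")
  }

  # strain roster
  cl <- spec$clusters
  strains <- character(0); cluster_of <- character(0); layout_of <- integer(0)
  for (i in seq_len(nrow(cl))) {
    nm <- if (cl$members[i] == 1L) cl$name[i]
          else paste0(cl$name[i], ".", LETTERS[seq_len(cl$members[i])])
    strains <- c(strains, nm)
    cluster_of <- c(cluster_of, rep(cl$name[i], cl$members[i]))
    layout_of <- c(layout_of, rep(cl$layout[i], cl$members[i]))
  }
  names(cluster_of) <- strains
  names(layout_of) <- strains
  ns <- length(strains)
  if (ns < 2L) stop("need >= 2 strains")

  # --- 1. plant delta layouts (one convergent d12/d21 pair per layout) ----
  layouts <- unique(cl$layout[!is.na(cl$layout)])
  layout_sizes <- setNames(180L + 34L * (seq_along(layouts) - 1L), layouts)
  d21rc <- revcomp(DELTA21)
  k12 <- nchar(DELTA12); k21 <- nchar(DELTA21)
  rec <- list()  # variant records under construction
  for (li in seq_along(layouts)) {
    lay <- layouts[li]
    S <- layout_sizes[[as.character(lay)]]
    loc <- alloc_any(S, gap = 3100L, prefer = chroms[(li - 1L) %% nchrom + 1L])
    ch <- loc$chrom; at <- loc$at                     # 0-based block start
    substr(seqs[[ch]], at + 1L, at + k12) <- DELTA12
    substr(seqs[[ch]], at + S - k21 + 1L, at + S) <- d21rc
    # 3'-anchor positions (1-based): end of d12 motif, start of rc(d21)
    anchors <- c(at + k12, at + S - k21 + 1L)
    for (pos in anchors) {
      refb <- substr(seqs[[ch]], pos, pos)
      carriers <- strains[layout_of[strains] != lay | is.na(layout_of[strains])]
      rec[[length(rec) + 1L]] <- list(chrom = ch, pos = pos, ref = refb,
                                      alt = ALT_MAP[[refb]],
                                      geno = ifelse(strains %in% carriers,
                                                    "hom_alt", "hom_ref"),
                                      kind = "layout")
    }
  }

  aug <- reference_genome(seqs)   # delta-augmented reference

  # --- 2. cluster backbone SNPs --------------------------------------------
  for (i in seq_len(nrow(cl))) {
    if (cl$shared[i] == 0L) next
    members <- strains[cluster_of == cl$name[i]]
    for (j in seq_len(cl$shared[i])) {
      loc <- alloc_any(60L, gap = 40L,
                       prefer = chroms[(i + j - 2L) %% nchrom + 1L])
      pos <- loc$at + 30L
      refb <- substr(seqs[[loc$chrom]], pos, pos)
      zyg <- if (j %% 3L == 0L) "het" else "hom_alt"
      rec[[length(rec) + 1L]] <- list(chrom = loc$chrom, pos = pos, ref = refb,
                                      alt = ALT_MAP[[refb]],
                                      geno = ifelse(strains %in% members, zyg,
                                                    "hom_ref"),
                                      kind = "backbone")
    }
  }

  # --- 3. private SNPs with vetted designable flanks -----------------------
  dcfg <- design_config()
  private <- setNames(vector("list", ns), strains)
  for (si in seq_len(ns)) {
    k <- if (spec$private_range[1] == spec$private_range[2]) spec$private_range[1]
         else sample(spec$private_range[1]:spec$private_range[2], 1L)
    rows <- list()
    for (j in seq_len(k)) {
      loc <- alloc_any(1100L, gap = 3000L,
                       prefer = chroms[(si + j - 2L) %% nchrom + 1L])
      pos <- vet_private_position(seqs[[loc$chrom]], loc$at, dcfg)
      refb <- substr(seqs[[loc$chrom]], pos, pos)
      zyg <- if (j %% 2L == 1L) "hom_alt" else "het"
      geno <- ifelse(strains == strains[si], zyg, "hom_ref")
      rec[[length(rec) + 1L]] <- list(chrom = loc$chrom, pos = pos, ref = refb,
                                      alt = ALT_MAP[[refb]], geno = geno,
                                      kind = "private")
      rows[[j]] <- data.frame(strain = strains[si], chrom = loc$chrom,
                              pos = pos, ref = refb, alt = ALT_MAP[[refb]],
                              zygosity = zyg, stringsAsFactors = FALSE)
    }
    private[[si]] <- do.call(rbind, rows)
  }

  # --- 4. assemble the truth matrix ---------------------------------------
  loci <- data.frame(
    chrom = vapply(rec, `[[`, character(1), "chrom"),
    pos = vapply(rec, `[[`, integer(1), "pos"),
    ref = vapply(rec, `[[`, character(1), "ref"),
    alt = vapply(rec, `[[`, character(1), "alt"))
  geno <- do.call(rbind, lapply(rec, `[[`, "geno"))
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  depth <- draw_depths(spec$depth, nrow(loci), ns)
  matrix <- genotype_matrix(strains, loci, geno, depth)

  # --- 5. strain genomes by applying carried alternate alleles -------------
  genomes <- setNames(vector("list", ns), strains)
  for (si in seq_len(ns)) {
    gseqs <- seqs
    carry <- which(matrix$geno[, si] %in% c("het", "hom_alt"))
    for (ix in carry) {
      ch <- matrix$loci$chrom[ix]; p <- matrix$loci$pos[ix]
      substr(gseqs[[ch]], p, p) <- matrix$loci$alt[ix]
    }
    genomes[[si]] <- reference_genome(gseqs)
  }

  structure(list(reference = aug, genomes = genomes, matrix = matrix,
                 private = private, layout_of = layout_of,
                 cluster_of = cluster_of, layout_sizes = layout_sizes,
                 spec = spec),
            class = "truth_set")
}

#' Generate a complete synthetic collection
#'
#' [generate_reference()] followed by [derive_strains()].
#'
#' @param spec a [collection_spec()].
#' @return a `truth_set`.
#' @export
generate_collection <- function(spec) {
  derive_strains(generate_reference(spec), spec)
}

# Scan offsets inside a private block for a position whose flank is clean
# (no long repeats, moderate GC, N-free) and whose allele-specific forward
# primer can reach the design Tm window. 1-based position returned.
vet_private_position <- function(seqc, block_at, dcfg,
                                 mcfg = marker_config()) {
  foot <- mcfg$max_primer_len + 5L
  for (off in seq(150L, 320L, by = 7L)) {
    pos <- block_at + off
    win <- substr(seqc, pos - foot, pos + foot)
    if (max_homopolymer_run(win) > mcfg$max_homopolymer) next
    if (max_dinuc_units(win) > mcfg$max_dinuc_units) next
    gc <- gc_fraction(substr(seqc, pos - mcfg$gc_window, pos + mcfg$gc_window))
    if (gc < mcfg$gc_min || gc > mcfg$gc_max) next
    if (!tm_window_reachable(seqc, pos, dcfg)) next
    return(pos)
  }
  stop("no designable private-SNP position in block at ", block_at)
}

# TRUE if some forward AS-primer length reaches the Tm window at pos.
tm_window_reachable <- function(seqc, pos, dcfg) {
  refb <- substr(seqc, pos, pos)
  for (l in dcfg$min_len:dcfg$max_len) {
    if (pos - l < 0L) next
    s <- as_primer_sequence(seqc, pos, refb, ALT_MAP[[refb]], "ref",
                            "forward", l, dcfg)
    if (abs(melting_temperature(s, dcfg) - dcfg$tm_target) <= dcfg$tm_tol)
      return(TRUE)
  }
  FALSE
}

draw_depths <- function(depth, nloci, nstrains) {
  if (identical(depth$model, "constant")) {
    matrix(as.integer(depth$value), nloci, nstrains)
  } else if (identical(depth$model, "range")) {
    matrix(sample(depth$min:depth$max, nloci * nstrains, replace = TRUE),
           nloci, nstrains)
  } else stop("unknown depth model")
}

#' Sample colonies from a strain mixture
#'
#' Colonies arise from single plated cells, so each colony is a pure strain;
#' the mixture exists only at the population level. The draw is multinomial
#' with the given proportions.
#'
#' @param genomes named list of strain genomes (e.g. `truth$genomes`).
#' @param proportions numeric vector summing to 1, named by strain (or in
#'   `genomes` order).
#' @param n number of colonies.
#' @param seed integer seed.
#' @return list with `labels` (data.frame `colony`, `strain`) and `genomes`
#'   (named list of colony genomes).
#' @export
sample_colonies <- function(genomes, proportions, n, seed) {
  stopifnot(n >= 1L, length(proportions) >= 1L)
  if (is.null(names(proportions))) {
    stopifnot(length(proportions) <= length(genomes))
    names(proportions) <- names(genomes)[seq_along(proportions)]
  }
  stopifnot(all(names(proportions) %in% names(genomes)),
            abs(sum(proportions) - 1) < 1e-8)
  set.seed(seed)
  draws <- sample(names(proportions), n, replace = TRUE, prob = proportions)
  ids <- sprintf("colony_%02d", seq_len(n))
  list(labels = data.frame(colony = ids, strain = draws,
                           stringsAsFactors = FALSE),
       genomes = setNames(lapply(draws, function(s) genomes[[s]]), ids))
}

#' Write the standard fixture bundle of a truth set
#'
#' Reference FASTA, per-strain genome FASTAs, truth VCF and a strain table
#' TSV (cluster and layout per strain).
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @export
write_fixture_bundle <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(truth$reference, file.path(dir, "reference.fa"))
  for (s in names(truth$genomes))
    write_fasta(truth$genomes[[s]], file.path(dir, paste0(s, ".fa")))
  write_vcf(truth$matrix, file.path(dir, "truth.vcf"),
            contig_lengths = vapply(truth$reference$seq, nchar, integer(1)))
  write_tsv_report(data.frame(strain = names(truth$cluster_of),
                              cluster = unname(truth$cluster_of),
                              layout = unname(truth$layout_of)),
                   file.path(dir, "strains.tsv"))
  invisible(dir)
}
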