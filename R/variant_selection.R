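# Strain-private SNP discovery and marker triage.
#
# A "private" SNP is a biallelic single-nucleotide variant whose alternate
# allele is carried (het or hom_alt) by exactly one strain of the collection.
# To serve as a traceability marker the locus must additionally be covered
# deeply in every strain (absence of the allele elsewhere must be certain)
# and sit in sequence context amenable to allele-specific PCR.

#' Identify strain-private SNPs
#'
#' Scans a genotype matrix for loci where the alternate allele occurs in one
#' strain only (het or hom_alt, both qualify), every strain is genotyped
#' (a missing call disqualifies the locus: it cannot certify absence), every
#' strain has depth >= `min_depth`, and both alleles are single nucleotides
#' (InDels are excluded).
#'
#' @param matrix a [genotype_matrix()].
#' @param min_depth minimum per-strain depth (default 50, the 50x rule).
#' @return data.frame of class `private_snps` with columns `strain`, `chrom`,
#'   `pos`, `ref`, `alt`, `zygosity` (`het`/`hom_alt`) and
#'   `min_depth_across_strains`, ordered by (strain, chrom, pos).
#' @export
call_private_snps <- function(matrix, min_depth = 50L) {
  stopifnot(inherits(matrix, "genotype_matrix"), min_depth >= 0)
  if (length(matrix$strains) < 2L) stop("need >= 2 strains")
  snp <- is_snp_locus(matrix$loci)
  carr <- matrix$geno == "het" | matrix$geno == "hom_alt"
  no_missing <- rowSums(matrix$geno == "missing") == 0L
  deep <- rowSums(matrix$depth >= min_depth) == length(matrix$strains)
  one_carrier <- rowSums(carr) == 1L
  keep <- which(snp & no_missing & deep & one_carrier)
  if (length(keep) == 0L) {
    out <- data.frame(strain = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      zygosity = character(0),
                      min_depth_across_strains = integer(0))
    class(out) <- c("private_snps", "data.frame")
    return(out)
  }
  owner_idx <- apply(carr[keep, , drop = FALSE], 1L, which)
  out <- data.frame(
    strain = matrix$strains[owner_idx],
    chrom = matrix$loci$chrom[keep],
    pos = matrix$loci$pos[keep],
    ref = matrix$loci$ref[keep],
    alt = matrix$loci$alt[keep],
    zygosity = matrix$geno[cbind(keep, owner_idx)],
    min_depth_across_strains = apply(matrix$depth[keep, , drop = FALSE], 1L, min),
    stringsAsFactors = FALSE)
  out <- out[order(out$strain, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("private_snps", "data.frame")
  out
}

#' Apply marker-selection criteria to private SNPs
#'
#' Each SNP becomes a marker candidate carrying zero or more failure flags:
#' \describe{
#'   \item{polymorphic_flank}{another variant of the collection lies within
#'     the primer footprint window `pos +/- (max_primer_len + 5)`.}
#'   \item{repetitive}{the footprint window contains a homopolymer run longer
#'     than `max_homopolymer` or a perfect dinucleotide repeat longer than
#'     `max_dinuc_units` units.}
#'   \item{masked}{soft-masked reference bases inside the footprint window.}
#'   \item{gc_extreme}{GC of the `pos +/- gc_window` flank outside
#'     `[gc_min, gc_max]`.}
#'   \item{non_unique_3prime}{the 3'-terminal `anchor_k`-mer of the would-be
#'     allele-specific primer (reference context ending at the SNP) occurs
#'     more than once in the reference, counting both strands.}
#' }
#' A candidate passes iff it has no flags. Passing candidates are ranked per
#' strain to maximize chromosome dispersion (greedy: the next pick on a
#' not-yet-used chromosome ranks higher), ties broken by (chromosome,
#' position) ascending.
#'
#' @param snps a `private_snps` data.frame from [call_private_snps()].
#' @param reference a [reference_genome()].
#' @param matrix the [genotype_matrix()] the SNPs came from (for the
#'   polymorphic-flank check).
#' @param config a [marker_config()].
#' @return data.frame of class `marker_candidates`: the SNP columns plus
#'   `flags` (comma-separated, "" if passing), `pass` (logical) and `rank`
#'   (integer, 1 = best per strain; `NA` for failing candidates).
#' @export
apply_marker_criteria <- function(snps, reference, matrix,
                                  config = marker_config()) {
  stopifnot(inherits(snps, "data.frame"), inherits(reference, "ref_genome"),
            inherits(matrix, "genotype_matrix"), inherits(config, "marker_config"))
  n <- nrow(snps)
  flags <- vector("list", n)
  foot <- config$max_primer_len + 5L
  for (i in seq_len(n)) {
    f <- character(0)
    chrom <- snps$chrom[i]; pos <- snps$pos[i]
    seqc <- chrom_seq(reference, chrom)
    L <- nchar(seqc)
    if (pos < 1L || pos > L) stop("SNP outside reference coordinates: ",
                                  chrom, ":", pos)
    if (substr(seqc, pos, pos) != snps$ref[i])
      stop("ref allele mismatch at ", chrom, ":", pos)
    # (a1) other variants inside the primer footprint window
    near <- matrix$loci$chrom == chrom &
      abs(matrix$loci$pos - pos) <= foot &
      !(matrix$loci$pos == pos & matrix$loci$alt == snps$alt[i])
    if (any(near)) f <- c(f, "polymorphic_flank")
    # (a2) repeats within the footprint window
    w0 <- max(0L, pos - 1L - foot); w1 <- min(L, pos + foot)
    win <- substr0(seqc, w0, w1)
    if (max_homopolymer_run(win) > config$max_homopolymer ||
        max_dinuc_units(win) > config$max_dinuc_units)
      f <- c(f, "repetitive")
    if (any(reference$mask[[chrom]][(w0 + 1L):w1])) f <- c(f, "masked")
    # (a3) flank GC
    g0 <- max(0L, pos - 1L - config$gc_window)
    g1 <- min(L, pos + config$gc_window)
    gc <- gc_fraction(substr0(seqc, g0, g1))
    if (gc < config$gc_min || gc > config$gc_max) f <- c(f, "gc_extreme")
    # uniqueness of the 3'-anchor k-mer (reference context ending at the SNP)
    k <- config$anchor_k
    if (pos >= k) {
      kmer <- substr(seqc, pos - k + 1L, pos)
      if (count_genome_occurrences(reference, kmer) > 1L)
        f <- c(f, "non_unique_3prime")
    } else f <- c(f, "non_unique_3prime")  # insufficient flank to anchor
    flags[[i]] <- f
  }
  out <- snps
  class(out) <- "data.frame"
  out$flags <- vapply(flags, paste, character(1), collapse = ",")
  out$pass <- lengths(flags) == 0L
  out$rank <- NA_integer_
  for (s in unique(out$strain)) {
    idx <- which(out$strain == s & out$pass)
    if (length(idx)) out$rank[idx] <- rank_by_chromosome_dispersion(out[idx, ])
  }
  out <- out[order(out$strain, !out$pass, out$rank, out$chrom, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_candidates", "data.frame")
  out
}

# Greedy chromosome-dispersion ranking of one strain's passing candidates:
# repeatedly sweep the (chrom, pos)-sorted list, picking at most one
# candidate per chromosome per sweep.
rank_by_chromosome_dispersion <- function(cands) {
  ord <- order(cands$chrom, cands$pos)
  remaining <- ord
  rk <- integer(nrow(cands))
  nxt <- 1L
  while (length(remaining)) {
    used <- character(0)
    taken <- integer(0)
    for (j in remaining) {
      if (!(cands$chrom[j] %in% used)) {
        rk[j] <- nxt; nxt <- nxt + 1L
        used <- c(used, cands$chrom[j])
        taken <- c(taken, j)
      }
    }
    remaining <- setdiff(remaining, taken)
  }
  rk
}

# Exact occurrence count of a k-mer in a genome, both strands.
count_genome_occurrences <- function(genome, kmer) {
  pat <- Biostrings::DNAString(kmer)
  rc <- Biostrings::reverseComplement(pat)
  total <- 0L
  for (chrom in chrom_names(genome)) {
    subj <- Biostrings::DNAString(chrom_seq(genome, chrom))
    total <- total + Biostrings::countPattern(pat, subj)
    if (as.character(rc) != as.character(pat))
      total <- total + Biostrings::countPattern(rc, subj)
  }
  total
}

#' Write a marker-candidate report as TSV
#'
#' @param candidates output of [apply_marker_criteria()].
#' @param path output file.
#' @export
write_candidate_report <- function(candidates, path) {
  cols <- c("strain", "chrom", "pos", "ref", "alt", "zygosity", "flags",
            "pass", "rank")
  write_tsv_report(candidates[, cols], path)
}
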