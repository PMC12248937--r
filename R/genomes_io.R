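# Data model and readers/writers: reference genomes (FASTA), multi-sample
# genotype matrices (VCF), trees (Newick), band patterns, TSV reports.

#' Construct a reference (or strain) genome
#'
#' A genome is an ordered set of named chromosome sequences over the ACGTN
#' alphabet, stored uppercase. Soft-masked (lowercase) input positions are
#' retained as a per-chromosome logical mask so marker triage can flag
#' masked loci.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param mask optional named list of logical vectors (`TRUE` = masked),
#'   one per chromosome, same lengths as the sequences.
#' @return an object of class `ref_genome`.
#' @export
reference_genome <- function(sequences, mask = NULL) {
  if (length(sequences) == 0L) stop("genome has no sequences")
  nms <- names(sequences)
  if (is.null(nms) || any(nms == "" | is.na(nms)))
    stop("all chromosomes must be named")
  if (anyDuplicated(nms)) stop("duplicate chromosome names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  up <- toupper(sequences)
  if (any(nchar(up) == 0L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) stop("non-IUPAC (non-ACGTN) characters in: ",
                     paste(nms[bad], collapse = ", "))
  if (is.null(mask)) {
    mask <- lapply(up, function(s) rep(FALSE, nchar(s)))
    names(mask) <- nms
  } else {
    stopifnot(identical(sort(names(mask)), sort(nms)),
              all(vapply(nms, function(n) length(mask[[n]]) == nchar(up[[n]]),
                         logical(1))))
    mask <- mask[nms]
  }
  structure(list(seq = setNames(as.character(up), nms), mask = mask),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x$seq), " chromosome(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp total\n", sep = "")
  for (n in head(names(x$seq), 10))
    cat("  ", n, ": ", nchar(x$seq[[n]]), " bp\n", sep = "")
  invisible(x)
}

chrom_names <- function(genome) names(genome$seq)
chrom_seq <- function(genome, chrom) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  s
}

#' Read a FASTA file as a genome
#'
#' Sequences are uppercased on load; lowercase (soft-masked) stretches are
#' recorded in the per-position mask.
#'
#' @param path FASTA file.
#' @return a [reference_genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  # FASTA headers: sequence name = first whitespace-delimited token
  nms <- sub("\\s.*$", "", names(raw))
  seqs <- as.character(raw)
  mask <- lapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars %in% c("a", "c", "g", "t", "n")
  })
  names(seqs) <- nms
  names(mask) <- nms
  reference_genome(seqs, mask)
}

#' Write a genome as FASTA
#'
#' @param genome a `ref_genome`.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genotype matrix

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a strains x loci genotype matrix
#'
#' The container for multi-strain biallelic variant calls: a locus table
#' (chromosome, 1-based position, ref and alt alleles) plus genotype-class
#' and depth matrices with one row per locus and one column per strain.
#'
#' @param strains character vector of strain names (>= 2).
#' @param loci data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param geno character matrix (loci x strains) with values
#'   `hom_ref`, `het`, `hom_alt` or `missing`.
#' @param depth non-negative integer matrix (loci x strains).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(strains, loci, geno, depth) {
  strains <- as.character(strains)
  if (length(strains) < 2L) stop("a genotype matrix needs >= 2 strains")
  if (anyDuplicated(strains)) stop("duplicate strain names")
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  n <- nrow(loci)
  geno <- matrix(as.character(geno), nrow = n, ncol = length(strains),
                 dimnames = list(NULL, strains))
  depth <- matrix(as.integer(depth), nrow = n, ncol = length(strains),
                  dimnames = list(NULL, strains))
  if (!all(geno %in% GT_LEVELS)) stop("invalid genotype class")
  if (any(depth < 0, na.rm = TRUE)) stop("negative depth")
  loci <- data.frame(chrom = as.character(loci$chrom),
                     pos = as.integer(loci$pos),
                     ref = as.character(loci$ref),
                     alt = as.character(loci$alt),
                     stringsAsFactors = FALSE)
  structure(list(strains = strains, loci = loci, geno = geno, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$loci), " loci x ", length(x$strains),
      " strains\n", sep = "")
  invisible(x)
}

n_loci <- function(m) nrow(m$loci)

# TRUE where the strain carries the alt allele (het or hom_alt).
carrier_matrix <- function(m) {
  carr <- m$geno == "het" | m$geno == "hom_alt"
  carr[m$geno == "missing"] <- NA
  carr
}

is_snp_locus <- function(loci) nchar(loci$ref) == 1L & nchar(loci$alt) == 1L

#' Read a multi-sample VCF into a genotype matrix
#'
#' Requires per-sample `GT` and `DP`. Multiallelic records are split into one
#' biallelic record per alternate allele (a genotype is `het`/`hom_alt` with
#' respect to that allele, `hom_ref` otherwise, `missing` if any GT allele is
#' missing). Records with symbolic alternate alleles (`<...>`), breakends or
#' `*` alleles are dropped. By default only records with FILTER `PASS` or `.`
#' are loaded.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_subset optional character vector of samples to load.
#' @param keep_filtered load records regardless of the FILTER column.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL, keep_filtered = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  param <- if (is.null(sample_subset)) VariantAnnotation::ScanVcfParam()
           else VariantAnnotation::ScanVcfParam(samples = sample_subset)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown",
                                                param = param)),
    error = function(e) stop("failed to read VCF (", conditionMessage(e), ")"))
  samples <- colnames(vcf)
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s))
      stop("samples absent from VCF header: ", paste(missing_s, collapse = ", "))
    samples <- sample_subset
  }
  g <- VariantAnnotation::geno(vcf)
  if (!all(c("GT", "DP") %in% names(g)))
    stop("VCF must carry GT and DP FORMAT fields")
  gt <- g$GT[, samples, drop = FALSE]
  dp <- g$DP[, samples, drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)  # DNAStringSetList (one set per record)
  filt <- VariantAnnotation::filt(vcf)
  keep_rec <- keep_filtered | filt %in% c("PASS", ".") | is.na(filt)

  out_chrom <- character(0); out_pos <- integer(0)
  out_ref <- character(0); out_alt <- character(0)
  out_geno <- list(); out_depth <- list()

  for (i in seq_along(chroms)) {
    if (!keep_rec[i]) next
    a_all <- as.character(alts[[i]])
    gts <- gt[i, ]
    dps <- suppressWarnings(as.integer(dp[i, ]))
    dps[is.na(dps)] <- 0L
    for (k in seq_along(a_all)) {
      a <- a_all[k]
      if (grepl("[<>\\[\\]*]", a) || a == "" || grepl("[^ACGTNacgtn]", a)) next
      cls <- vapply(gts, classify_gt, character(1), allele_index = k)
      out_chrom <- c(out_chrom, chroms[i]); out_pos <- c(out_pos, pos[i])
      out_ref <- c(out_ref, toupper(refs[i])); out_alt <- c(out_alt, toupper(a))
      out_geno[[length(out_geno) + 1L]] <- cls
      out_depth[[length(out_depth) + 1L]] <- dps
    }
  }
  if (length(out_chrom) == 0L)
    stop("no usable biallelic records in ", path)
  genotype_matrix(samples,
                  data.frame(chrom = out_chrom, pos = out_pos,
                             ref = out_ref, alt = out_alt),
                  do.call(rbind, out_geno),
                  do.call(rbind, out_depth))
}

# Map one VCF GT string to a genotype class w.r.t. alternate allele k.
classify_gt <- function(gt, allele_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) == 0L || any(alleles == ".")) return("missing")
  if (grepl("[^0-9.]", gsub("[/|]", "", gt))) stop("malformed GT: ", gt)
  ai <- suppressWarnings(as.integer(alleles))
  if (any(is.na(ai))) stop("malformed GT: ", gt)
  nalt <- sum(ai == allele_index)
  if (nalt == 0L) "hom_ref" else if (nalt == length(ai)) "hom_alt" else "het"
}

#' Re-emit a genotype matrix as a minimal VCF 4.2 file
#'
#' Writes records with GT and DP per sample (used for fixture bundles and
#' filtered-subset re-emission; this is not a general-purpose VCF writer).
#' Zygosity is encoded as `0/0`, `0/1`, `1/1` or `./.`.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file.
#' @param contig_lengths optional named integer vector for `##contig` lines.
#' @export
write_vcf <- function(matrix, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=snptracer",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", matrix$strains), collapse = "\t"), con)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  for (i in seq_len(n_loci(matrix))) {
    fields <- paste0(gt_code[matrix$geno[i, ]], ":", matrix$depth[i, ])
    writeLines(paste(c(matrix$loci$chrom[i], matrix$loci$pos[i], ".",
                       matrix$loci$ref[i], matrix$loci$alt[i], ".", "PASS",
                       ".", "GT:DP", fields), collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Band patterns

#' Construct a band pattern
#'
#' A band pattern is the multiset of amplicon sizes resolved in one gel lane,
#' stored as an ascending numeric vector. It is the unit of fingerprint
#' comparison and colony assignment.
#'
#' @param sizes numeric vector of band sizes (bp), all positive.
#' @return a sorted numeric vector of class `band_pattern`.
#' @export
band_pattern <- function(sizes = numeric(0)) {
  sizes <- as.numeric(sizes)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) stop("band sizes must be positive")
  structure(sort(sizes), class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  if (length(x) == 0) cat("<band_pattern> (no bands)\n")
  else cat("<band_pattern> ", paste(round(unclass(x), 1), collapse = ", "),
           " bp\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Newick I/O (via ape, with a strict label dialect)

NEWICK_LABEL_RE <- "^[A-Za-z0-9_.-]+$"

#' Write a phylogenetic tree to a Newick file
#'
#' Labels are restricted to `[A-Za-z0-9_.-]` so that write/read round-trips
#' are unambiguous; any other label is rejected.
#'
#' @param tree an `ape` `phylo` object with branch lengths.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("duplicate leaf labels")
  bad <- !grepl(NEWICK_LABEL_RE, labs)
  if (any(bad)) stop("labels outside the [A-Za-z0-9_.-] Newick dialect: ",
                     paste(labs[bad], collapse = ", "))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path Newick file.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse Newick file: ", path)
  tr
}

# ---------------------------------------------------------------------------
# TSV report writers

write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
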