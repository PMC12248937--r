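# Pairwise unshared-variant distances and neighbor-joining.
#
# The distance between two strains is the number of loci at which exactly one
# of them carries the alternate allele (allele-presence XOR: het and hom_alt
# both count as "carries"). This matches the allele-presence semantics of
# allele-specific PCR; a strict-genotype mode (het vs hom_alt counted as
# different) is available.

#' Count unshared variants between every strain pair
#'
#' @param matrix a [genotype_matrix()] of biallelic SNPs.
#' @param mode `"presence"` (default): loci count if exactly one strain of
#'   the pair carries the alt allele. `"genotype"`: loci count if the two
#'   genotype classes differ.
#' @return list of class `dist_matrix` with `strains` and the symmetric
#'   integer matrix `d`. Loci with a missing call in either strain are
#'   skipped for that pair. An empty record list yields an all-zero matrix
#'   with a warning.
#' @export
pairwise_unshared <- function(matrix, mode = c("presence", "genotype")) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  mode <- match.arg(mode)
  ns <- length(matrix$strains)
  d <- matrix(0L, ns, ns, dimnames = list(matrix$strains, matrix$strains))
  if (n_loci(matrix) == 0L) {
    warning("genotype matrix has no records; distances are all zero")
  } else {
    if (mode == "presence") {
      val <- carrier_matrix(matrix)           # logical with NA for missing
    } else {
      val <- matrix$geno
      val[val == "missing"] <- NA
    }
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        ok <- !is.na(val[, i]) & !is.na(val[, j])
        dij <- sum(val[ok, i] != val[ok, j])
        d[i, j] <- d[j, i] <- as.integer(dij)
      }
    }
  }
  structure(list(strains = matrix$strains, d = d), class = "dist_matrix")
}

#' Construct a distance-matrix object
#'
#' @param d symmetric numeric matrix with zero diagonal; row/column names are
#'   the strain names.
#' @return a `dist_matrix`.
#' @export
dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs strain names")
  check_dist(d)
  structure(list(strains = rownames(d), d = d), class = "dist_matrix")
}

check_dist <- function(d) {
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8,
                                              check.attributes = FALSE)))
    stop("distance matrix must be square and symmetric")
  if (any(d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  invisible(TRUE)
}

#' Write a distance matrix as square TSV
#' @param dm a `dist_matrix`.
#' @param path output file.
#' @export
write_dist_tsv <- function(dm, path) {
  df <- data.frame(strain = dm$strains, dm$d, check.names = FALSE)
  write_tsv_report(df, path)
}

#' Read a distance matrix from TSV (square or PHYLIP-style lower triangle)
#'
#' Square TSV as written by [write_dist_tsv()]; alternatively a PHYLIP-style
#' file whose first line is the taxon count, followed by `name d1 d2 ...`
#' lower-triangle rows.
#'
#' @param path input file.
#' @return a `dist_matrix`.
#' @export
read_dist_tsv <- function(path) {
  first <- trimws(readLines(path, n = 1L))
  if (grepl("^[0-9]+$", first)) {                      # PHYLIP lower triangle
    n <- as.integer(first)
    lines <- readLines(path)[-1L]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != n) stop("PHYLIP matrix: expected ", n, " rows")
    nms <- character(n)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      nms[i] <- tok[1]
      vals <- as.numeric(tok[-1])
      if (length(vals) != i - 1L) stop("PHYLIP matrix: bad row ", i)
      if (i > 1L) { d[i, 1:(i - 1L)] <- vals; d[1:(i - 1L), i] <- vals }
    }
    dimnames(d) <- list(nms, nms)
    return(dist_matrix(d))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  storage.mode(d) <- "double"
  dist_matrix(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing `Q(i, j) = (N - 2) d(i, j) - r_i - r_j`, attach the pair with
#' the standard branch-length formulas, and reduce the matrix with
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. Ties in Q are broken by the
#' smallest (i, j) index pair; negative branch lengths are clamped to zero.
#' Exact on additive (four-point-condition) matrices.
#'
#' @param dm a `dist_matrix` (or plain symmetric named matrix) with n >= 2.
#' @return an unrooted `ape` `phylo` tree with branch lengths. For n = 2 the
#'   two leaves are joined by a single edge split as d/2 + d/2; for n = 3 the
#'   (unique) star topology is returned.
#' @export
neighbor_joining <- function(dm) {
  if (!inherits(dm, "dist_matrix")) dm <- dist_matrix(dm)
  check_dist(dm$d)
  labs <- dm$strains
  n <- length(labs)
  if (n < 2L) stop("need >= 2 taxa")
  bad <- !grepl(NEWICK_LABEL_RE, labs)
  if (any(bad)) stop("taxon labels outside [A-Za-z0-9_.-]: ",
                     paste(labs[bad], collapse = ", "))
  if (n == 2L) {
    h <- dm$d[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         labs[1], h, labs[2], h)))
  }
  d <- dm$d
  nodes <- as.list(labs)          # newick fragment per active node
  repeat {
    N <- length(nodes)
    if (N == 3L) break
    r <- rowSums(d)
    best <- NULL; bestq <- Inf
    for (i in seq_len(N - 1L)) {
      for (j in (i + 1L):N) {
        q <- (N - 2) * d[i, j] - r[i] - r[j]
        if (q < bestq - 1e-9) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (N - 2))
    vj <- d[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newick <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], vi, nodes[[j]], vj)
    keep <- setdiff(seq_len(N), c(i, j))
    dnew <- 0.5 * (d[i, keep] + d[j, keep] - d[i, j])
    dnew <- pmax(dnew, 0)
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, dnew), c(dnew, 0))
    nodes <- c(nodes[keep], list(newick))
  }
  # final trifurcation: pendant lengths from the three-point formulas
  v1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[1]], v1, nodes[[2]], v2, nodes[[3]], v3)
  ape::read.tree(text = txt)
}
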