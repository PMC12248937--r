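# Allele-specific (ARMS) primer and assay design.
#
# Per validated private SNP the designer builds two primer pairs sharing one
# allele-specific footprint whose 3'-terminal base sits on the SNP: a
# wild-type pair (3' base = reference allele) and a variant pair (3' base =
# alternate allele). Both allele-specific primers additionally carry an
# engineered destabilizing mismatch at position -2 from the 3' end, which
# sharpens terminal-base discrimination. The two conventional mates are
# placed so the wild-type and variant products differ by >= 200 bp, making
# the allele call readable from band size on a gel.

#' Construct a primer object
#'
#' @param sequence 5'->3' sequence as synthesized.
#' @param chrom template chromosome.
#' @param start0,end0 binding footprint on the template, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param allele_specific logical flag.
#' @param mismatch_offsets offsets from the 3' end where the primer departs
#'   from plain template complementarity (-1 = terminal allele base,
#'   -2 = engineered destabilizer); empty for conventional primers.
#' @param tm melting temperature (Celsius).
#' @return an object of class `primer`.
#' @export
primer <- function(sequence, chrom, start0, end0, strand, allele_specific,
                   mismatch_offsets = integer(0), tm = NA_real_) {
  stopifnot(strand %in% c("+", "-"), end0 - start0 == nchar(sequence))
  structure(list(sequence = toupper(sequence), chrom = chrom,
                 start0 = as.integer(start0), end0 = as.integer(end0),
                 strand = strand, allele_specific = isTRUE(allele_specific),
                 mismatch_offsets = as.integer(mismatch_offsets), tm = tm),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> 5'-%s-3' (%d nt, %s%s, %s:%d-%d, Tm %.1f C)\n",
              x$sequence, nchar(x$sequence),
              if (x$allele_specific) "AS, " else "", x$strand,
              x$chrom, x$start0, x$end0, x$tm))
  invisible(x)
}

# Engineered -2 base: keyed on the base of the strand the primer anneals to,
# giving a deliberate non-Watson-Crick pairing (A.A, C.C, T.T; A.G for
# template G). Always differs from the Watson-Crick choice.
destab_base <- function(annealing_base, config) {
  d <- config$mismatch_table[[annealing_base]]
  if (is.null(d)) stop("no -2 substitution for template base ", annealing_base)
  d
}

#' Design one allele-specific primer for a SNP
#'
#' The primer's 3'-terminal base sits on the SNP and equals the chosen
#' allele; the base at offset -2 is replaced by the destabilizing
#' substitution. Primer length (within `min_len..max_len`) is chosen to
#' bring the Tm closest to `tm_target`; the choice is made on the shared
#' reference-allele context so the wild-type and variant primers of one SNP
#' always have identical footprints. Design fails (error) if no length lands
#' within `tm_target +/- tm_tol`.
#'
#' @param reference a [reference_genome()].
#' @param snp one row of a `private_snps` data.frame (fields `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param allele `"alt"` (variant-specific) or `"ref"` (wild-type-specific).
#' @param direction `"forward"` (+ strand, product extends downstream) or
#'   `"reverse"` (- strand, product extends upstream).
#' @param config a [design_config()].
#' @return a [primer()] with `mismatch_offsets = c(-1L, -2L)`.
#' @export
design_as_primer <- function(reference, snp, allele = c("alt", "ref"),
                             direction = c("forward", "reverse"),
                             config = design_config()) {
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  chrom <- as.character(snp$chrom); pos <- as.integer(snp$pos)
  seqc <- chrom_seq(reference, chrom)
  L <- nchar(seqc)
  if (substr(seqc, pos, pos) != snp$ref)
    stop("ref allele mismatch at ", chrom, ":", pos)
  build <- function(len, which_allele) {
    as_primer_sequence(seqc, pos, snp$ref, snp$alt, which_allele, direction,
                       len, config)
  }
  lens <- config$min_len:config$max_len
  feasible <- if (direction == "forward") lens[pos - lens >= 0]
              else lens[pos - 1L + lens <= L]
  if (length(feasible) == 0L) stop("insufficient flank for AS primer at ",
                                   chrom, ":", pos)
  # length selection on the ref-allele context (shared by both primers)
  tms <- vapply(feasible, function(l) melting_temperature(build(l, "ref"), config),
                numeric(1))
  dev <- abs(tms - config$tm_target)
  if (min(dev) > config$tm_tol)
    stop(sprintf("AS primer design failure at %s:%d (%s): no length in %d-%d reaches Tm %.1f +/- %.1f",
                 chrom, pos, direction, config$min_len, config$max_len,
                 config$tm_target, config$tm_tol))
  len <- feasible[which.min(dev)]
  seq_out <- build(len, allele)
  if (direction == "forward") {
    primer(seq_out, chrom, pos - len, pos, "+", TRUE, c(-1L, -2L),
           melting_temperature(seq_out, config))
  } else {
    primer(seq_out, chrom, pos - 1L, pos - 1L + len, "-", TRUE, c(-1L, -2L),
           melting_temperature(seq_out, config))
  }
}

# Assemble the synthesized AS-primer sequence for one (allele, direction).
as_primer_sequence <- function(seqc, pos, ref, alt, allele, direction, len,
                               config) {
  allele_base <- if (allele == "alt") alt else ref
  if (direction == "forward") {
    chars <- strsplit(substr(seqc, pos - len + 1L, pos), "", fixed = TRUE)[[1]]
    chars[len] <- allele_base
    # -2 position: primer anneals to the minus strand; annealing base there
    # is the complement of the plus-strand base
    t_base <- comp_base(chars[len - 1L])
    chars[len - 1L] <- destab_base(t_base, config)
    paste(chars, collapse = "")
  } else {
    top <- strsplit(substr(seqc, pos, pos - 1L + len), "", fixed = TRUE)[[1]]
    top[1L] <- allele_base
    p <- rev(comp_base(top))                       # primer 5'->3'
    # -2 position anneals to the plus strand base just right of the SNP
    t_base <- substr(seqc, pos + 1L, pos + 1L)
    p[len - 1L] <- destab_base(t_base, config)
    paste(p, collapse = "")
  }
}

# Conventional mate with a fixed product boundary: the footprint's outer end
# is pinned (so the product size is exact) and the length is chosen by Tm.
# Returns NULL (with attribute "reason") instead of erroring, so callers can
# scan placements.
design_conventional_primer <- function(reference, chrom, boundary0, strand,
                                       config, matrix = NULL) {
  seqc <- chrom_seq(reference, chrom)
  L <- nchar(seqc)
  lens <- config$min_len:config$max_len
  feasible <- if (strand == "-") lens[boundary0 - lens >= 0]
              else lens[boundary0 + lens <= L]
  if (length(feasible) == 0L) return(NULL)
  best <- NULL; bestdev <- Inf
  for (l in feasible) {
    if (strand == "-") { s0 <- boundary0 - l; e0 <- boundary0 }
    else { s0 <- boundary0; e0 <- boundary0 + l }
    foot <- substr0(seqc, s0, e0)
    if (grepl("N", foot, fixed = TRUE)) next
    pseq <- if (strand == "-") revcomp(foot) else foot
    tm <- melting_temperature(pseq, config)
    dev <- abs(tm - config$tm_target)
    if (dev <= config$tm_tol && dev < bestdev) {
      bestdev <- dev
      best <- primer(pseq, chrom, s0, e0, strand, FALSE, integer(0), tm)
    }
  }
  if (is.null(best)) return(NULL)
  if (!footprint_clear(reference, matrix, chrom, best$start0, best$end0))
    return(NULL)
  best
}

# Footprint acceptability: unique in the reference (exact full-length match,
# both strands) and free of known variants other than an allowed position.
footprint_clear <- function(reference, matrix, chrom, s0, e0, allow_pos = NA) {
  foot <- substr0(chrom_seq(reference, chrom), s0, e0)
  if (count_genome_occurrences(reference, foot) != 1L) return(FALSE)
  if (!is.null(matrix)) {
    hit <- matrix$loci$chrom == chrom & matrix$loci$pos > s0 &
      matrix$loci$pos <= e0
    if (!is.na(allow_pos)) hit <- hit & matrix$loci$pos != allow_pos
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Design a complete allele-specific assay for one SNP
#'
#' Builds the shared allele-specific footprint (forward on the + strand
#' first; if that fails the Tm window, retried as reverse on the - strand),
#' then scans conventional-mate placements so that the variant product size
#' lies in `[product_min, product_max]` (starting at `as_size_min`) and the
#' wild-type product differs from it by at least `min_size_gap` while staying
#' inside the same range. All four footprints must be unique in the
#' reference and, when `matrix` is given, free of known variants other than
#' the target SNP.
#'
#' @param reference a [reference_genome()].
#' @param snp one row of a `private_snps`/`marker_candidates` data.frame.
#' @param config a [design_config()].
#' @param matrix optional [genotype_matrix()] for variant-collision checks.
#' @param as_size_min smallest variant-product size to consider; staggering
#'   this across assays yields the distinct band sizes a multiplex panel
#'   needs (see [design_assays()]).
#' @return an object of class `as_assay`: `snp`, `wt_fwd`, `wt_rev`,
#'   `as_fwd`, `as_rev` primers, `wt_size`, `as_size` and `strain`.
#'   Errors with a reason if no placement satisfies the constraints.
#' @export
design_assay <- function(reference, snp, config = design_config(),
                         matrix = NULL, as_size_min = NULL) {
  as_size_min <- as.integer(as_size_min %||% config$product_min)
  stopifnot(as_size_min >= config$product_min)
  chrom <- as.character(snp$chrom); pos <- as.integer(snp$pos)
  for (direction in c("forward", "reverse")) {
    as_p <- tryCatch(design_as_primer(reference, snp, "alt", direction, config),
                     error = function(e) NULL)
    if (is.null(as_p)) next
    if (!footprint_clear(reference, matrix, chrom, as_p$start0, as_p$end0,
                         allow_pos = pos)) next
    wt_p <- design_as_primer(reference, snp, "ref", direction, config)
    # scan variant-product sizes, then wild-type sizes
    for (S_as in as_size_min:config$product_max) {
      mate_as <- mate_at_size(reference, as_p, S_as, config, matrix)
      if (is.null(mate_as)) next
      S_wt <- NULL; mate_wt <- NULL
      up <- if (S_as + config$min_size_gap <= config$product_max)
        seq.int(S_as + config$min_size_gap, config$product_max) else integer(0)
      down <- if (S_as - config$min_size_gap >= config$product_min)
        seq.int(S_as - config$min_size_gap, config$product_min) else integer(0)
      for (S in c(up, down)) {
        m <- mate_at_size(reference, wt_p, S, config, matrix)
        if (!is.null(m)) { S_wt <- S; mate_wt <- m; break }
      }
      if (is.null(S_wt)) next
      out <- structure(list(
        snp = as.data.frame(snp)[, c("strain", "chrom", "pos", "ref", "alt",
                                     "zygosity")],
        strain = as.character(snp$strain),
        wt_fwd = if (direction == "forward") wt_p else mate_wt,
        wt_rev = if (direction == "forward") mate_wt else wt_p,
        as_fwd = if (direction == "forward") as_p else mate_as,
        as_rev = if (direction == "forward") mate_as else as_p,
        wt_size = as.integer(S_wt), as_size = as.integer(S_as)),
        class = "as_assay")
      return(out)
    }
  }
  stop(sprintf("assay design failure at %s:%d: no placement satisfies the Tm window and size constraints",
               chrom, pos))
}

# Conventional mate achieving an exact product size with an AS primer.
mate_at_size <- function(reference, as_primer, size, config, matrix) {
  if (as_primer$strand == "+") {
    boundary0 <- as_primer$start0 + size     # product = [as start, boundary)
    if (boundary0 - size < 0) return(NULL)
    design_conventional_primer(reference, as_primer$chrom, boundary0, "-",
                               config, matrix)
  } else {
    boundary0 <- as_primer$end0 - size       # product = [boundary, as end)
    if (boundary0 < 0) return(NULL)
    design_conventional_primer(reference, as_primer$chrom, boundary0, "+",
                               config, matrix)
  }
}

#' @export
print.as_assay <- function(x, ...) {
  cat(sprintf("<as_assay> %s %s:%d %s>%s | variant product %d bp, wild-type %d bp\n",
              x$strain, x$snp$chrom, x$snp$pos, x$snp$ref, x$snp$alt,
              x$as_size, x$wt_size))
  invisible(x)
}

#' Design assays for several SNPs with staggered product sizes
#'
#' Convenience wrapper calling [design_assay()] per SNP with
#' `as_size_min = product_min + (i - 1) * stagger`, so every assay lands on a
#' distinct variant-product size (the paper's criterion (d): fragments
#' distinguishable on a gel). SNPs whose design fails are reported and
#' skipped.
#'
#' @param reference a [reference_genome()].
#' @param snps `private_snps`/`marker_candidates` data.frame (one assay per
#'   row attempted, in row order).
#' @param config a [design_config()].
#' @param matrix optional [genotype_matrix()].
#' @param stagger spacing (bp) between consecutive assays' minimum variant
#'   product sizes.
#' @return list of `as_assay` objects; failures are attached as attribute
#'   `"failures"` (data.frame of chrom, pos, reason).
#' @export
design_assays <- function(reference, snps, config = design_config(),
                          matrix = NULL, stagger = 40L) {
  assays <- list()
  fail <- data.frame(chrom = character(0), pos = integer(0),
                     reason = character(0))
  slot <- 0L
  for (i in seq_len(nrow(snps))) {
    smin <- config$product_min + slot * stagger
    if (smin + config$min_size_gap > config$product_max) smin <- config$product_min
    res <- tryCatch(design_assay(reference, snps[i, ], config, matrix,
                                 as_size_min = smin),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fail <- rbind(fail, data.frame(chrom = snps$chrom[i], pos = snps$pos[i],
                                     reason = res))
    } else {
      assays[[length(assays) + 1L]] <- res
      slot <- slot + 1L
    }
  }
  attr(assays, "failures") <- fail
  assays
}

# ---------------------------------------------------------------------------
# Multiplex panels

#' Assemble a multiplex panel from designed assays
#'
#' Only the variant-specific (AS) pairs enter the reaction, so
#' `primer_count = 2 * n_assays` (2 to 12 primers, i.e. 1 to 6 assays).
#' The panel is validated for: melting-temperature spread across all primers
#' `<= tm_spread_max`; within-strain expected band separation
#' `>= gel_resolution`; and absence of 3'-end cross-complementarity runs of
#' `dimer_max` or more bases between any two primers (potential
#' primer-dimers). Any violation rejects the panel, naming the offending
#' pair.
#'
#' @param assays list of `as_assay` objects (1 to 6).
#' @param config a [design_config()].
#' @param protocol a [touchdown_protocol()]; defaults to the standard
#'   touch-down program.
#' @return an object of class `multiplex_panel` with `assays`,
#'   `primer_count`, `signatures` (named list: strain -> expected
#'   [band_pattern()]) and `protocol`.
#' @export
build_multiplex_panel <- function(assays, config = design_config(),
                                  protocol = touchdown_protocol()) {
  if (inherits(assays, "as_assay")) assays <- list(assays)
  n <- length(assays)
  if (n < 1L || n > 6L)
    stop("a panel holds 1 to 6 assays (2 to 12 primers); got ", n)
  stopifnot(all(vapply(assays, inherits, logical(1), "as_assay")))
  primers <- unlist(lapply(assays, function(a) list(a$as_fwd, a$as_rev)),
                    recursive = FALSE)
  tms <- vapply(primers, function(p) p$tm, numeric(1))
  if (diff(range(tms)) > config$tm_spread_max)
    stop(sprintf("panel rejected: Tm spread %.2f C exceeds %.2f C",
                 diff(range(tms)), config$tm_spread_max))
  # primer-dimer screen
  seqs <- vapply(primers, function(p) p$sequence, character(1))
  for (i in seq_along(seqs)) {
    for (j in i:length(seqs)) {
      if (dimerizes_3prime(seqs[i], seqs[j], config$dimer_max))
        stop(sprintf("panel rejected: 3' cross-complementarity (>= %d nt) between primers %d and %d",
                     config$dimer_max, i, j))
    }
  }
  strains <- vapply(assays, function(a) a$strain, character(1))
  sizes <- vapply(assays, function(a) a$as_size, integer(1))
  signatures <- lapply(split(sizes, strains), band_pattern)
  for (s in names(signatures)) {
    b <- signatures[[s]]
    if (length(b) > 1L && any(diff(b) < config$gel_resolution))
      stop(sprintf("panel rejected: bands %s closer than the %d bp gel resolution for strain %s",
                   paste(round(unclass(b)), collapse = "/"),
                   config$gel_resolution, s))
  }
  structure(list(assays = assays, primer_count = 2L * n,
                 signatures = signatures, protocol = protocol),
            class = "multiplex_panel")
}

# TRUE if the two primers' 3' ends can anneal to each other: the 3'-terminal
# k bases of a are the reverse complement of the 3'-terminal k bases of b
# (the extensible end-on-end dimer that wrecks a multiplex reaction).
dimerizes_3prime <- function(a, b, k) {
  if (k <= 0) return(FALSE)
  ta <- substr(a, nchar(a) - k + 1L, nchar(a))
  tb <- substr(b, nchar(b) - k + 1L, nchar(b))
  identical(ta, revcomp(tb))
}

#' @export
print.multiplex_panel <- function(x, ...) {
  cat(sprintf("<multiplex_panel> %d assay(s), %d primers, %d strain signature(s)\n",
              length(x$assays), x$primer_count, length(x$signatures)))
  for (s in names(x$signatures))
    cat("  ", s, ": ", paste(round(unclass(x$signatures[[s]])), collapse = ", "),
        " bp\n", sep = "")
  invisible(x)
}

#' All allele-specific primers of a panel
#'
#' @param panel a `multiplex_panel`.
#' @return named list of [primer()]s (`<strain>.<i>.F` / `.R`).
#' @export
panel_primers <- function(panel) {
  out <- list()
  for (i in seq_along(panel$assays)) {
    a <- panel$assays[[i]]
    out[[sprintf("%s.%d.F", a$strain, i)]] <- a$as_fwd
    out[[sprintf("%s.%d.R", a$strain, i)]] <- a$as_rev
  }
  out
}

#' Write a panel report as TSV
#'
#' One row per assay: strain, locus, primer sequences 5'->3', Tm values and
#' product sizes.
#'
#' @param panel a `multiplex_panel`.
#' @param path output file.
#' @export
write_panel_report <- function(panel, path) {
  rows <- lapply(seq_along(panel$assays), function(i) {
    a <- panel$assays[[i]]
    data.frame(assay = i, strain = a$strain, chrom = a$snp$chrom,
               pos = a$snp$pos, ref = a$snp$ref, alt = a$snp$alt,
               as_forward = a$as_fwd$sequence, as_reverse = a$as_rev$sequence,
               tm_forward = round(a$as_fwd$tm, 2),
               tm_reverse = round(a$as_rev$tm, 2),
               as_product_bp = a$as_size, wt_product_bp = a$wt_size)
  })
  write_tsv_report(do.call(rbind, rows), path)
}

# ---------------------------------------------------------------------------
# Thermal protocol

#' Touch-down thermal cycling protocol
#'
#' Annealing starts at `start_temp` and decreases by `step` degrees per
#' cycle; the touch-down phase holds `floor((start - end) / step) + 1`
#' cycles (annealing temperatures `start, start - step, ...` down to the
#' last value still `>= end_temp`), after which `standard_cycles` cycles run
#' at `end_temp`. Defaults reproduce the optimized program: 98 C 2 min
#' hot-start activation; cycles of 95 C 30 s / annealing 30 s / 72 C 60 s;
#' 69.5 -> 61.5 C at -1 C per cycle (9 touch-down cycles) plus 25 standard
#' cycles (34 total); final extension 72 C 5 min.
#'
#' @param start_temp,end_temp touch-down annealing range (C),
#'   `start_temp >= end_temp`.
#' @param step per-cycle decrement (C), > 0.
#' @param standard_cycles number of standard cycles at `end_temp`.
#' @param activation,denature,extension,final_extension `c(temp, seconds)`
#'   pairs for the fixed protocol segments.
#' @param anneal_seconds annealing hold (s).
#' @return an object of class `thermal_protocol` with `touchdown`
#'   (data.frame of per-cycle temperatures/holds), `standard`, `activation`,
#'   `final_extension`, `touchdown_cycles`, `standard_cycles` and
#'   `total_cycles`.
#' @export
touchdown_protocol <- function(start_temp = 69.5, end_temp = 61.5, step = 1,
                               standard_cycles = 25L,
                               activation = c(98, 120),
                               denature = c(95, 30),
                               extension = c(72, 60),
                               final_extension = c(72, 300),
                               anneal_seconds = 30) {
  if (step <= 0) stop("step must be > 0")
  if (end_temp > start_temp) stop("end_temp must not exceed start_temp")
  anneal <- seq(start_temp, end_temp, by = -step)   # last value >= end_temp
  td <- data.frame(cycle = seq_along(anneal),
                   denature_temp = denature[1], denature_s = denature[2],
                   anneal_temp = anneal, anneal_s = anneal_seconds,
                   extend_temp = extension[1], extend_s = extension[2])
  structure(list(activation = activation,
                 touchdown = td,
                 standard = data.frame(denature_temp = denature[1],
                                       denature_s = denature[2],
                                       anneal_temp = end_temp,
                                       anneal_s = anneal_seconds,
                                       extend_temp = extension[1],
                                       extend_s = extension[2]),
                 final_extension = final_extension,
                 touchdown_cycles = nrow(td),
                 standard_cycles = as.integer(standard_cycles),
                 total_cycles = nrow(td) + as.integer(standard_cycles)),
            class = "thermal_protocol")
}

#' @export
print.thermal_protocol <- function(x, ...) {
  cat("<thermal_protocol>\n")
  cat(sprintf("  activation       %.1f C, %d s\n", x$activation[1],
              x$activation[2]))
  cat(sprintf("  touch-down       %d cycles, annealing %.1f -> %.1f C\n",
              x$touchdown_cycles, x$touchdown$anneal_temp[1],
              x$touchdown$anneal_temp[x$touchdown_cycles]))
  cat(sprintf("  standard         %d cycles at %.1f C\n", x$standard_cycles,
              x$standard$anneal_temp))
  cat(sprintf("  final extension  %.1f C, %d s\n", x$final_extension[1],
              x$final_extension[2]))
  cat(sprintf("  total            %d cycles\n", x$total_cycles))
  invisible(x)
}
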