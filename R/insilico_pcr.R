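# In-silico PCR: primer binding-site scans, amplicon prediction, gel band
# rendering, inter-delta fingerprints, fingerprint clustering, colony
# assignment and frequency tallies.
#
# Binding rule (the in-silico reading of ARMS specificity): a primer binds a
# site iff its 3'-terminal base matches the template exactly and it has at
# most `internal_mismatch_max` internal mismatches. One internal mismatch is
# tolerated for assay primers -- exactly what the engineered -2 destabilizer
# produces on the intended template -- while a 3' mismatch (the
# non-target allele) blocks extension entirely.

# Default inter-delta primers (delta-12 / delta-21 of Legras & Karst 2003),
# overridable in interdelta_fingerprint().
DELTA12 <- "TCAACAATGGAATCCCAAC"
DELTA21 <- "CATCTTAACACCGTATATGA"

#' Find binding sites of one primer on one chromosome
#'
#' @param template_seq chromosome sequence (character scalar).
#' @param primer_seq primer sequence 5'->3'.
#' @param max_internal_mismatch internal mismatches tolerated.
#' @return data.frame with `start0`, `end0` (footprint, 0-based half-open)
#'   and `strand` (`+` = primer extends rightward, `-` = leftward).
#' @keywords internal
find_binding_sites <- function(template_seq, primer_seq,
                               max_internal_mismatch = 1L) {
  k <- nchar(primer_seq)
  if (k < 8L) stop("primer shorter than seed length (8 nt)")
  subj <- Biostrings::DNAString(template_seq)
  pat <- Biostrings::DNAString(primer_seq)
  out <- list()
  hits <- Biostrings::matchPattern(pat, subj,
                                   max.mismatch = max_internal_mismatch)
  if (length(hits)) {
    s <- BiocGenerics::start(hits); e <- BiocGenerics::end(hits)
    last <- substr(primer_seq, k, k)
    ok <- substring(template_seq, e, e) == last
    if (any(ok)) out[[1]] <- data.frame(start0 = s[ok] - 1L, end0 = e[ok],
                                        strand = "+")
  }
  rc <- Biostrings::reverseComplement(pat)
  hits <- Biostrings::matchPattern(rc, subj,
                                   max.mismatch = max_internal_mismatch)
  if (length(hits)) {
    s <- BiocGenerics::start(hits); e <- BiocGenerics::end(hits)
    first_rc <- comp_base(substr(primer_seq, k, k))  # primer 3' on - strand
    ok <- substring(template_seq, s, s) == first_rc
    if (any(ok)) out[[length(out) + 1L]] <-
        data.frame(start0 = s[ok] - 1L, end0 = e[ok], strand = "-")
  }
  if (length(out) == 0L)
    data.frame(start0 = integer(0), end0 = integer(0), strand = character(0))
  else do.call(rbind, out)
}

#' Predict PCR amplicons of a primer set on a genome
#'
#' Scans every chromosome of the template genome for binding sites of every
#' primer (both strands; 3'-terminal base must match exactly, at most
#' `internal_mismatch_max` internal mismatches) and emits one amplicon per
#' convergent forward/reverse site pair on the same chromosome no longer
#' than `max_amplicon`.
#'
#' @param template a [reference_genome()] (strain genome).
#' @param primers list of [primer()] objects or a named character vector of
#'   primer sequences.
#' @param config a [sim_config()].
#' @param max_internal_mismatch override of `config$internal_mismatch_max`
#'   (used for the more permissive inter-delta scan).
#' @return data.frame of class `amplicons`: `chrom`, `start0`, `end0`,
#'   `length`, `fwd_primer`, `rev_primer`.
#' @export
predict_amplicons <- function(template, primers, config = sim_config(),
                              max_internal_mismatch = NULL) {
  stopifnot(inherits(template, "ref_genome"))
  mm <- as.integer(max_internal_mismatch %||% config$internal_mismatch_max)
  seqs <- primer_sequences(primers)
  res <- list()
  for (chrom in chrom_names(template)) {
    tmpl <- chrom_seq(template, chrom)
    sites <- lapply(names(seqs), function(id) {
      s <- find_binding_sites(tmpl, seqs[[id]], mm)
      if (nrow(s)) s$primer <- id
      s
    })
    sites <- do.call(rbind, sites[vapply(sites, nrow, integer(1)) > 0])
    if (is.null(sites) || nrow(sites) == 0L) next
    fwd <- sites[sites$strand == "+", , drop = FALSE]
    rev <- sites[sites$strand == "-", , drop = FALSE]
    if (nrow(fwd) == 0L || nrow(rev) == 0L) next
    for (i in seq_len(nrow(fwd))) {
      len <- rev$end0 - fwd$start0[i]
      ok <- rev$start0 >= fwd$start0[i] & rev$end0 >= fwd$end0[i] &
        len <= config$max_amplicon &
        len >= pmax(fwd$end0[i] - fwd$start0[i], rev$end0 - rev$start0)
      if (any(ok)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start0 = fwd$start0[i], end0 = rev$end0[ok],
          length = len[ok], fwd_primer = fwd$primer[i],
          rev_primer = rev$primer[ok])
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res)
  else data.frame(chrom = character(0), start0 = integer(0),
                  end0 = integer(0), length = integer(0),
                  fwd_primer = character(0), rev_primer = character(0))
  rownames(out) <- NULL
  class(out) <- c("amplicons", "data.frame")
  out
}

primer_sequences <- function(primers) {
  if (is.character(primers)) {
    if (is.null(names(primers)))
      names(primers) <- paste0("p", seq_along(primers))
    return(as.list(toupper(primers)))
  }
  if (inherits(primers, "primer")) primers <- list(primers)
  seqs <- lapply(primers, function(p) {
    if (inherits(p, "primer")) p$sequence else toupper(as.character(p))
  })
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("p", seq_along(seqs))
  seqs
}

#' Render amplicons (or raw sizes) as a gel band pattern
#'
#' Bands are what a gel resolves, not molecules: sizes closer than
#' `gel_resolution` are merged (single linkage) into one band at their mean.
#' Idempotent: re-rendering a rendered pattern changes nothing.
#'
#' @param amplicons an `amplicons` data.frame, a [band_pattern()] or a
#'   numeric vector of sizes.
#' @param gel_resolution merge resolution (bp).
#' @return a [band_pattern()].
#' @export
gel_pattern <- function(amplicons, gel_resolution = 25) {
  sizes <- if (is.data.frame(amplicons)) amplicons$length
           else as.numeric(amplicons)
  if (length(sizes) == 0L) return(band_pattern())
  sizes <- sort(sizes)
  grp <- cumsum(c(1, diff(sizes) >= gel_resolution))
  band_pattern(vapply(split(sizes, grp), mean, numeric(1)))
}

#' Inter-delta fingerprint of a genome
#'
#' Finds all binding sites of the delta-12 and delta-21 primers (both
#' strands, allowing `interdelta_mismatch_max` internal mismatches to model
#' diverged delta elements; the 3' base must still match), emits all
#' convergent inter-site amplicons up to `max_amplicon` and renders them as
#' a gel pattern. Strains with identical delta layouts give identical
#' fingerprints, which is precisely why closely related strains need SNP
#' markers.
#'
#' @param genome a [reference_genome()] (strain genome).
#' @param delta12_seq,delta21_seq primer sequences (defaults: delta-12 and
#'   delta-21).
#' @param config a [sim_config()].
#' @return a [band_pattern()].
#' @export
interdelta_fingerprint <- function(genome, delta12_seq = DELTA12,
                                   delta21_seq = DELTA21,
                                   config = sim_config()) {
  amps <- predict_amplicons(genome,
                            c(delta12 = delta12_seq, delta21 = delta21_seq),
                            config,
                            max_internal_mismatch = config$interdelta_mismatch_max)
  gel_pattern(amps, config$gel_resolution)
}

# band-pattern equality at gel resolution: same band count, all pairwise
# differences of matched (sorted) bands below the resolution
patterns_equal <- function(a, b, gel_resolution) {
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  all(abs(unclass(a) - unclass(b)) < gel_resolution)
}

#' Partition strains by fingerprint equality
#'
#' Strains whose band patterns match band-by-band (within `gel_resolution`)
#' fall in one class; classes are connected components of the pairwise-match
#' graph, returned sorted by decreasing size, then by first member name.
#'
#' @param patterns named list of [band_pattern()]s (strain -> pattern), all
#'   rendered at the same resolution.
#' @param gel_resolution band-match tolerance (bp).
#' @return list of character vectors (the classes).
#' @export
cluster_fingerprints <- function(patterns, gel_resolution = 25) {
  nms <- names(patterns)
  stopifnot(!is.null(nms), !anyDuplicated(nms))
  n <- length(patterns)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (patterns_equal(patterns[[i]], patterns[[j]], gel_resolution)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  classes <- lapply(split(seq_len(n), roots), function(ix) sort(nms[ix]))
  ord <- order(-lengths(classes),
               vapply(classes, `[`, character(1), 1L))
  unname(classes[ord])
}

#' Assign a colony to a strain from its observed band pattern
#'
#' Exact signature matching at gel resolution: an empty pattern or one
#' matching no panel signature is `"unassigned"`; a pattern matching the
#' merged union of two or more signatures (a mixed template) is
#' `"ambiguous"`; otherwise the matching strain is called.
#'
#' @param observed a [band_pattern()] (or numeric sizes).
#' @param panel a [build_multiplex_panel()] result.
#' @param gel_resolution band-match tolerance (bp).
#' @return list of class `colony_assignment`: `observed`, `call`,
#'   `matched` (the strains whose signatures compose the observation).
#' @export
assign_colony <- function(observed, panel, gel_resolution = 25) {
  if (!inherits(observed, "band_pattern")) observed <- band_pattern(observed)
  sig <- panel$signatures
  res <- function(call, matched) structure(
    list(observed = observed, call = call, matched = matched),
    class = "colony_assignment")
  if (length(observed) == 0L) return(res("unassigned", character(0)))
  hits <- names(sig)[vapply(sig, patterns_equal, logical(1), a = observed,
                            gel_resolution = gel_resolution)]
  if (length(hits) == 1L) return(res(hits, hits))
  if (length(hits) > 1L) return(res("ambiguous", hits))
  # mixed-template check: union of >= 2 signatures
  strains <- names(sig)
  if (length(strains) >= 2L) {
    for (k in 2:length(strains)) {
      combs <- combn(strains, k, simplify = FALSE)
      for (cc in combs) {
        u <- gel_pattern(unlist(lapply(sig[cc], unclass)), gel_resolution)
        if (patterns_equal(observed, u, gel_resolution))
          return(res("ambiguous", cc))
      }
    }
  }
  res("unassigned", character(0))
}

#' @export
print.colony_assignment <- function(x, ...) {
  cat(sprintf("<colony_assignment> call=%s (bands: %s)\n", x$call,
              if (length(x$observed)) paste(round(unclass(x$observed)),
                                            collapse = ", ") else "none"))
  invisible(x)
}

#' Genotype a set of colonies with a panel
#'
#' Runs [predict_amplicons()] with the panel's AS primers on each colony
#' genome, renders the gel pattern and assigns the colony.
#'
#' @param colonies list of colony genomes ([reference_genome()]s), named by
#'   colony id.
#' @param panel a `multiplex_panel`.
#' @param config a [sim_config()].
#' @return data.frame of class `assignment_report`: `colony`, `bands`
#'   (slash-separated sizes), `call`.
#' @export
genotype_colonies <- function(colonies, panel, config = sim_config()) {
  primers <- panel_primers(panel)
  rows <- lapply(names(colonies), function(id) {
    amps <- predict_amplicons(colonies[[id]], primers, config)
    pat <- gel_pattern(amps, config$gel_resolution)
    asg <- assign_colony(pat, panel, config$gel_resolution)
    data.frame(colony = id,
               bands = paste(round(unclass(pat)), collapse = "/"),
               call = asg$call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assignment_report", "data.frame")
  out
}

#' Tally strain and cluster frequencies from colony assignments
#'
#' Percentages are computed over all colonies (assigned plus unassigned/
#' ambiguous) and rounded half-away-from-zero to the nearest integer
#' (14 of 26 colonies -> 54).
#'
#' @param assignments an `assignment_report` data.frame (columns `colony`,
#'   `call`) or a character vector of calls.
#' @param grouping optional named character vector strain -> cluster for the
#'   per-cluster tally.
#' @return list with `per_strain` and (if `grouping` given) `per_cluster`
#'   data.frames (`n`, `percent`), plus `total`.
#' @export
tally_frequencies <- function(assignments, grouping = NULL) {
  calls <- if (is.data.frame(assignments)) assignments$call
           else as.character(assignments)
  if (length(calls) == 0L) stop("no assignments to tally")
  total <- length(calls)
  pct <- function(n) round_half_away(100 * n / total)
  tab <- table(calls)
  per_strain <- data.frame(strain = names(tab), n = as.integer(tab),
                           percent = pct(as.integer(tab)),
                           stringsAsFactors = FALSE)
  per_strain <- per_strain[order(-per_strain$n, per_strain$strain), ]
  rownames(per_strain) <- NULL
  out <- list(per_strain = per_strain, total = total)
  if (!is.null(grouping)) {
    grp <- ifelse(calls %in% names(grouping), grouping[calls], calls)
    gt <- table(grp)
    per_cluster <- data.frame(cluster = names(gt), n = as.integer(gt),
                              percent = pct(as.integer(gt)),
                              stringsAsFactors = FALSE)
    per_cluster <- per_cluster[order(-per_cluster$n, per_cluster$cluster), ]
    rownames(per_cluster) <- NULL
    out$per_cluster <- per_cluster
  }
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
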