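#' Marker-selection configuration
#'
#' Thresholds for [apply_marker_criteria()]. Defaults encode the operational
#' reading of the published selection criteria: a candidate locus must sit in
#' non-polymorphic, non-repetitive, unmasked sequence of moderate GC, and its
#' 3'-anchor k-mer must be unique in the reference.
#'
#' @param min_depth minimum per-strain read depth at a private locus (50x).
#' @param max_primer_len longest primer considered; the polymorphic-flank
#'   window is `pos +/- (max_primer_len + 5)` bp.
#' @param max_homopolymer longest tolerated single-base run in the flank.
#' @param max_dinuc_units longest tolerated perfect dinucleotide repeat
#'   (in units, i.e. 4 means `(XY)x4` passes, `(XY)x5` is flagged).
#' @param gc_window half-width (bp) of the window for the GC check.
#' @param gc_min,gc_max acceptable GC fraction of the window.
#' @param anchor_k length of the 3'-terminal k-mer whose uniqueness in the
#'   reference (both strands) is required.
#' @return a named list of class `marker_config`.
#' @export
marker_config <- function(min_depth = 50L,
                          max_primer_len = 28L,
                          max_homopolymer = 6L,
                          max_dinuc_units = 4L,
                          gc_window = 100L,
                          gc_min = 0.30,
                          gc_max = 0.65,
                          anchor_k = 15L) {
  stopifnot(min_depth >= 0, max_primer_len >= 18, anchor_k >= 8,
            gc_min >= 0, gc_max <= 1, gc_min < gc_max)
  structure(list(min_depth = as.integer(min_depth),
                 max_primer_len = as.integer(max_primer_len),
                 max_homopolymer = as.integer(max_homopolymer),
                 max_dinuc_units = as.integer(max_dinuc_units),
                 gc_window = as.integer(gc_window),
                 gc_min = gc_min, gc_max = gc_max,
                 anchor_k = as.integer(anchor_k)),
            class = "marker_config")
}

#' Assay-design configuration
#'
#' Parameters for [design_as_primer()], [design_assay()] and
#' [build_multiplex_panel()]. Melting temperatures use unified
#' nearest-neighbor thermodynamics with a monovalent-equivalent salt
#' correction; the annealing end point of the touch-down program (61.5 C)
#' motivates the default Tm target of 62 C.
#'
#' @param min_len,max_len primer length bounds (nt).
#' @param tm_target,tm_tol primer design Tm window `tm_target +/- tm_tol` (C).
#' @param tm_spread_max largest allowed Tm spread inside one panel (C).
#' @param min_size_gap minimum |wild-type product - variant product| (bp).
#' @param product_min,product_max allowed amplicon size range (bp).
#' @param gel_resolution smallest band-size difference resolved on the
#'   agarose gel (bp); also the within-strain band-separation requirement.
#' @param dimer_max 3'-terminal complementarity run (nt) that rejects a
#'   primer pair as a potential primer-dimer.
#' @param mismatch_table named character vector mapping the annealing-strand
#'   template base to the engineered -2 primer base (a deliberately
#'   non-Watson-Crick pairing).
#' @param monovalent_mM,mg_mM,dntp_mM,primer_uM ionic/concentration terms of
#'   the Tm model (see [melting_temperature()]).
#' @return a named list of class `design_config`.
#' @export
design_config <- function(min_len = 18L, max_len = 28L,
                          tm_target = 62, tm_tol = 2,
                          tm_spread_max = 3,
                          min_size_gap = 200L,
                          product_min = 150L, product_max = 800L,
                          gel_resolution = 25L,
                          dimer_max = 5L,
                          mismatch_table = c(A = "A", C = "C", G = "A", T = "T"),
                          monovalent_mM = 50, mg_mM = 2.0, dntp_mM = 0.8,
                          primer_uM = 0.5) {
  stopifnot(min_len >= 8, max_len >= min_len, tm_tol > 0,
            min_size_gap > 0, product_min > 0, product_max > product_min,
            all(c("A", "C", "G", "T") %in% names(mismatch_table)))
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 tm_target = tm_target, tm_tol = tm_tol,
                 tm_spread_max = tm_spread_max,
                 min_size_gap = as.integer(min_size_gap),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 gel_resolution = as.integer(gel_resolution),
                 dimer_max = as.integer(dimer_max),
                 mismatch_table = mismatch_table,
                 monovalent_mM = monovalent_mM, mg_mM = mg_mM,
                 dntp_mM = dntp_mM, primer_uM = primer_uM),
            class = "design_config")
}

#' In-silico PCR configuration
#'
#' Binding-rule and gel parameters for [predict_amplicons()] and
#' [interdelta_fingerprint()]. A primer binds a site iff its 3'-terminal base
#' matches the template exactly and the number of internal mismatches does
#' not exceed the per-primer-class tolerance (1 for allele-specific primers,
#' which accommodates their engineered -2 mismatch; 2 for inter-delta primers,
#' which anneal to diverged delta elements).
#'
#' @param internal_mismatch_max internal mismatches tolerated for assay
#'   primers.
#' @param interdelta_mismatch_max internal mismatches tolerated for
#'   inter-delta primers.
#' @param max_amplicon longest amplicon visible on the gel (bp).
#' @param gel_resolution band-merge resolution (bp), see [gel_pattern()].
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(internal_mismatch_max = 1L,
                       interdelta_mismatch_max = 2L,
                       max_amplicon = 3000L,
                       gel_resolution = 25L) {
  stopifnot(internal_mismatch_max >= 0, max_amplicon > 0, gel_resolution > 0)
  structure(list(internal_mismatch_max = as.integer(internal_mismatch_max),
                 interdelta_mismatch_max = as.integer(interdelta_mismatch_max),
                 max_amplicon = as.integer(max_amplicon),
                 gel_resolution = as.integer(gel_resolution)),
            class = "sim_config")
}
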