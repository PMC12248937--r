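# Nearest-neighbor melting-temperature model.
#
# Unified NN parameters (SantaLucia 1998, 1 M NaCl): per-stack enthalpy
# (kcal/mol) and entropy (cal/mol/K), plus initiation terms for terminal
# G:C and A:T pairs. Salt is handled as a monovalent-equivalent
# concentration: free Mg2+ (Mg minus dNTP chelation) is converted with the
# 120*sqrt(mM) rule, and the entropy is corrected with 0.368 * (n-1) *
# ln[Na+_eq]. The duplex is assumed non-self-complementary, so
# Tm = dH / (dS + R ln(Ct/4)) with Ct the primer concentration.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_R <- 1.98722                      # cal/mol/K

#' Nearest-neighbor melting temperature of a primer
#'
#' Deterministic unified-NN Tm of the primer against its perfect complement.
#' The engineered -2 mismatch of allele-specific primers is deliberately not
#' penalized: the value is the conventional design Tm of the oligo.
#'
#' @param sequence primer sequence, 5'->3', ACGT only, length >= 8.
#' @param config a [design_config()]; the ionic terms `monovalent_mM`,
#'   `mg_mM`, `dntp_mM` and the primer concentration `primer_uM` are used.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(sequence, config = design_config()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 8L) stop("sequence shorter than 8 nt")
  if (grepl("[^ACGT]", sequence)) stop("non-ACGT characters in sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  stacks <- paste0(chars[-n], chars[-1L])
  dh <- sum(NN_DH[stacks])
  ds <- sum(NN_DS[stacks])
  for (term in chars[c(1L, n)]) {
    key <- if (term %in% c("G", "C")) "GC" else "AT"
    dh <- dh + NN_INIT_DH[[key]]
    ds <- ds + NN_INIT_DS[[key]]
  }
  na_eq <- monovalent_equivalent_M(config)
  ds <- ds + 0.368 * (n - 1L) * log(na_eq)
  ct <- config$primer_uM * 1e-6
  tm_k <- (dh * 1000) / (ds + GAS_R * log(ct / 4))
  tm_k - 273.15
}

monovalent_equivalent_M <- function(config) {
  free_mg <- max(config$mg_mM - config$dntp_mM, 0)
  (config$monovalent_mM + 120 * sqrt(free_mg)) / 1000
}
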