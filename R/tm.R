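# Nearest-neighbor duplex thermodynamics, SantaLucia (1998) unified
# parameter set. dH in kcal/mol, dS in cal/(mol K). The ten unique stacks
# are expanded to all sixteen dinucleotides (a stack and its reverse
# complement share parameters), which also makes Tm invariant under
# reverse complement by construction.
.NN_DH <- c(
  AA = -7.9, TT = -7.9,
  AT = -7.2,
  TA = -7.2,
  CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8,
  GA = -8.2, TC = -8.2,
  CG = -10.6,
  GC = -9.8,
  GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, TT = -22.2,
  AT = -20.4,
  TA = -21.3,
  CA = -22.7, TG = -22.7,
  GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0,
  GA = -22.2, TC = -22.2,
  CG = -27.2,
  GC = -24.4,
  GG = -19.9, CC = -19.9
)
# Duplex initiation with a terminal G.C vs terminal A.T pair.
.NN_INIT_DH <- c(AT = 2.3, GC = 0.1)
.NN_INIT_DS <- c(AT = 4.1, GC = -2.8)
.GAS_R <- 1.987  # cal/(mol K)

.terminal_class <- function(base) ifelse(base %in% c("A", "T"), "AT", "GC")

#' Nearest-neighbor oligonucleotide melting temperature
#'
#' Duplex Tm from the SantaLucia (1998) unified nearest-neighbor parameter
#' set with the entropic salt correction 0.368 (N-1) ln\[Na+\] and the
#' bimolecular term R ln(C_T/4) for non-self-complementary duplexes.
#' Defaults: 50 mM monovalent salt, 500 nM total primer concentration.
#'
#' @param sequence primer sequence, 5'->3', A/C/G/T only, length >= 8.
#' @param na_m monovalent cation concentration, mol/L.
#' @param primer_nm total oligonucleotide concentration C_T, nM.
#' @return melting temperature in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(sequence, na_m = 0.05, primer_nm = 500) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8L) stop("sequence must be >= 8 nt", call. = FALSE)
  .check_acgt(sequence, what = "primer", allow_gap = FALSE)
  ch <- .seq_chars(sequence)
  n <- length(ch)
  steps <- paste0(ch[-n], ch[-1L])
  dh <- sum(.NN_DH[steps]) +
    .NN_INIT_DH[.terminal_class(ch[1L])] +
    .NN_INIT_DH[.terminal_class(ch[n])]
  ds <- sum(.NN_DS[steps]) +
    .NN_INIT_DS[.terminal_class(ch[1L])] +
    .NN_INIT_DS[.terminal_class(ch[n])]
  ds <- ds + 0.368 * (n - 1L) * log(na_m)
  k <- primer_nm * 1e-9 / 4
  unname(dh * 1000 / (ds + .GAS_R * log(k)) - 273.15)
}

# Vectorized window Tm used by the designer's enumeration: dH/dS of the
# stack sum are cumulative along the template, so the Tm of any window
# [s, e] is O(1) after one pass. Deliberately a separate code path from
# tm_nearest_neighbor(), which the independent validator uses.
.tm_window_fun <- function(template, na_m = 0.05, primer_nm = 500) {
  ch <- .seq_chars(template)
  n <- length(ch)
  steps <- paste0(ch[-n], ch[-1L])
  cum_dh <- c(0, cumsum(.NN_DH[steps]))
  cum_ds <- c(0, cumsum(.NN_DS[steps]))
  term <- .terminal_class(ch)
  k <- primer_nm * 1e-9 / 4
  rlnk <- .GAS_R * log(k)
  function(starts, ends) {
    dh <- cum_dh[ends] - cum_dh[starts] +
      .NN_INIT_DH[term[starts]] + .NN_INIT_DH[term[ends]]
    ds <- cum_ds[ends] - cum_ds[starts] +
      .NN_INIT_DS[term[starts]] + .NN_INIT_DS[term[ends]] +
      0.368 * (ends - starts) * log(na_m)
    unname(dh * 1000 / (ds + rlnk) - 273.15)
  }
}
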