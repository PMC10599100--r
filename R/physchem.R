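# Average (isotope-weighted) residue masses, Da; the free-residue mass
# minus one water. X contributes the mean of the twenty standard residues.
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_MASS <- 18.01524

#' Ionizable-group pKa table (EMBOSS values)
#'
#' The default pKa set used by the pI engine: side chains D 3.9, E 4.1,
#' C 8.5, Y 10.1, H 6.5, K 10.8, R 12.5; N-terminus 8.6, C-terminus 3.6.
#' Any named numeric vector with these nine entries can be substituted,
#' e.g. to approximate another prediction server's behaviour.
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `D`, `E`,
#'   `C`, `Y`, `H`, `K`, `R`.
#' @export
emboss_pka <- function() {
  c(Nterm = 8.6, Cterm = 3.6,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
    H = 6.5, K = 10.8, R = 12.5)
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.015 Da). `X` residues
#' contribute the mean standard-residue mass. Additive by construction:
#' `mw(paste0(a, b)) == mw(a) + mw(b) - 18.015`.
#'
#' @param sequence Amino-acid string (nonempty).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(sequence) {
  if (!nzchar(sequence)) abort("molecular_weight: empty sequence")
  ch <- seq_chars(toupper(sequence))
  m <- RESIDUE_MASS[ch]
  m[is.na(m)] <- mean(RESIDUE_MASS)
  sum(m) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch ionization model: the N-terminus and the K, R, H
#' side chains contribute `+1/(1 + 10^(pH - pKa))` each; the C-terminus
#' and the D, E, C, Y side chains contribute `-1/(1 + 10^(pKa - pH))`.
#' Strictly decreasing in pH, which makes the isoelectric point unique.
#'
#' @param sequence Amino-acid string.
#' @param pH pH value in `[0, 14]`.
#' @param pka pKa table, default [emboss_pka()].
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(sequence, pH, pka = emboss_pka()) {
  ch <- seq_chars(toupper(sequence))
  pos_counts <- c(Nterm = 1, K = sum(ch == "K"), R = sum(ch == "R"),
                  H = sum(ch == "H"))
  neg_counts <- c(Cterm = 1, D = sum(ch == "D"), E = sum(ch == "E"),
                  C = sum(ch == "C"), Y = sum(ch == "Y"))
  pos <- sum(pos_counts / (1 + 10^(pH - pka[names(pos_counts)])))
  neg <- sum(neg_counts / (1 + 10^(pka[names(neg_counts)] - pH)))
  unname(pos - neg)
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge()] crosses zero, found by bisection on
#' `(0, 14)`. Because the charge is strictly decreasing in pH and the two
#' termini are always present, the crossing exists and is unique.
#'
#' @param sequence Amino-acid string (nonempty).
#' @param pka pKa table, default [emboss_pka()].
#' @param tol Stop when `|charge| < tol` or the bracket is narrower than
#'   1e-6 pH units. Default 1e-4.
#' @return The theoretical pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = emboss_pka(), tol = 1e-4) {
  if (!nzchar(sequence)) abort("isoelectric_point: empty sequence")
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-6) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Acidity band of a pI value
#'
#' `basic` above pH 7.5, `acidic` below 6.5, `neutral` between. The bands
#' reproduce the qualitative split observed for WxLIP proteins: highly
#' basic (~8-11) in Lactiplantibacillus and Listeria versus acidic
#' (5.1-6.8) in Enterococcus.
#'
#' @param pi pI value(s) in pH units.
#' @param acidic_max Upper edge of the acidic band, default 6.5.
#' @param basic_min Lower edge of the basic band, default 7.5.
#' @return Character vector in `{"acidic", "neutral", "basic"}`.
#' @export
acidity_call <- function(pi, acidic_max = 6.5, basic_min = 7.5) {
  dplyr::case_when(pi > basic_min ~ "basic",
                   pi < acidic_max ~ "acidic",
                   TRUE ~ "neutral")
}

#' Physicochemical property table
#'
#' Computes, per protein, the columns of a ProtParam-style property
#' table: residue length, average molecular weight (Da and kDa), the
#' theoretical pI and its acidity band. When `mature = TRUE`, a second
#' set of columns repeats the computation on the mature chain (sequence
#' minus a nominal `signal_clip`-residue signal peptide).
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param pka pKa table, default [emboss_pka()].
#' @param mature Also compute mature-chain values? Default `TRUE`.
#' @param signal_clip Signal-peptide length clipped for the mature chain,
#'   default 25.
#' @return A tibble: `protein_id`, `length`, `mw`, `mw_kda`, `pi`,
#'   `acidity`, and (if requested) `mature_length`, `mature_mw`,
#'   `mature_pi`.
#' @export
physchem_profile <- function(proteins, pka = emboss_pka(), mature = TRUE,
                             signal_clip = 25) {
  out <- proteins |>
    select("protein_id", "sequence") |>
    mutate(length = str_length(.data$sequence),
           mw = map_dbl(.data$sequence, molecular_weight),
           mw_kda = round(.data$mw / 1000, 1),
           pi = round(map_dbl(.data$sequence, isoelectric_point, pka = pka), 2),
           acidity = acidity_call(.data$pi))
  if (mature) {
    mat_seq <- ifelse(out$length > signal_clip,
                      str_sub(out$sequence, signal_clip + 1),
                      out$sequence)
    out <- out |>
      mutate(mature_length = str_length(mat_seq),
             mature_mw = map_dbl(mat_seq, molecular_weight),
             mature_pi = round(map_dbl(mat_seq, isoelectric_point,
                                       pka = pka), 2))
  }
  select(out, -"sequence")
}
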