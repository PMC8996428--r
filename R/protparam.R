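# Physicochemical protein descriptors: average molecular weight, GRAVY
# (Kyte-Doolittle), Ikai aliphatic index, Guruprasad instability index and
# a Henderson-Hasselbalch isoelectric point solved by bisection.

check_residues <- function(aa, what) {
  bad <- setdiff(unique(aa), AA20)
  if (length(bad) > 0L)
    stop(what, ": unknown residue(s): ", paste(bad, collapse = ", "))
}

split_aa <- function(protein_seq, what) {
  if (!is.character(protein_seq) || length(protein_seq) != 1L || nchar(protein_seq) == 0L)
    stop(what, ": empty or invalid protein sequence")
  aa <- strsplit(toupper(protein_seq), "")[[1]]
  check_residues(aa, what)
  aa
}

#' Average molecular weight of a protein (Da)
#'
#' Sum of average residue masses plus one water (18.0153 Da), the ExPASy
#' ProtParam convention.
#'
#' @param protein_seq Amino-acid string over the 20 standard residues.
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(protein_seq) {
  aa <- split_aa(protein_seq, "molecular_weight")
  sum(AA_MASS[aa]) + WATER_MASS
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; negative values
#' indicate a hydrophilic protein.
#'
#' @inheritParams molecular_weight
#' @return GRAVY value.
#' @export
gravy <- function(protein_seq) {
  aa <- split_aa(protein_seq, "gravy")
  mean(KD_HYDROPATHY[aa])
}

#' Aliphatic index (Ikai)
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X the mole percent of
#' each residue; higher values indicate greater thermostability.
#'
#' @inheritParams molecular_weight
#' @return Aliphatic index.
#' @export
aliphatic_index <- function(protein_seq) {
  aa <- split_aa(protein_seq, "aliphatic_index")
  x <- 100 * c(A = mean(aa == "A"), V = mean(aa == "V"),
               I = mean(aa == "I"), L = mean(aa == "L"))
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Instability index (Guruprasad)
#'
#' `(10/L) * sum DIWV(residue_i, residue_{i+1})` over all dipeptides, using
#' the published 20x20 dipeptide weight table. Values above 40 predict an
#' unstable protein.
#'
#' @inheritParams molecular_weight
#' @return Instability index.
#' @export
instability_index <- function(protein_seq) {
  aa <- split_aa(protein_seq, "instability_index")
  n <- length(aa)
  if (n < 2L) stop("instability_index: sequence of length 1 has no dipeptide")
  (10 / n) * sum(DIWV[cbind(aa[-n], aa[-1L])])
}

net_charge <- function(counts, nterm = 1, cterm = 1, ph, pka) {
  hh_pos <- function(pk) 1 / (1 + 10^(ph - pk))
  hh_neg <- function(pk) 1 / (1 + 10^(pk - ph))
  pos <- nterm * hh_pos(pka[["Nterm"]]) +
    counts[["K"]] * hh_pos(pka[["K"]]) +
    counts[["R"]] * hh_pos(pka[["R"]]) +
    counts[["H"]] * hh_pos(pka[["H"]])
  neg <- cterm * hh_neg(pka[["Cterm"]]) +
    counts[["D"]] * hh_neg(pka[["D"]]) +
    counts[["E"]] * hh_neg(pka[["E"]]) +
    counts[["C"]] * hh_neg(pka[["C"]]) +
    counts[["Y"]] * hh_neg(pka[["Y"]])
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the free termini and
#' the ionizable side chains (K, R, H positive; D, E, C, Y negative) is
#' zero, found by bisection on `[0, 14]` to `|charge| < tol`.
#'
#' @inheritParams molecular_weight
#' @param pka_set Named vector of pKa values (default: EMBOSS `iep` values;
#'   names `Nterm`, `Cterm`, `K`, `R`, `H`, `D`, `E`, `C`, `Y`).
#' @param tol Charge convergence tolerance.
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(protein_seq, pka_set = EMBOSS_PKA, tol = 1e-4) {
  aa <- split_aa(protein_seq, "isoelectric_point")
  counts <- lapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(r) sum(aa == r))
  names(counts) <- c("K", "R", "H", "D", "E", "C", "Y")
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, ph = mid, pka = pka_set)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Full descriptor panel with categorical calls
#'
#' Computes all descriptors plus the categorical interpretations used in
#' family surveys: basic (pI > 7), unstable (instability > 40),
#' thermostable (aliphatic index >= 65), hydrophilic (GRAVY < 0).
#'
#' @inheritParams molecular_weight
#' @return One-row data.frame: length, mw, pi, instability, aliphatic,
#'   gravy, is_basic, is_unstable, is_thermostable, is_hydrophilic.
#' @export
protein_properties <- function(protein_seq) {
  pi <- isoelectric_point(protein_seq)
  ii <- instability_index(protein_seq)
  ai <- aliphatic_index(protein_seq)
  gr <- gravy(protein_seq)
  data.frame(length = nchar(protein_seq),
             mw = molecular_weight(protein_seq),
             pi = pi, instability = ii, aliphatic = ai, gravy = gr,
             is_basic = pi > 7, is_unstable = ii > 40,
             is_thermostable = ai >= 65, is_hydrophilic = gr < 0)
}
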