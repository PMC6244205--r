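# Molecular weight and isoelectric point of mature proteins.

#' Default average residue mass table
#'
#' Conventional average (not monoisotopic) residue masses in Da, plus the
#' mass of one water added per peptide. An editable copy ships as
#' `inst/extdata/residue_masses.tsv`; see [read_mass_table()].
#'
#' @return list with `masses` (named numeric, Da per residue) and `water`.
#' @export
default_mass_table <- function() {
  list(masses = c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326),
    water = 18.01524)
}

#' Read a residue-mass table from TSV
#'
#' Expects columns `residue` and `mass_da`; a row with residue `H2O` gives
#' the water mass.
#'
#' @param path TSV path (defaults to the shipped table).
#' @return list as in [default_mass_table()].
#' @export
read_mass_table <- function(path = system.file("extdata",
                                               "residue_masses.tsv",
                                               package = "ltpscan")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  water <- tab$mass_da[tab$residue == "H2O"]
  tab <- tab[tab$residue != "H2O", ]
  masses <- setNames(tab$mass_da, tab$residue)
  if (any(masses <= 0) || length(water) != 1L || water <= 0)
    stop("mass table must contain positive masses and one H2O row")
  list(masses = masses, water = water)
}

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water. Unknown residues (X) or
#' stops are rejected with the offending positions listed.
#'
#' @param sequence protein string.
#' @param table mass table (see [default_mass_table()]).
#' @return mass in Da.
#' @export
#' @examples
#' molecular_weight("G")  # 75.07 Da
molecular_weight <- function(sequence, table = default_mass_table()) {
  chars <- seq_chars(as_residues(sequence, "protein"))
  bad <- which(!(chars %in% names(table$masses)))
  if (length(bad) > 0L)
    stop(sprintf("non-standard residue(s) %s at position(s) %s",
                 paste(unique(chars[bad]), collapse = ","),
                 paste(bad, collapse = ",")))
  sum(table$masses[chars]) + table$water
}

#' Default pKa set (EMBOSS-style)
#'
#' pKa values for the ionizable side chains and the termini, with the
#' charge sign of each group. Cysteines are treated as free thiols
#' (disulphides are ignored for pI). An editable copy ships as
#' `inst/extdata/pka_set.tsv`.
#'
#' @return data frame: group, pka, sign (+1 basic, -1 acidic).
#' @export
default_pka_set <- function() {
  data.frame(
    group = c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y"),
    pka = c(8.6, 3.6, 8.5, 3.9, 4.1, 6.5, 10.8, 12.5, 10.1),
    sign = c(+1, -1, -1, -1, -1, +1, +1, +1, -1),
    stringsAsFactors = FALSE)
}

#' Read a pKa set from TSV
#'
#' @param path TSV path with columns group, pka, sign.
#' @return data frame as in [default_pka_set()].
#' @export
read_pka_set <- function(path = system.file("extdata", "pka_set.tsv",
                                            package = "ltpscan")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(tab$pka <= 0 | tab$pka >= 14))
    stop("pKa values must lie in (0, 14)")
  tab
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch: positive groups contribute
#' `1 / (1 + 10^(pH - pKa))`, negative groups `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param sequence protein string.
#' @param pH pH value.
#' @param pka pKa set data frame.
#' @return net charge (strictly decreasing in pH).
#' @export
protein_charge <- function(sequence, pH, pka = default_pka_set()) {
  chars <- seq_chars(as_residues(sequence, "protein"))
  counts <- c(Nterm = 1, Cterm = 1,
              table(factor(chars, levels = setdiff(pka$group,
                                                   c("Nterm", "Cterm")))))
  total <- 0
  for (i in seq_len(nrow(pka))) {
    n <- counts[pka$group[i]]
    if (is.na(n) || n == 0) next
    total <- total + if (pka$sign[i] > 0)
      n / (1 + 10^(pH - pka$pka[i]))
    else
      -n / (1 + 10^(pka$pka[i] - pH))
  }
  unname(total)
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] where the net Henderson-Hasselbalch charge
#' crosses zero. The charge is strictly decreasing in pH, so the root is
#' unique; bisection runs to the requested tolerance.
#'
#' @param sequence protein string (non-empty).
#' @param pka pKa set data frame.
#' @param tol bisection tolerance on pH.
#' @return pI estimate.
#' @export
isoelectric_point <- function(sequence, pka = default_pka_set(),
                              tol = 1e-4) {
  stopifnot(nzchar(sequence))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
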