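# Published 20-value reference columns used by the characterization and
# correlation machinery. Values are stored in the order in which the source
# tables list residues (I F G V A M L T C Y S N E R W D Q H K P, i.e. by
# descending propensity score) and re-keyed to the canonical alphabet on
# return. Decimal commas in the printed membrane-propensity tables are
# normalised to periods.

.fixture_order <- c(
  "I", "F", "G", "V", "A", "M", "L", "T", "C", "Y",
  "S", "N", "E", "R", "W", "D", "Q", "H", "K", "P"
)

.paper_tables <- list(
  # GA-optimised membrane-transport-protein amino-acid propensity scores
  table3_scores = c(571.9, 566.6, 552.8, 526.1, 521.4, 520.9, 490.2, 469.7,
                    468.5, 460.1, 433.5, 424.7, 422.8, 415.6, 411.6, 407.8,
                    407.1, 398.4, 398.3, 396.4),
  # Kyte-Doolittle hydropathy index (AAindex KYTJ820101)
  table3_kytj = c(4.5, 2.8, -0.4, 4.2, 1.8, 1.9, 3.8, -0.7, 2.5, -1.3,
                  -0.8, -3.5, -3.5, -4.5, -0.9, -3.5, -3.5, -3.2, -3.9, -1.6),
  # Free energy change epsilon(i) -> alpha(Rh) (AAindex WERD780104)
  table3_werd = c(0.06, 0.4, 0.27, -0.11, -0.07, 0.03, -0.17, 0.09, 0.17,
                  -0.61, -0.11, -0.57, -0.63, -0.4, -0.61, -0.8, -0.26,
                  -0.49, -0.45, -0.47),
  # Average internal preferences (AAindex OLSK800101)
  table3_olsk = c(2.32, 1.72, 1.34, 1.99, 1.38, 1.78, 1.47, 0.89, 1.43,
                  0.47, 0.86, 0.37, 0.71, 0, 0.82, 0.52, 0.22, 0.66, 0.15,
                  0.85),
  # Amino-acid composition of single-span transmembrane helices
  table4_single_span = c(3.46, 1.48, 1.27, 2.46, 1.73, 0.86, 2.56, 0.59,
                         0.84, 0.59, 0.49, 0.01, 0.01, 0, 0.74, 0.03, 0.03,
                         0.06, 0.03, 0.18),
  # Amino-acid composition of multi-span transmembrane helices
  # (AAindex NAKH920108)
  table4_nakh = c(13.73, 10.99, 6.17, 12.43, 9.36, 3.93, 16.64, 4.68, 2.56,
                  3.13, 5.58, 2.31, 0.94, 0.27, 2.2, 0.94, 1.14, 0.47,
                  0.58, 1.96),
  # Hydration potential (AAindex WOLR810101)
  table4_wolr = c(2.15, -0.76, 2.39, 1.99, 1.94, -1.48, 2.28, -4.88, -1.24,
                  -6.11, -5.06, -9.68, -10.2, -19.92, -5.88, -10.95, -9.38,
                  -10.27, -9.52, -3.68),
  # Updated hydration energies; five residues unmeasured (NA)
  table4_hydration = c(-10.9, -12.3, -14.5, -11.6, -12, -12.5, -11.3, -13.6,
                       -13.1, -16.9, -14.8, -17.5, NA, NA, -15.2, NA, -17.9,
                       -20, NA, NA)
)

#' Published reference columns for characterization checks
#'
#' Returns one of the embedded 20-value reference columns: the published
#' GA-optimised membrane-transport amino-acid propensity scores and the
#' physicochemical scales they were correlated against (hydropathy index,
#' helix free-energy change, average internal preferences, single- and
#' multi-span transmembrane helix compositions, and two hydration-energy
#' scales, one of which has NA for the five unmeasured residues E, R, D, K
#' and P).
#'
#' @param name One of `"table3_scores"`, `"table3_kytj"`, `"table3_werd"`,
#'   `"table3_olsk"`, `"table4_single_span"`, `"table4_nakh"`,
#'   `"table4_wolr"`, `"table4_hydration"`.
#' @return A numeric vector of 20 values named by residue, in canonical
#'   alphabet order (NA preserved where the source prints NA).
#' @examples
#' paper_fixture("table3_scores")[["I"]]  # 571.9
#' @export
paper_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.paper_tables)) {
    abort(sprintf(
      "Unknown fixture; expected one of: %s",
      paste(names(.paper_tables), collapse = ", ")
    ))
  }
  v <- setNames(.paper_tables[[name]], .fixture_order)
  v[AA_ALPHABET]
}
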