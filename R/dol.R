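#' Degree of labeling of AF647-conjugated antibodies
#'
#' DOL = (A650 / eps647) * epsIgG / (A280 - cf * A650), with eps647 the
#' extinction coefficient of AF647 at 650 nm, epsIgG that of IgG at
#' 280 nm, and cf the correction factor for AF647 absorption at 280 nm.
#'
#' @param A280,A650 Absorbances at 280 and 650 nm.
#' @param eps647,epsIgG Extinction coefficients (1/(M cm)).
#' @param cf647 Correction factor for dye absorbance at 280 nm.
#' @return Dimensionless degree of labeling.
#' @export
dolAF647 <- function(A280, A650, eps647 = 239000, epsIgG = 210000,
                     cf647 = 0.03) {
  stopifnot(all(A280 >= 0), all(A650 >= 0))
  corr <- A280 - cf647 * A650
  if (any(corr <= 0))
    stop("corrected protein absorbance A280 - 0.03 A650 must be positive")
  (A650 / eps647) * epsIgG / corr
}

#' Degree of labeling of DNA-conjugated antibodies
#'
#' Computes antibody and DNA concentrations from absorbances at 280 and
#' 260 nm with mutual spectral correction, and returns DOL =
#' cDNA / cAb:
#' cAb = (A280 - 0.61 A260) / (epsIgG (1 - 0.55 * 0.61)),
#' cDNA = (A260 - 0.55 epsIgG cAb) / epsDNA.
#'
#' @param A280,A260 Absorbances at 280 and 260 nm.
#' @param epsIgG,epsDNA Extinction coefficients of IgG at 280 nm and of
#'   the ssDNA handle at 260 nm (1/(M cm)).
#' @param cfDNA Correction factor for DNA absorbance at 280 nm.
#' @param cfProtein Correction factor for protein absorbance at 260 nm.
#' @return Dimensionless degree of labeling (DNA strands per antibody).
#' @export
dolDNA <- function(A280, A260, epsIgG = 210000, epsDNA = 142000,
                   cfDNA = 0.61, cfProtein = 0.55) {
  stopifnot(all(A280 >= 0), all(A260 >= 0))
  denom <- epsIgG - cfProtein * cfDNA * epsIgG
  cAb <- (A280 - A260 * cfDNA) / denom
  if (any(cAb <= 0)) stop("non-positive antibody concentration")
  cDNA <- (A260 - cAb * epsIgG * cfProtein) / epsDNA
  if (any(cDNA < -1e-12 * pmax(A260, 1)))
    stop("negative DNA concentration")
  pmax(cDNA, 0) / cAb
}
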