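#' Built-in calibration profiles for the synthetic-data generator
#'
#' `"paper2020"` encodes the magnitudes reported for mouse embryonic stem
#' cells: promoter summit offsets downstream of the TSS of 21 bp (NELFA),
#' 39 bp (RNAPII Ser5p) and 184 bp (Ctr9); NELFA-Ctr9 summit distances of
#' 465 bp on super enhancers and 163 bp elsewhere; 231 SEs and 8,563 TEs;
#' Ctr9 occupancy of 72% of SEs and 7% of TEs; H3K4me1 on 90% / H3K27ac on
#' 88% of SEs (83% / 31% of TEs); a 2.7-fold SE:TE Ctr9 density ratio;
#' knockdown down-regulation fractions of 73.5% (SE-associated genes),
#' 63.8% (TE) and 53.7% (other); and RNAPII Ser2p knockdown occupancy
#' divisors of 1.5 (SE) and 1.3 (TE). RNAPII Ser2p enhancer occupancy is
#' parameterized conditional on Ctr9 binding (87.5% on Ctr9+ SEs, giving
#' the 63% marginal), and eRNA presence conditional on Ctr9 likewise
#' (76% of Ctr9+ SEs), so the containment constraints (every Ser2p+ or
#' eRNA+ enhancer is Ctr9+) hold by construction.
#'
#' `"minimal"` is a 2-chromosome, 20-gene, 10-enhancer (3 SE / 7 TE)
#' profile for fast unit tests.
#'
#' @param name `"paper2020"` or `"minimal"`.
#' @return A [CalibrationProfile-class].
#' @examples
#' promoterOffsets(defaultProfile("paper2020"))
#' enhancerCounts(defaultProfile("minimal"))
#' @export
defaultProfile <- function(name) {
  if (!name %in% c("paper2020", "minimal")) {
    .stopf("unknown profile '%s'; available profiles: paper2020, minimal",
           name)
  }
  offsets <- matrix(c(21, 5, 39, 5, 184, 5), nrow = 3L, byrow = TRUE,
                    dimnames = list(c("NELFA", "Ser5p", "Ctr9"),
                                    c("mean", "sd")))
  pair <- matrix(c(465, 50, 163, 50), nrow = 2L, byrow = TRUE,
                 dimnames = list(c("SE", "TE"), c("mean", "sd")))
  occ <- matrix(c(0.72, 0.72, 0.83, 0.875, 0.88, 0.90,
                  0.07, 0.10, 0.20, 0.40, 0.31, 0.83),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("SE", "TE"),
                                c("Ctr9", "NELFA", "Ser5p", "Ser2p",
                                  "H3K27ac", "H3K4me1")))
  knockdown <- list(
    downFraction = c(SE = 0.735, TE = 0.638, other = 0.537),
    downLog2 = c(mean = 0.9, sd = 0.5, min = 0.02),
    upLog2 = c(mean = 0.25, sd = 0.2, min = 0.02),
    ser2pDivisor = c(SE = 1.5, TE = 1.3))
  expression <- list(
    silentFraction = 0.25,
    levels = c(low = 3, medium = 20, high = 150),
    levelProb = c(low = 0.25, medium = 0.50, high = 0.25),
    sdLog = 0.4)
  coverage <- list(
    binWidth = 10L, kernelHalfWidth = 150,
    noisePerBp = 0.2, seBoundDensity = 10,
    geneKernelMass = c(NELFA = 40000, Ser5p = 40000, Ctr9 = 30000,
                       Ser2p = 30000, H3K27ac = 20000),
    enhKernelMass = list(SE = c(NELFA = 20000, Ser5p = 20000,
                                Ser2p = 20000),
                         TE = c(NELFA = 6000, Ser5p = 6000, Ser2p = 6000)),
    histoneDensity = c(H3K27ac = 5, H3K4me1 = 4),
    promoterMarkSd = 50, promoterPeakHalfWidth = 200L,
    enhancerPeakHalfWidth = 300L, ernaHalfWidth = 250L)
  genome <- list(
    nChrom = 5L, nGenes = 2000L, geneSlot = 12000L, seSlot = 12000L,
    teSlot = 4000L, seWidth = 8000L, teWidth = 2000L,
    geneLenMin = 3000L, geneLenMax = 8000L, geneMargin = 2000L,
    otherFraction = 0.30, tailMargin = 10000L, chromLength = NULL)
  counts <- c(SE = 231, TE = 8563)
  if (name == "minimal") {
    counts <- c(SE = 3, TE = 7)
    genome$nChrom <- 2L
    genome$nGenes <- 20L
  }
  methods::new("CalibrationProfile", name = name,
               promoterOffsets = offsets, pairDistance = pair,
               counts = counts, occProb = occ,
               ernaProb = c(SE = 0.76, TE = 0.05),
               unilateralFraction = 0.9, densityRatio = 2.7,
               knockdown = knockdown, expression = expression,
               coverage = coverage, genome = genome)
}
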