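# Montage and frequency-band constants shared across modules.

# 32-channel subset of the 10-20 system common to the three reference
# database layouts, in the conventional order.
.MONTAGE32 <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
  "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
  "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
  "PO4", "O2"
)

# Left/right hemisphere pairs used for the 56 band-power differences,
# ordered frontal -> central -> parietal; difference = right - left.
.ASYM_PAIRS <- list(
  c("Fp1", "Fp2"), c("AF3", "AF4"), c("F3", "F4"), c("F7", "F8"),
  c("FC5", "FC6"), c("FC1", "FC2"),
  c("C3", "C4"), c("T7", "T8"), c("CP5", "CP6"), c("CP1", "CP2"),
  c("P3", "P4"), c("P7", "P8"), c("PO3", "PO4"), c("O1", "O2")
)

# Band edges (Hz) used for average band power and differential entropy.
.BANDS <- list(
  theta = c(4, 8), alpha = c(9, 12), beta = c(13, 30), gamma = c(31, 45)
)

# Band edges (Hz) used for the hemispheric power differences.
.ASYM_BANDS <- list(
  theta = c(4, 8), alpha = c(8, 14), beta = c(14, 31), gamma = c(31, 45)
)

#' Frequency-band scheme for spectral features
#'
#' The package carries two sets of band edges: `bands` (theta 4-8, alpha
#' 9-12, beta 13-30, gamma 31-45 Hz) used for average band power and
#' differential entropy, and `asymBands` (theta 4-8, alpha 8-14, beta 14-31,
#' gamma 31-45 Hz) used for the hemispheric power differences. Both are kept
#' as found in the respective feature definitions rather than unified.
#'
#' @param bands named list of `c(low, high)` band edges in Hz for band power
#'   and differential entropy.
#' @param asymBands named list of band edges for hemispheric differences.
#' @return a `BandScheme` list with elements `bands` and `asymBands`.
#' @examples
#' sch <- bandScheme()
#' sch$bands$alpha
#' @export
bandScheme <- function(bands = .BANDS, asymBands = .ASYM_BANDS) {
  checkEdges <- function(b, what) {
    for (nm in names(b)) {
      e <- b[[nm]]
      if (length(e) != 2L || e[1] >= e[2])
        stop(sprintf("%s band '%s': edges must be strictly increasing",
                     what, nm))
    }
  }
  checkEdges(bands, "power")
  checkEdges(asymBands, "asymmetry")
  structure(list(bands = bands, asymBands = asymBands),
            class = "BandScheme")
}
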