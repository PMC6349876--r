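# Frozen chi-angle reference table: one mean rotamer value per residue
# type per angle (degrees), in the spirit of side-chain dihedral
# libraries averaged over folded-protein structures. Shipped as a fixed
# package table so the AlphaBeta similarity CVs are reproducible.

CHI_REFERENCE_DEFAULT <- list(
  chi1 = list(
    R = -67, N = -65, D = -70, C = -65, Q = -66, E = -67, H = -63,
    I = -61, L = -65, K = -67, M = -65, F = -65, P = -27, S = 64,
    T = 62, W = -67, Y = -65, V = 175
  ),
  chi2 = list(
    R = 180, N = -60, D = -30, Q = 180, E = 180, H = -75, I = 168,
    K = 180, L = 175, M = 180, F = 80, P = 38, W = 95, Y = 80
  )
)

#' Chi-angle reference values for a sequence
#'
#' Expands the packaged per-residue-type rotamer mean table to one
#' reference angle per residue for the requested chi angle; residues
#' lacking the angle get NA.
#'
#' @param sequence a [peptide_sequence()].
#' @param angle_kind `"chi1"` or `"chi2"`.
#' @param table reference table; defaults to the packaged library means.
#' @return numeric vector of reference angles (degrees), NA where the
#'   residue type has no such angle.
#' @export
chi_reference <- function(sequence, angle_kind = c("chi1", "chi2"),
                          table = CHI_REFERENCE_DEFAULT) {
  angle_kind <- match.arg(angle_kind)
  has <- if (angle_kind == "chi1") HAS_CHI1 else HAS_CHI2
  vapply(sequence$residues, function(code) {
    if (!code %in% has) return(NA_real_)
    v <- table[[angle_kind]][[code]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}
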