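#' EMSA binding ratio
#'
#' Fraction of probe shifted into the RNA-protein complex:
#' bound / (free + bound). Scale-invariant in the band intensities.
#'
#' @param bound_intensity RNA-protein band intensity (arbitrary units >= 0).
#' @param free_intensity free-RNA band intensity (arbitrary units >= 0).
#' @return binding ratio in \[0, 1\].
#' @export
emsa_binding_ratio <- function(bound_intensity, free_intensity) {
  if (any(bound_intensity < 0) || any(free_intensity < 0))
    stop("intensities must be >= 0")
  tot <- bound_intensity + free_intensity
  if (any(tot == 0)) stop("bound and free intensities both zero")
  bound_intensity / tot
}

#' Relative cytoplasmic/nuclear export ratio by 2^(-ddCt)
#'
#' Per compartment, dCt = Ct(target) - Ct(reference); per condition,
#' d(C/N) = dCt(cyto) - dCt(nuc); across conditions,
#' ddCt = d(C/N, treatment) - d(C/N, control); the relative fold change in the
#' cytoplasmic/nuclear ratio is 2^(-ddCt). Positive ddCt therefore means a
#' fold change below 1, i.e. reduced export in the treatment.
#'
#' @param treatment,control lists (or named vectors) with elements
#'   `ct_target_cyto`, `ct_ref_cyto`, `ct_target_nuc`, `ct_ref_nuc`.
#' @return fold change (numeric).
#' @export
relative_cn_ratio <- function(treatment, control) {
  dd <- function(x) {
    x <- as.list(x)
    stopifnot(all(is.finite(unlist(x[c("ct_target_cyto", "ct_ref_cyto",
                                       "ct_target_nuc", "ct_ref_nuc")]))))
    (x$ct_target_cyto - x$ct_ref_cyto) - (x$ct_target_nuc - x$ct_ref_nuc)
  }
  2^(-(dd(treatment) - dd(control)))
}
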