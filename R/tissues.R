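#' Tissue electrical conductivities
#'
#' Low-frequency conductivities (S/m) of the tissues represented in the
#' forearm phantom, plus the electrode gel. Values follow the IT'IS material
#' database entries commonly used for transcutaneous stimulation modelling.
#' Air is exactly 0 and marks voxels outside the conductive domain.
#'
#' @param overrides optional named numeric vector of conductivities to
#'   replace or extend the defaults.
#' @return named numeric vector, S/m.
#' @export
#' @examples
#' tissue_table()[["muscle"]]
tissue_table <- function(overrides = NULL) {
  tab <- c(
    air             = 0,
    skin            = 0.1482,
    sat             = 0.0776,  # subcutaneous adipose tissue
    fat             = 0.0776,
    muscle          = 0.4610,
    cortical_bone   = 0.0063,
    cancellous_bone = 0.0804,
    marrow          = 0.1797,
    tendon          = 0.3675,
    blood           = 0.6624,
    nerve           = 0.3475,
    gel             = 1.7
  )
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    tab[names(overrides)] <- overrides
  }
  if (anyDuplicated(names(tab))) stop("duplicate tissue names")
  if (any(!is.finite(tab)) || any(tab < 0)) stop("conductivities must be finite and >= 0")
  tab
}

#' Integer label codes used in voxel grids
#'
#' @return named integer vector mapping tissue name to its voxel label.
#' @export
tissue_codes <- function() {
  setNames(seq_along(tissue_table()) - 1L, names(tissue_table()))
}
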