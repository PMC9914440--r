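#' Convert micrometres to nanometres
#'
#' Explicit length converters between the two internal unit systems:
#' single-particle-tracking trajectories are handled in micrometres, STORM
#' detection tables in nanometres.
#'
#' @param x numeric vector of lengths in micrometres.
#' @return numeric vector in nanometres.
#' @export
um_to_nm <- function(x) x * 1000

#' Convert nanometres to micrometres
#'
#' @param x numeric vector of lengths in nanometres.
#' @return numeric vector in micrometres.
#' @rdname um_to_nm
#' @export
nm_to_um <- function(x) x / 1000
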