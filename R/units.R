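#' Physical constants and unit conversions
#'
#' All internal computations use SI units: gradient amplitude in T/m, time in
#' s, diffusivity in m^2/s and diffusion weighting b in s/m^2. Scanner-facing
#' interfaces (waveform files, the command line) speak mT/m and s/mm^2; these
#' helpers convert explicitly so that no silent factor-of-10^6 can slip in.
#'
#' `mde_gamma()` returns the gyromagnetic ratio used throughout, the proton
#' value 2.6752218744e8 rad s^-1 T^-1 by default. It can be overridden for a
#' session via `options(mdesim.gamma = ...)`, e.g. for deuterium work.
#'
#' @return `mde_gamma()`: the gyromagnetic ratio in rad s^-1 T^-1.
#' @examples
#' mde_gamma()
#' b_to_si(4800)    # s/mm^2 -> s/m^2
#' b_from_si(4.8e9) # back to s/mm^2
#' @export
mde_gamma <- function() {
  getOption("mdesim.gamma", 2.6752218744e8)
}

#' @rdname mde_gamma
#' @param b diffusion weighting in s/mm^2.
#' @export
b_to_si <- function(b) b * 1e6

#' @rdname mde_gamma
#' @param b_si diffusion weighting in s/m^2.
#' @export
b_from_si <- function(b_si) b_si / 1e6

#' @rdname mde_gamma
#' @param g gradient amplitude in mT/m.
#' @export
gradient_to_si <- function(g) g * 1e-3

#' @rdname mde_gamma
#' @param g_si gradient amplitude in T/m.
#' @export
gradient_from_si <- function(g_si) g_si * 1e3
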