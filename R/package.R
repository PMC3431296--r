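#' operonoise: intrinsic-noise consequences of operon cotranscription
#'
#' Stochastic simulation, linear-noise-approximation theory, ultrasensitive
#' threshold analysis and operon-enrichment statistics for two-gene protein
#' interaction modules expressed from shared or separate transcription
#' units.
#'
#' @importFrom generics tidy glance
#' @importFrom rlang .data
#' @importFrom dplyr %>%
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
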