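#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods for repeatdepth result objects
#'
#' Quick diagnostic ggplots: the fitted GC-bias profile (rate per GC bin),
#' per-measurement percent errors against the CHEF reference, and per-cell
#' integrated FISH intensity by strain.
#'
#' @param object A `gc_bias_profile`, `error_summary` or
#'   `strain_intensity_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-repeatdepth
NULL
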