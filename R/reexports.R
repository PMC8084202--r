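# Generics this package implements methods for, re-exported so users get
# tidy()/glance()/fit()/autoplot() without attaching their home packages.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics fit
#' @export
generics::fit

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
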