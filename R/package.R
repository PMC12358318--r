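#' @keywords internal
#' @useDynLib panlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
"_PACKAGE"

#' @export
tibble::as_tibble

#' @export
ggplot2::autoplot
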