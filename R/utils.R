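#' @importFrom rlang %||% .data
#' @importFrom dplyr n
#' @importFrom utils head
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# count mismatching characters between two equal-length strings
.mm_count <- function(a, b) {
  if (a == b) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}
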