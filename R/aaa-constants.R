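# The nine semantic attributes, in the order used throughout the package.
MIL_ATTRIBUTES <- c("tex", "sph", "mal", "lob", "spi", "mar", "cal", "sub", "int")

#' Legal score range of a semantic attribute
#'
#' All attributes are scored in \[1, 5\] except calcification ("cal"),
#' which uses \[1, 6\].
#'
#' @param attribute Attribute abbreviation, one of
#'   `tex, sph, mal, lob, spi, mar, cal, sub, int`.
#' @return Numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' attribute_range("mal")
#' attribute_range("cal")
attribute_range <- function(attribute) {
  if (!attribute %in% MIL_ATTRIBUTES) {
    rlang::abort(paste0("unknown attribute '", attribute, "'"),
                 class = "milcascade_domain_error")
  }
  if (attribute == "cal") c(1, 6) else c(1, 5)
}
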