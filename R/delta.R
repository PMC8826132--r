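#' Delta notation from isotope ratios
#'
#' Converts measured isotope abundance ratios to conventional delta notation in
#' parts per mil: `delta = ((r_sample / r_standard) - 1) * 1000`. For carbon the
#' ratio is 13C/12C and the standard is VPDB.
#'
#' @param r_sample Numeric vector of sample isotope ratios (> 0).
#' @param r_standard Numeric vector of standard isotope ratios (> 0); recycled
#'   against `r_sample`.
#' @return Numeric vector of delta values in permil.
#' @examples
#' delta_from_ratio(1.01, 1)   # 10 permil
#' delta_from_ratio(0.0112372 * 0.99, 0.0112372)  # -10 permil vs VPDB 13C/12C
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard))
    stop("isotope ratios must be numeric", call. = FALSE)
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)))
    stop("isotope ratios must be finite", call. = FALSE)
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be strictly positive", call. = FALSE)
  (r_sample / r_standard - 1) * 1000
}
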