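#' IC50 to binding-affinity conversion
#'
#' Converts a half-maximal inhibitory concentration (molar) to a binding
#' affinity on the free-energy scale, \eqn{BA = 1.3633 \times \log_{10}(IC_{50})}
#' kcal/mol. The constant is \eqn{RT\ln 10} at 298 K, so a ten-fold drop in
#' IC50 strengthens the affinity by 1.3633 kcal/mol. More negative values mean
#' stronger predicted binding; a 1 uM compound maps to about -8.18 kcal/mol.
#'
#' @param ic50_molar positive numeric vector of IC50 values in molar units.
#' @return numeric vector of binding affinities in kcal/mol.
#' @seealso [ic50_from_ba()] for the exact inverse, [to_molar()] for unit
#'   normalization.
#' @examples
#' ba_from_ic50(1e-6)   # -8.1798
#' ba_from_ic50(1)      # 0
#' @export
ba_from_ic50 <- function(ic50_molar) {
  if (!is.numeric(ic50_molar) || length(ic50_molar) == 0) {
    stop("ic50_molar must be a non-empty numeric vector")
  }
  if (any(!is.finite(ic50_molar)) || any(ic50_molar <= 0)) {
    stop("ic50_molar values must be finite and > 0")
  }
  BA_LOG10_SLOPE * log10(ic50_molar)
}

#' @rdname ba_from_ic50
#' @param ba numeric vector of binding affinities in kcal/mol.
#' @return `ic50_from_ba`: numeric vector of IC50 values in molar units.
#' @export
ic50_from_ba <- function(ba) {
  if (!is.numeric(ba) || any(!is.finite(ba))) {
    stop("ba must be finite numeric")
  }
  10^(ba / BA_LOG10_SLOPE)
}

# kcal/mol per log10 unit of concentration: RT*ln(10) at 298 K
BA_LOG10_SLOPE <- 1.3633
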