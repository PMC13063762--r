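#' Convert log2 fold changes to signed linear fold changes
#'
#' Maps a log2 fold change onto the signed linear fold-change convention used
#' throughout the interaction analysis: up-regulation gives `2^log2fc`
#' (always >= 1), down-regulation gives `-(2^|log2fc|)` (always <= -1), so the
#' open interval (-1, 1) is never produced and `log2fc = 0` maps to `1` (no
#' change). A signed FC of -2 therefore means "halved expression".
#'
#' @param log2fc Numeric vector of finite log2 fold changes.
#' @return Numeric vector of signed fold changes, `|value| >= 1`.
#' @examples
#' signed_fold_change(c(1, 0, -1, -2))  # 2, 1, -2, -4
#' @seealso [percent_change()], [backtransform_pex()]
#' @export
signed_fold_change <- function(log2fc) {
  if (!is.numeric(log2fc)) {
    stop("`log2fc` must be numeric, got ", class(log2fc)[1], call. = FALSE)
  }
  if (length(log2fc) && any(!is.finite(log2fc))) {
    stop("`log2fc` contains non-finite values (NA/NaN/Inf) at position(s) ",
         paste(utils::head(which(!is.finite(log2fc)), 5L), collapse = ", "),
         call. = FALSE)
  }
  ifelse(log2fc >= 0, 2^log2fc, -(2^abs(log2fc)))
}

#' Convert signed fold changes to percent expression change (pEX)
#'
#' Shifts signed fold changes so that "no change" is 0: positive FCs lose 1,
#' negative FCs gain 1. On this scale +1.0 means +100% (doubling) and -1.0
#' means -100% (halving, i.e. FC = -2). The negative branch is the unique
#' continuation that keeps pEX continuous and sign-symmetric with pEX = 0
#' exactly at log2FC = 0.
#'
#' @param fc Numeric vector of signed fold changes with `|fc| >= 1`
#'   (see [signed_fold_change()]).
#' @return Numeric vector of fractional expression changes.
#' @examples
#' percent_change(c(2, 1, -2))  # 1, 0, -1
#' @export
percent_change <- function(fc) {
  if (!is.numeric(fc)) {
    stop("`fc` must be numeric", call. = FALSE)
  }
  if (length(fc) && any(!is.finite(fc))) {
    stop("`fc` contains non-finite values", call. = FALSE)
  }
  bad <- abs(fc) < 1
  if (any(bad)) {
    stop("signed fold changes must satisfy |fc| >= 1; offending value(s): ",
         paste(utils::head(fc[bad], 5L), collapse = ", "), call. = FALSE)
  }
  ifelse(fc > 0, fc - 1, fc + 1)
}

#' Additive expectation of two single-stress pEX values
#'
#' The null model for the combined response: the percent expression changes
#' under the two single stresses simply add.
#'
#' @param pex_h,pex_s Numeric vectors of percent expression changes (hypoxia
#'   and salt).
#' @return Numeric vector `pex_h + pex_s`.
#' @export
additive_expectation <- function(pex_h, pex_s) {
  if (!is.numeric(pex_h) || !is.numeric(pex_s)) {
    stop("pEX inputs must be numeric", call. = FALSE)
  }
  if ((length(pex_h) && any(!is.finite(pex_h))) ||
      (length(pex_s) && any(!is.finite(pex_s)))) {
    stop("pEX inputs must be finite", call. = FALSE)
  }
  pex_h + pex_s
}

#' Back-transform pEX to a log2 fold change
#'
#' Inverse of [percent_change()] composed with [signed_fold_change()]:
#' restores the signed linear FC (`pex + 1` for pex >= 0, `pex - 1` below)
#' and returns `sign(FC) * log2(|FC|)`. Used to place the additive
#' expectation on the log2FC axis of observed-vs-expected scatter plots.
#'
#' @param pex Numeric vector of percent expression changes.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' backtransform_pex(c(1, 0, -3))  # 1, 0, -2
#' @export
backtransform_pex <- function(pex) {
  if (!is.numeric(pex)) {
    stop("`pex` must be numeric", call. = FALSE)
  }
  if (length(pex) && any(!is.finite(pex))) {
    stop("`pex` contains non-finite values", call. = FALSE)
  }
  fc <- ifelse(pex >= 0, pex + 1, pex - 1)
  sign(fc) * log2(abs(fc))
}

#' Classifier configuration
#'
#' @param tolerance Half-width of the additive band, in pEX units (which
#'   coincide with linear-FC units since pEX is FC shifted by 1). Default 0.5.
#' @param interval_closed If `TRUE` (default) a deviation of exactly
#'   `tolerance` is still additive (closed interval); if `FALSE` the band is
#'   open and boundary genes are enhanced/divergent.
#' @param mode `"directional"` (default): enhanced means the combined pEX lies
#'   *above* the additive expectation, divergent *below*, regardless of the
#'   sign of the responses — so a jointly down-regulated gene whose combined
#'   repression is stronger than the sum is *divergent*. `"magnitude"`
#'   classifies on `|pEX|` instead (enhanced = larger absolute response than
#'   `|expectation|`); provided for exploratory use only and never used for
#'   the standard directional output.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(tolerance = 0.5, interval_closed = TRUE,
                              mode = c("directional", "magnitude")) {
  mode <- match.arg(mode)
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      !is.finite(tolerance) || tolerance <= 0) {
    stop("`tolerance` must be a single positive number", call. = FALSE)
  }
  structure(
    list(tolerance = tolerance,
         interval_closed = isTRUE(interval_closed),
         mode = mode),
    class = "classifier_config"
  )
}

interaction_labels <- c("additive", "enhanced", "divergent")

#' Classify combined responses against the additive expectation
#'
#' Labels each observation *additive* when the combined pEX falls within
#' `tolerance` of the expectation, *enhanced* when above the band, and
#' *divergent* when below. No epsilon fuzz is applied at the boundary: with
#' a closed interval a deviation of exactly `tolerance` is additive and any
#' strictly larger deviation is not.
#'
#' @param pex_hs Numeric vector, combined-stress percent expression change.
#' @param expectation Numeric vector, additive expectation
#'   (see [additive_expectation()]).
#' @param cfg A [classifier_config()].
#' @return Factor with levels additive, enhanced, divergent.
#' @examples
#' classify_interaction(c(2.3, 2.6, 1.4, 2.5), 2, classifier_config())
#' @export
classify_interaction <- function(pex_hs, expectation,
                                 cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  if ((length(pex_hs) && any(!is.finite(pex_hs))) ||
      (length(expectation) && any(!is.finite(expectation)))) {
    stop("classification inputs must be finite", call. = FALSE)
  }
  if (cfg$mode == "magnitude") {
    deviation <- abs(pex_hs) - abs(expectation)
  } else {
    deviation <- pex_hs - expectation
  }
  tol <- cfg$tolerance
  if (cfg$interval_closed) {
    lab <- ifelse(deviation > tol, "enhanced",
                  ifelse(deviation < -tol, "divergent", "additive"))
  } else {
    lab <- ifelse(deviation >= tol, "enhanced",
                  ifelse(deviation <= -tol, "divergent", "additive"))
  }
  factor(lab, levels = interaction_labels)
}
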