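#' Modified global mean (MOD) normalization
#'
#' Two centering passes on the Cq matrix: (a) center each target's values
#' around its own mean across samples, giving every target equal weight;
#' (b) center the result within each sample around the mean over expressed
#' targets -- optionally only over the targets expressed in every sample
#' (`commonOnly = TRUE`).  The per-sample step (b) means are the
#' normalization factors.  "Expressed" means uncensored: censored wells are
#' excluded from both passes unless `imputedValues` supplies replacements,
#' in which case the completed cells take part like expressed ones.
#'
#' @param object a [CqExperiment-class], or a plain numeric matrix (targets
#'   in rows) in which `NA` marks unexpressed cells.
#' @param commonOnly restrict step (b) to targets expressed in all samples.
#' @param imputedValues optional matrix of the same dimensions supplying
#'   values for censored cells.
#' @return A list with `normalized` (matrix, NA where unexpressed) and
#'   `factors` (named per-sample numeric vector with a `method` attribute).
#' @export
modNormalize <- function(object, commonOnly = FALSE, imputedValues = NULL) {
  if (is(object, "CqExperiment")) {
    mat <- cqValues(object)
    cen <- isCensored(object)
    mat[which(cen)] <- NA
    if (!is.null(imputedValues)) {
      stopifnot(identical(dim(imputedValues), dim(mat)))
      idx <- which(cen & !is.na(imputedValues))
      mat[idx] <- imputedValues[idx]
    }
  } else {
    mat <- as.matrix(object)
    if (!is.null(imputedValues)) {
      idx <- which(is.na(mat) & !is.na(imputedValues))
      mat[idx] <- imputedValues[idx]
    }
  }
  if (nrow(mat) < 2L) stop("MOD normalization needs at least 2 targets")
  a <- mat - rowMeans(mat, na.rm = TRUE)
  if (commonOnly) {
    common <- rowSums(is.na(a)) == 0L
    if (!any(common))
      stop("no target is expressed in every sample")
    factors <- colMeans(a[common, , drop = FALSE])
  } else {
    factors <- colMeans(a, na.rm = TRUE)
  }
  normalized <- sweep(a, 2L, factors)
  names(factors) <- colnames(mat)
  attr(factors, "method") <- if (commonOnly) "MOD_common" else "MOD"
  list(normalized = normalized, factors = factors)
}

#' Latent mean normalization (LMN) factors
#'
#' The per-sample effects of the unified model are normalization factors
#' estimated jointly with everything else, so censored wells inform them
#' through their likelihood contribution instead of being dropped or
#' imputed.  Under the global variant the factor of sample j is `beta_j`
#' plus the average interaction of j's group (global-mean normalization
#' attributes the group-average shift to the factors, mirroring what the
#' modified global mean absorbs), plus `mu` if `absolute = TRUE`.  Under
#' the reference-gene variant it is `mu + beta_j + zeta_j`.  With no
#' censoring and a common noise scale the global factors equal the MOD
#' factors up to one additive constant.
#'
#' @param fit a converged [UCNRFit-class].
#' @param absolute include the intercept (global variant).
#' @return Named per-sample numeric vector with a `method` attribute.
#' @export
lmnFactors <- function(fit, absolute = FALSE) {
  if (!fit@converged) stop("fit did not converge; factors unavailable")
  co <- ucnrCoef(fit)
  d <- fit@design
  if (fit@spec@variant == "reference") {
    f <- co$mu + co$beta + co$zeta
  } else {
    gbar <- colMeans(co$gamma[!d$is_reference, , drop = FALSE])
    f <- co$beta + gbar[d$group_of_sample] + if (absolute) co$mu else 0
  }
  grp <- groupLabels(fit@data)
  if (any(table(grp) < 2L))
    attr(f, "low_information") <- TRUE
  attr(f, "method") <- "LMN"
  f
}
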