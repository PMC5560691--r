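#' CqExperiment: a container for qPCR quantification-cycle data
#'
#' `CqExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' two assays: `cq`, the observed quantification cycles (targets in rows,
#' samples in columns), and `censored`, a logical matrix flagging wells whose
#' reaction never crossed the detection threshold before the limit of
#' detection (LOD).  Censored wells store the LOD itself as their `cq` value,
#' reflecting that an undetermined reaction is only known to satisfy
#' Cq >= LOD.  Wells that are missing for technical reasons unrelated to
#' expression level (e.g. a failed pipetting step) are `NA` in both assays
#' and excluded from all likelihoods.
#'
#' Column metadata must contain a `group` factor (the experimental groups
#' being compared); row metadata may contain a logical `is_reference` flag
#' marking reference genes used by the reference-gene model variant.
#' The LOD is stored in `metadata(x)$lod`; simulated data may carry a
#' `metadata(x)$truth` list with the generating parameters.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [CqExperiment()] for the constructor, [readCqTable()] to import
#'   instrument exports.
#' @export
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("cq", "censored") %in% an))
    return("assays 'cq' and 'censored' are required")
  cq <- SummarizedExperiment::assay(object, "cq")
  cen <- SummarizedExperiment::assay(object, "censored")
  if (!is.numeric(cq)) msg <- c(msg, "'cq' assay must be numeric")
  if (!is.logical(cen)) msg <- c(msg, "'censored' assay must be logical")
  if (!identical(is.na(cq), is.na(cen)))
    msg <- c(msg, "missing wells must be NA in both 'cq' and 'censored'")
  lod <- S4Vectors::metadata(object)$lod
  if (is.null(lod) || !is.numeric(lod) || length(lod) != 1L || is.na(lod) ||
      lod <= 0)
    msg <- c(msg, "metadata(x)$lod must be a single positive number")
  else if (is.logical(cen) && is.numeric(cq)) {
    obs <- !is.na(cen)
    if (any(obs & !cen & cq >= lod, na.rm = TRUE))
      msg <- c(msg, "uncensored cq values must be strictly below the LOD")
    if (any(obs & cen & cq != lod, na.rm = TRUE))
      msg <- c(msg, "censored cq values must be stored at the LOD")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData(x)$group is required")
  if (is.null(msg)) TRUE else msg
})

#' Model specification for the unified censored normal regression
#'
#' Chooses between the global variant (sample effects carry the
#' normalization factor; all targets get target-by-group interactions) and
#' the reference-gene variant (reference genes carry per-sample
#' normalization effects and are assumed non-differential, so only targets
#' of interest get interactions).
#'
#' @slot variant `"global"` or `"reference"`.
#' @slot heteroskedastic logical; per-target noise standard deviations
#'   (default) or a single common one.
#' @slot removalThreshold fraction in (0, 1]; targets whose overall censoring
#'   fraction reaches this value are removed before fitting.
#' @seealso [modelSpec()], [fitUCNR()]
#' @export
setClass("ModelSpec",
         representation(variant = "character",
                        heteroskedastic = "logical",
                        removalThreshold = "numeric"))

setValidity("ModelSpec", function(object) {
  msg <- NULL
  if (!object@variant %in% c("global", "reference"))
    msg <- c(msg, "variant must be 'global' or 'reference'")
  if (length(object@removalThreshold) != 1L ||
      object@removalThreshold <= 0 || object@removalThreshold > 1)
    msg <- c(msg, "removalThreshold must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ModelSpec-class Constructor.
#' @param variant model variant, `"global"` or `"reference"`.
#' @param heteroskedastic logical, per-target noise SDs.
#' @param removalThreshold censoring fraction at which a target is dropped.
#' @return A `ModelSpec` object.
#' @export
modelSpec <- function(variant = c("global", "reference"),
                      heteroskedastic = TRUE,
                      removalThreshold = 0.8) {
  new("ModelSpec", variant = match.arg(variant),
      heteroskedastic = isTRUE(heteroskedastic),
      removalThreshold = removalThreshold)
}

#' Maximum-likelihood fit of the unified censored normal regression
#'
#' Returned by [fitUCNR()].  Holds the free-parameter estimates under the
#' package's full-rank coding, the maximized censored log-likelihood, the
#' covariance matrix of the free parameters (inverse observed information),
#' convergence diagnostics, and the (possibly reduced) dataset the model was
#' fitted to.
#'
#' @slot theta named numeric vector of free parameters (mean parameters
#'   followed by log noise scales).
#' @slot design list describing the observation-to-parameter incidence;
#'   see [buildDesign()].
#' @slot spec the [ModelSpec-class] used.
#' @slot loglik maximized censored log-likelihood.
#' @slot vcov covariance matrix over the free parameters.
#' @slot converged logical convergence flag.
#' @slot niter number of optimizer iterations.
#' @slot gradnorm infinity norm of the score at the reported optimum.
#' @slot data the `CqExperiment` actually fitted (after removal rule).
#' @slot removed data.frame of targets removed by the censoring threshold,
#'   with per-group censored counts.
#' @slot notes character vector of per-target warnings (e.g. a group fully
#'   censored, a noise SD at its lower bound).
#' @export
setClass("UCNRFit",
         representation(theta = "numeric", design = "list",
                        spec = "ModelSpec", loglik = "numeric",
                        vcov = "matrix", converged = "logical",
                        niter = "integer", gradnorm = "numeric",
                        data = "CqExperiment", removed = "data.frame",
                        notes = "character"))

setMethod("show", "UCNRFit", function(object) {
  d <- object@design
  cat("UCNRFit (unified censored normal regression)\n")
  cat(sprintf("  variant: %s; targets: %d; samples: %d; groups: %d\n",
              object@spec@variant, d$I, d$J, d$K))
  cat(sprintf("  observations: %d (%d censored)\n",
              nrow(d$obs), sum(d$obs$cens)))
  cat(sprintf("  log-likelihood: %.4f; converged: %s (|grad|_inf = %.2e)\n",
              object@loglik, object@converged, object@gradnorm))
  if (nrow(object@removed))
    cat(sprintf("  removed targets (censoring >= %.0f%%): %s\n",
                100 * object@spec@removalThreshold,
                paste(object@removed$target_id, collapse = ", ")))
  if (length(object@notes))
    cat("  notes:", length(object@notes), "warning(s); see notes slot\n")
  invisible(NULL)
})

setMethod("show", "CqExperiment", function(object) {
  callNextMethod()
  cen <- SummarizedExperiment::assay(object, "censored")
  cat(sprintf("lod: %s; censored: %d/%d wells (%.1f%%)\n",
              format(S4Vectors::metadata(object)$lod),
              sum(cen, na.rm = TRUE), sum(!is.na(cen)),
              100 * mean(cen, na.rm = TRUE)))
  invisible(NULL)
})
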