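#' Simulate a two-group qPCR experiment from the latent linear model
#'
#' Draws latent Cq values from the model underlying the unified analysis:
#' per-target baselines spread over the typical miRNA Cq range, per-sample
#' technical shifts (the true normalization factors, centered within each
#' group so they match the model's estimand), per-target noise scales, and
#' injected log2 fold changes on a subset of targets, split equally between
#' up- and downregulation.  The defaults mirror a two-group study of 61
#' samples (39 + 22) on 50 targets with 20 altered targets at |delta| = 2
#' (a linear fold change of 4).  The generated data are fully observed
#' (LOD = Inf); apply [censorAtLod()] or [censorAtFraction()] to introduce
#' undetermined values.
#'
#' The true parameter values are stored in `metadata(x)$truth`:
#' `delta` (per target, on the `mean(group 1) - mean(group 2)` scale used by
#' [deltaContrasts()]), `beta`, `sigma`, `base`, and the group roles.
#'
#' @param nTargets number of targets I.
#' @param groupSizes named integer vector of samples per group (two groups).
#' @param nDE number of differentially expressed targets (half up, half
#'   down; DE targets are chosen at random).
#' @param delta absolute log2 fold change of DE targets, in cycles.
#' @param targetRange range of per-target baseline Cq values (uniform).
#' @param betaSD standard deviation of the per-sample technical shifts.
#' @param sigmaRange range of per-target noise SDs (uniform draw), ignored
#'   when `sigma` is given.
#' @param sigma optional per-target noise SDs (scalar or length `nTargets`).
#' @param nReference number of additional reference genes appended (not DE,
#'   flagged in rowData; for the reference-gene variant).
#' @param seed optional RNG seed for reproducibility.
#' @return A fully observed [CqExperiment-class] with truth metadata.
#' @examples
#' sim <- simulateCqExperiment(nTargets = 10, groupSizes = c(A = 5, B = 5),
#'                             nDE = 2, seed = 7)
#' metadata(sim)$truth$delta
#' @export
simulateCqExperiment <- function(nTargets = 50,
                                 groupSizes = c(A = 39, B = 22),
                                 nDE = 20, delta = 2,
                                 targetRange = c(24, 34), betaSD = 0.8,
                                 sigmaRange = c(0.3, 1.2), sigma = NULL,
                                 nReference = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(groupSizes) == 2L, nDE <= nTargets)
  if (is.null(names(groupSizes))) names(groupSizes) <- c("A", "B")
  I <- nTargets + nReference
  J <- sum(groupSizes)
  grp <- factor(rep(names(groupSizes), groupSizes),
                levels = names(groupSizes))
  base <- runif(I, targetRange[1], targetRange[2])
  beta <- rnorm(J, 0, betaSD)
  for (g in levels(grp))                       # center within group: the
    beta[grp == g] <- beta[grp == g] - mean(beta[grp == g])  # estimand
  if (is.null(sigma)) sigma <- runif(I, sigmaRange[1], sigmaRange[2])
  sigma <- rep_len(sigma, I)
  deltas <- numeric(I)
  if (nDE > 0) {
    de <- sample(seq_len(nTargets), nDE)
    sign <- rep(c(1, -1), length.out = nDE)
    deltas[de] <- sign * delta
  }
  ## delta = mean(group 1) - mean(group 2) on the Cq scale: a positive
  ## delta lowers group 2's Cq (upregulation in group 2)
  shift <- outer(deltas, as.integer(grp == levels(grp)[2]))
  m <- outer(base, beta, "+") - shift
  eps <- matrix(rnorm(I * J, 0, sigma), I, J)   # sigma recycles by row
  cq <- m + eps
  tid <- c(paste0("target_", seq_len(nTargets)),
           if (nReference) paste0("ref_", seq_len(nReference)))
  rownames(cq) <- tid
  colnames(cq) <- paste0("sample_", seq_len(J))
  isref <- c(rep(FALSE, nTargets), rep(TRUE, nReference))
  names(deltas) <- names(base) <- names(sigma) <- tid
  names(beta) <- colnames(cq)
  CqExperiment(cq, group = grp, lod = Inf, isReference = isref,
               truth = list(delta = deltas, beta = beta, sigma = sigma,
                            base = base,
                            reference_group = levels(grp)[1],
                            comparison_group = levels(grp)[2]))
}

#' Equalize group means of every target (null data)
#'
#' Shifts one group of each target so that the MOD-normalized group means
#' coincide, producing a dataset in which no target is differentially
#' expressed while all other real-data structure is kept.  Because the two
#' centering passes couple targets and samples, the shift is applied
#' iteratively until the normalized group-mean difference of every target is
#' below 1e-12.
#'
#' @param object a fully observed [CqExperiment-class] (no censored wells).
#' @param shiftGroup the group whose values are shifted (default: second
#'   level).
#' @return A `CqExperiment` with equalized normalized group means and
#'   truth metadata with `delta = 0`.
#' @export
nullifyGroups <- function(object, shiftGroup = NULL) {
  if (any(isCensored(object), na.rm = TRUE))
    stop("nullifyGroups is defined on fully observed data")
  grp <- groupLabels(object)
  if (nlevels(grp) != 2L) stop("exactly two groups required")
  if (is.null(shiftGroup)) shiftGroup <- levels(grp)[2]
  cq <- cqValues(object)
  js <- which(grp == shiftGroup)
  jo <- which(grp != shiftGroup)
  for (it in 1:200) {
    nm <- modNormalize(cq)$normalized
    d <- rowMeans(nm[, js, drop = FALSE], na.rm = TRUE) -
      rowMeans(nm[, jo, drop = FALSE], na.rm = TRUE)
    if (max(abs(d), na.rm = TRUE) < 1e-12) break
    cq[, js] <- cq[, js] - d
  }
  truth <- S4Vectors::metadata(object)$truth
  if (is.null(truth)) truth <- list()
  truth$delta <- setNames(numeric(nrow(cq)), rownames(cq))
  CqExperiment(cq, group = grp, lod = lodValue(object),
               isReference = isReference(object), truth = truth)
}
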