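#' LOD imputation pipeline
#'
#' The first classical strategy for undetermined wells: impute them at the
#' limit of detection on the raw Cq scale, then MOD-normalize the completed
#' matrix (censored cells participate in both centering passes at the LOD).
#'
#' @param object a [CqExperiment-class].
#' @param commonOnly restrict the sample-centering pass to common targets.
#' @return The normalized completed matrix, with attribute `method = "LOD"`
#'   and the normalization factors in attribute `factors`.
#' @export
imputeLOD <- function(object, commonOnly = FALSE) {
  lodmat <- matrix(lodValue(object), nrow(object), ncol(object))
  n <- modNormalize(object, commonOnly = commonOnly, imputedValues = lodmat)
  out <- n$normalized
  attr(out, "method") <- "LOD"
  attr(out, "factors") <- n$factors
  out
}

#' Maximum normalized value + 1 imputation
#'
#' Fills each target's unexpressed cells of a normalized matrix with the
#' maximum of its expressed normalized values plus one cycle, preserving the
#' "worst observable" status of undetermined reactions (multiple
#' undetermined wells of a target become ties).
#'
#' @param normalized numeric matrix (targets in rows) with `NA` for
#'   unexpressed cells, e.g. `modNormalize(x)$normalized`.
#' @return The completed matrix with attribute `method = "MNV1"`.
#' @export
imputeMNV1 <- function(normalized) {
  x <- as.matrix(normalized)
  nas <- is.na(x)
  if (any(rowSums(!nas) == 0L))
    stop("fully censored target(s) must be removed before MNV+1 imputation: ",
         paste(rownames(x)[rowSums(!nas) == 0L], collapse = ", "))
  for (i in which(rowSums(nas) > 0L))
    x[i, nas[i, ]] <- max(x[i, !nas[i, ]]) + 1
  attr(x, "method") <- "MNV1"
  x
}

#' K-nearest-neighbour imputation
#'
#' Fills unexpressed cells of a normalized matrix with the average expressed
#' value of the target's nearest neighbours.  Distances between targets are
#' Euclidean over the samples where both are expressed, rescaled by
#' `sqrt(J / n_complete)` to be comparable across pairs with different
#' overlap.  For a cell (i, j) the k nearest targets expressed at sample j
#' are averaged; when fewer than k such targets exist, all available ones
#' are used with a warning, and an error is raised when none is.
#'
#' @param normalized numeric matrix (targets in rows) with `NA` for
#'   unexpressed cells.
#' @param k neighbour count (the classical default is 10).
#' @return The completed matrix with attributes `method = "KNN"`, `k`.
#' @export
imputeKNN <- function(normalized, k = 10L) {
  x <- as.matrix(normalized)
  I <- nrow(x); J <- ncol(x)
  stopifnot(k >= 1L)
  if (I < k + 1L) stop("KNN imputation needs at least k + 1 targets")
  nas <- is.na(x)
  todo <- which(rowSums(nas) > 0L)
  warned <- FALSE
  for (i in todo) {
    d2 <- rep(Inf, I)
    for (ii in seq_len(I)) {
      if (ii == i) next
      both <- !nas[i, ] & !nas[ii, ]
      nb <- sum(both)
      if (nb == 0L) next
      d2[ii] <- sum((x[i, both] - x[ii, both])^2) * J / nb
    }
    for (j in which(nas[i, ])) {
      avail <- which(!nas[, j] & is.finite(d2))
      if (!length(avail))
        stop("no expressed neighbour available for cell (",
             rownames(x)[i], ", ", colnames(x)[j], ")")
      if (length(avail) < k && !warned) {
        warning("fewer than k expressed neighbours for some cells; ",
                "using all available ones")
        warned <- TRUE
      }
      nn <- avail[order(d2[avail])][seq_len(min(k, length(avail)))]
      x[i, j] <- mean(x[nn, j])
    }
  }
  attr(x, "method") <- "KNN"
  attr(x, "k") <- k
  x
}

#' Sequential per-target two-sample tests
#'
#' The classical pipeline's testing step: one two-sample test per target on
#' normalized (and imputed) values, with Benjamini-Hochberg adjustment
#' across targets.  The default is the pooled-variance t-test (matching the
#' one-noise-scale-per-target model); `test = "wilcoxon"` uses the rank-sum
#' test with the tie-corrected normal approximation, and
#' `welch = TRUE` switches the t-test to unequal variances.
#'
#' @param imputed numeric matrix (targets x samples) without unexpressed
#'   cells for the targets to be tested.
#' @param group per-sample group factor.
#' @param test `"t"` or `"wilcoxon"`.
#' @param comparison `c(reference_group, comparison_group)`; the estimate is
#'   `mean(reference) - mean(comparison)` on the normalized scale, i.e. a
#'   log2 fold change with the same sign convention as [testDE()].
#' @param welch use the Welch t-test instead of pooled variances.
#' @return A data.frame with columns `target_id`, `delta_hat`, `se`,
#'   `stat`, `p_value`, `p_adj`.
#' @export
sequentialTest <- function(imputed, group, test = c("t", "wilcoxon"),
                           comparison = NULL, welch = FALSE) {
  test <- match.arg(test)
  x <- as.matrix(imputed)
  group <- factor(group)
  if (is.null(comparison)) comparison <- levels(group)[1:2]
  if (!all(comparison %in% levels(group)))
    stop("comparison must name two existing groups")
  jref <- which(group == comparison[1])
  jalt <- which(group == comparison[2])
  if (length(jref) < 2L || length(jalt) < 2L)
    stop("each group needs at least 2 samples")
  out <- data.frame(target_id = rownames(x), delta_hat = NA_real_,
                    se = NA_real_, stat = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(x))) {
    a <- x[r, jref]; b <- x[r, jalt]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) next
    out$delta_hat[r] <- mean(a) - mean(b)
    if (sd(a) == 0 && sd(b) == 0) {
      warning("zero variance in both groups for target ", rownames(x)[r])
      out$p_value[r] <- 1
      out$stat[r] <- 0
      next
    }
    if (test == "t") {
      tt <- t.test(a, b, var.equal = !welch)
      out$stat[r] <- unname(tt$statistic)
      out$p_value[r] <- tt$p.value
      out$se[r] <- unname(tt$stderr)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                         correct = FALSE))
      out$stat[r] <- unname(wt$statistic)
      out$p_value[r] <- wt$p.value
    }
  }
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adj[ok] <- bhAdjust(out$p_value[ok])
  out
}

#' Run a full sequential baseline pipeline
#'
#' Convenience wrapper chaining the removal rule, MOD normalization, one of
#' the three imputation strategies and [sequentialTest()].
#'
#' @param object a [CqExperiment-class].
#' @param method `"LOD"`, `"MNV1"` or `"KNN"`.
#' @param test `"t"` or `"wilcoxon"`.
#' @param k neighbour count for KNN.
#' @param comparison `c(reference_group, comparison_group)`.
#' @param commonOnly see [modNormalize()].
#' @param removalThreshold censoring fraction at which targets are dropped
#'   before the analysis.
#' @param welch use Welch instead of pooled t.
#' @return A data.frame as from [sequentialTest()], with attribute
#'   `removed` listing dropped targets.
#' @export
baselineDE <- function(object, method = c("LOD", "MNV1", "KNN"),
                       test = c("t", "wilcoxon"), k = 10L,
                       comparison = NULL, commonOnly = FALSE,
                       removalThreshold = 0.8, welch = FALSE) {
  method <- match.arg(method)
  rm <- removeHeavilyCensored(object, removalThreshold)
  dat <- rm$data
  imp <- switch(method,
    LOD = imputeLOD(dat, commonOnly = commonOnly),
    MNV1 = imputeMNV1(modNormalize(dat, commonOnly = commonOnly)$normalized),
    KNN = imputeKNN(modNormalize(dat, commonOnly = commonOnly)$normalized,
                    k = k))
  res <- sequentialTest(imp, groupLabels(dat), test = test,
                        comparison = comparison, welch = welch)
  attr(res, "removed") <- rm$removed
  attr(res, "method") <- method
  res
}
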