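#' Data-driven selection of the limit of detection
#'
#' The censoring threshold matters: set too high, late-cycle noise (values
#' that do not come from genuine amplification) contaminates the fit; set
#' too low, informative observations are discarded.  For each candidate LOD
#' the dataset is re-censored at that value and the unified model refitted;
#' candidates are then compared by a cross-validated log-likelihood: wells
#' are split into folds, the model is refitted with each fold held out
#' (held-out wells become missing, not censored), and the held-out wells of
#' a fixed evaluation set -- those whose raw Cq lies strictly below the
#' smallest candidate, hence expressed under every candidate -- are scored
#' by their normal log-density under the fitted means and noise scales.
#' Scoring identical held-out observations for every candidate makes fits
#' with different censored counts directly comparable: candidates above the
#' true boundary admit noise into the likelihood and predict worse, while
#' candidates below it waste data and predict less precisely.  Without
#' cross-validation an in-sample version of this score is maximized by the
#' smallest candidate (the fit concentrates on the very observations being
#' scored), so held-out evaluation is the default; the criterion remains
#' pluggable via `criterion`.
#'
#' @param object a [CqExperiment-class] holding the raw values (wells
#'   already undetermined in the input stay censored under every candidate).
#' @param candidates numeric vector of at least two candidate LODs, within
#'   the upper region of the observed Cq range.
#' @param spec a [ModelSpec-class].
#' @param folds number of cross-validation folds (default 5); `folds = 1`
#'   scores in-sample (not recommended, see above).
#' @param criterion optional function `(fit, data, evalIndex) -> numeric`
#'   returning the mean log-score of the wells in the logical targets x
#'   samples mask `evalIndex`; larger is better.
#' @return A list of class `ucnr_lod_profile` with `profile` (data.frame of
#'   `lod`, `criterion`, `n_censored`, `skipped`) and `selected` (the
#'   maximizing candidate).
#' @examples
#' sim <- simulateCqExperiment(nTargets = 6, groupSizes = c(A = 10, B = 10),
#'                             nDE = 0, targetRange = c(28, 36), seed = 3)
#' dat <- censorAtLod(sim, 40)
#' \donttest{prof <- selectLod(dat, candidates = c(36, 38, 40))}
#' @export
selectLod <- function(object, candidates, spec = modelSpec(), folds = 5L,
                      criterion = NULL) {
  if (length(candidates) < 2L)
    stop("at least two candidate LOD values are required")
  candidates <- as.numeric(candidates)
  if (any(candidates > lodValue(object)))
    stop("candidates cannot exceed the current LOD")
  cq <- cqValues(object)
  evalmask <- !is.na(cq) & !isCensored(object) & cq < min(candidates)
  if (!any(evalmask))
    stop("no observation lies below the smallest candidate")
  if (is.null(criterion)) criterion <- lodCriterionDensity
  wells <- which(!is.na(cq))
  foldid <- sample(rep_len(seq_len(folds), length(wells)))
  prof <- data.frame(lod = candidates, criterion = NA_real_,
                     n_censored = NA_integer_, skipped = FALSE)
  for (r in seq_along(candidates)) {
    L <- candidates[r]
    dat <- censorAtLod(object, L)
    prof$n_censored[r] <- sum(isCensored(dat), na.rm = TRUE)
    res <- tryCatch({
      if (folds == 1L) {
        fit <- fitUCNR(dat, spec, hessian = FALSE)
        criterion(fit, dat, evalmask)
      } else {
        scores <- numeric(0)
        weights <- numeric(0)
        for (f in seq_len(folds)) {
          hold <- wells[foldid == f]
          emask <- matrix(FALSE, nrow(cq), ncol(cq),
                          dimnames = dimnames(cq))
          emask[hold] <- TRUE
          emask <- emask & evalmask
          if (!any(emask)) next
          train <- dat
          a <- SummarizedExperiment::assay(train, "cq")
          b <- SummarizedExperiment::assay(train, "censored")
          a[hold] <- NA
          b[hold] <- NA
          SummarizedExperiment::assay(train, "cq") <- a
          SummarizedExperiment::assay(train, "censored") <- b
          fit <- fitUCNR(train, spec, hessian = FALSE)
          scores <- c(scores, criterion(fit, dat, emask))
          weights <- c(weights, sum(emask))
        }
        sum(scores * weights) / sum(weights)
      }
    }, error = function(e) {
      warning("candidate LOD ", L, " skipped: ", conditionMessage(e))
      NA_real_
    })
    prof$criterion[r] <- res
    prof$skipped[r] <- is.na(res)
  }
  if (all(prof$skipped)) stop("every candidate was skipped")
  sel <- prof$lod[which.max(prof$criterion)]
  structure(list(profile = prof, selected = sel),
            class = "ucnr_lod_profile")
}

## mean log-density of the wells in evalIndex under the fitted model, with
## a residual-df correction of the ML noise scales
lodCriterionDensity <- function(fit, data, evalIndex) {
  m <- ucnrFitted(fit)
  co <- ucnrCoef(fit)
  d <- fit@design
  nu <- sum(!d$obs$cens)
  if (nu <= d$p_mean + 2L) return(NA_real_)
  corr <- sqrt(nu / (nu - d$p_mean))
  keep <- rownames(evalIndex) %in% rownames(m)
  evalIndex[!keep, ] <- FALSE
  if (!any(evalIndex)) return(NA_real_)
  idx <- which(evalIndex)
  tgt <- ((idx - 1L) %% nrow(evalIndex)) + 1L
  smp <- ((idx - 1L) %/% nrow(evalIndex)) + 1L
  map <- match(rownames(evalIndex), rownames(m))
  sig <- if (length(co$sigma) == 1L) rep(co$sigma, nrow(m)) else co$sigma
  sig <- sig * corr
  y <- cqValues(data)[idx]
  mm <- m[cbind(map[tgt], smp)]
  ss <- sig[map[tgt]]
  ok <- is.finite(mm)
  if (!any(ok)) return(NA_real_)
  mean(dnorm(y[ok], mm[ok], ss[ok], log = TRUE))
}

#' @export
print.ucnr_lod_profile <- function(x, ...) {
  cat("LOD selection profile\n")
  print(x$profile, row.names = FALSE)
  cat("selected LOD:", x$selected, "\n")
  invisible(x)
}
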