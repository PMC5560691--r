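#' Censoring-sweep comparison of analysis methods
#'
#' Starting from a fully observed dataset, the sweep repeatedly censors the
#' current maximum uncensored Cq value (ties at the maximum are censored
#' together, so the LOD stays a strict upper bound for the expressed
#' values), producing a stepwise decreasing LOD.  At evaluated steps every
#' configured method is re-run -- the unified censored regression, and the
#' sequential pipelines with LOD, MNV+1 or KNN imputation -- and per-target
#' estimates and p-values are recorded.  Targets whose censoring fraction
#' reaches `removalThreshold` are removed from the study (for all methods)
#' and logged.  A method failing at a step is recorded as missing for that
#' step and the sweep continues.
#'
#' Refitting every method at each of up to thousands of steps is the full
#' design; `stride` evaluates every stride-th step instead for desk-scale
#' runs.
#'
#' @param object a fully observed [CqExperiment-class] (typically simulated,
#'   with truth metadata).
#' @param methods subset of `c("UCNR", "LOD", "MNV1", "KNN")`.
#' @param stride evaluate every stride-th censoring step (step 0, the
#'   uncensored state, is always evaluated).
#' @param maxCensoredFraction stop once the overall censored fraction
#'   exceeds this value.
#' @param removalThreshold per-target censoring fraction triggering removal.
#' @param k KNN neighbour count.
#' @param test sequential test type, `"t"` or `"wilcoxon"`.
#' @param comparison `c(reference_group, comparison_group)`.
#' @param spec [ModelSpec-class] for the unified fits (removal threshold is
#'   taken from `removalThreshold`, not from `spec`).
#' @return A long data.frame of class `ucnr_sweep`: one row per evaluated
#'   step x method x target with `step`, `lod`, `n_censored`, `method`,
#'   `target_id`, `delta_hat`, `p_value`, `censored_fraction` (per target)
#'   and `removed`.  Attributes: `truth`, `alpha`-free; see
#'   [sweepSummary()] and [robustnessProportion()].
#' @export
censoringSweep <- function(object,
                           methods = c("UCNR", "LOD", "MNV1", "KNN"),
                           stride = 1L, maxCensoredFraction = 0.35,
                           removalThreshold = 0.8, k = 10L,
                           test = "t", comparison = NULL,
                           spec = modelSpec()) {
  methods <- match.arg(methods, c("UCNR", "LOD", "MNV1", "KNN"),
                       several.ok = TRUE)
  if (any(isCensored(object), na.rm = TRUE))
    stop("the sweep starts from a fully observed dataset")
  spec@removalThreshold <- removalThreshold
  vals <- cqValues(object)
  obs <- sort(unique(vals[!is.na(vals)]), decreasing = TRUE)
  ntot <- sum(!is.na(vals))
  ncen_at <- vapply(obs, function(v) sum(vals >= v, na.rm = TRUE), numeric(1))
  keep_steps <- which(ncen_at / ntot <= maxCensoredFraction)
  last <- if (length(keep_steps)) max(keep_steps) else 0L
  eval_steps <- unique(c(0L, seq_len(last)[seq_len(last) %% stride == 0L],
                         last))
  eval_steps <- sort(eval_steps)
  grp <- groupLabels(object)
  if (is.null(comparison)) comparison <- levels(grp)[1:2]

  rows <- vector("list", length(eval_steps) * length(methods))
  ri <- 0L
  for (s in eval_steps) {
    if (s == 0L) {
      dat <- object
      lod_s <- lodValue(object)
    } else {
      lod_s <- obs[s]
      dat <- censorAtLod(object, lod_s)
    }
    frac <- censoredFraction(dat, "target")
    removed <- names(frac)[frac >= removalThreshold]
    ncen <- sum(isCensored(dat), na.rm = TRUE)
    for (meth in methods) {
      est <- tryCatch({
        if (meth == "UCNR") {
          fit <- fitUCNR(dat, spec)
          de <- testDE(fit, comparison)
          de[, c("target_id", "delta_hat", "p_value")]
        } else {
          de <- suppressWarnings(
            baselineDE(dat, method = meth, test = test,
                       comparison = comparison, k = k,
                       removalThreshold = removalThreshold))
          de[, c("target_id", "delta_hat", "p_value")]
        }
      }, error = function(e) NULL)
      all_t <- rownames(object)
      row <- data.frame(step = s, lod = lod_s, n_censored = ncen,
                        method = meth, target_id = all_t,
                        delta_hat = NA_real_, p_value = NA_real_,
                        censored_fraction = unname(frac[all_t]),
                        removed = all_t %in% removed,
                        stringsAsFactors = FALSE)
      if (!is.null(est)) {
        m <- match(row$target_id, est$target_id)
        row$delta_hat <- est$delta_hat[m]
        row$p_value <- est$p_value[m]
      }
      ri <- ri + 1L
      rows[[ri]] <- row
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  attr(out, "truth") <- S4Vectors::metadata(object)$truth
  attr(out, "comparison") <- comparison
  class(out) <- c("ucnr_sweep", "data.frame")
  out
}

#' Bias and RMSE along a censoring sweep
#'
#' Scores the per-step estimates of a [censoringSweep()] against the true
#' log2 fold changes stored with the simulated data: per step and method,
#' the mean of `delta_hat - delta_true` (bias) and the root mean squared
#' error over the targets still in the study.
#'
#' @param trace a `ucnr_sweep` object with truth metadata.
#' @return A data.frame with `step`, `lod`, `n_censored`, `method`,
#'   `n_targets`, `bias`, `rmse`.
#' @export
sweepSummary <- function(trace) {
  truth <- attr(trace, "truth")
  if (is.null(truth)) stop("the sweep carries no truth metadata")
  delta <- truth$delta
  keep <- !trace$removed & !is.na(trace$delta_hat)
  tr <- trace[keep, , drop = FALSE]
  err <- tr$delta_hat - delta[tr$target_id]
  key <- interaction(tr$step, tr$method, drop = TRUE)
  agg <- data.frame(step = tapply(tr$step, key, `[`, 1),
                    lod = tapply(tr$lod, key, `[`, 1),
                    n_censored = tapply(tr$n_censored, key, `[`, 1),
                    method = tapply(as.character(tr$method), key, `[`, 1),
                    n_targets = as.vector(tapply(err, key, length)),
                    bias = as.vector(tapply(err, key, mean)),
                    rmse = as.vector(tapply(err, key,
                                            function(e) sqrt(mean(e^2)))),
                    row.names = NULL, stringsAsFactors = FALSE)
  agg[order(agg$method, agg$step), ]
}

#' Robustness proportion of a hypothesis test under censoring
#'
#' The fraction of a truly differentially expressed target's observations
#' that can be censored before the method's test first fails to reject at
#' level `alpha` (a type II error).  If the test still rejects at every
#' evaluated step at which the target is present, the proportion is the
#' target's censored fraction at its last step in the study.
#'
#' @param trace a `ucnr_sweep` from [censoringSweep()].
#' @param target target id (must be truly DE when truth is available).
#' @param method one of the sweep's methods.
#' @param alpha significance level (raw p-values, default 0.05).
#' @return A fraction in \[0, 1\].
#' @export
robustnessProportion <- function(trace, target, method, alpha = 0.05) {
  truth <- attr(trace, "truth")
  if (!is.null(truth) && truth$delta[target] == 0)
    stop("target ", target, " is not differentially expressed: ",
         "a type II error is undefined")
  tr <- trace[trace$target_id == target & trace$method == method &
                !trace$removed, , drop = FALSE]
  tr <- tr[order(tr$step), , drop = FALSE]
  ## steps at which the method itself failed are missing, not acceptances
  tr <- tr[!is.na(tr$p_value), , drop = FALSE]
  if (!nrow(tr)) stop("no sweep records for this target/method")
  fail <- which(tr$p_value > alpha)
  if (length(fail)) tr$censored_fraction[fail[1]]
  else min(tr$censored_fraction[nrow(tr)], 1)
}

#' Plot bias or RMSE curves of a censoring sweep
#'
#' @param trace a `ucnr_sweep`.
#' @param what `"bias"` or `"rmse"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plotSweep <- function(trace, what = c("bias", "rmse")) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSweep requires ggplot2")
  s <- sweepSummary(trace)
  s$value <- s[[what]]
  ggplot2::ggplot(s, ggplot2::aes(x = n_censored, y = value,
                                  colour = method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "censored Cq values", y = what, colour = "method")
}
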