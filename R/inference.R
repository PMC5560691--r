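#' Per-target log2 fold-change contrasts
#'
#' The log2 fold change of target i between two groups is a linear contrast
#' of the latent means (one Cq cycle corresponds to one log2 expression
#' unit, with lower Cq meaning higher expression), measured relative to the
#' normalization the model variant implies.  Under the global variant the
#' normalization factor is the per-sample global mean, so a group-level
#' shift common to all targets is technical by assumption and
#' \eqn{\delta_i} is the target's group difference centered over targets:
#' with no censoring it reduces exactly to the group-mean difference of
#' MOD-normalized values.  Under the reference-gene variant the per-sample
#' factor is anchored by the reference genes, and \eqn{\delta_i} is the
#' target's group difference in excess of the reference genes' group
#' difference.  Both are estimable functionals of the free parameters, so
#' estimates and standard errors do not depend on the identifiability
#' coding.  The sign convention is
#' `delta = mean(reference group) - mean(comparison group)`, so a positive
#' delta means upregulation in the comparison group; `flip = TRUE` reverses
#' it.
#'
#' @param fit a converged [UCNRFit-class].
#' @param comparison character vector `c(reference_group, comparison_group)`;
#'   defaults to the first two group levels.
#' @param flip reverse the sign convention.
#' @param smallSample apply the residual-degrees-of-freedom correction
#'   `sqrt(N / (N - p))` to the standard errors; on by default, because the
#'   ML noise estimates divide by N and the uncorrected Wald test is
#'   mildly anticonservative at small sample sizes.  Set `FALSE` for the
#'   plain asymptotic standard errors.
#' @return A data.frame with columns `target_id`, `delta_hat`, `se`.
#' @export
deltaContrasts <- function(fit, comparison = NULL, flip = FALSE,
                           smallSample = TRUE) {
  if (!fit@converged)
    stop("fit did not converge; refusing to form contrasts")
  d <- fit@design
  comparison <- resolve_comparison(d, comparison)
  kref <- match(comparison[1], d$group_ids)
  kalt <- match(comparison[2], d$group_ids)
  targets <- which(!d$is_reference)
  pm <- seq_len(d$p_mean)
  Vm <- fit@vcov[pm, pm, drop = FALSE]
  eta <- fit@theta[pm]
  C <- matrix(NA_real_, length(targets), d$p_mean)
  for (r in seq_along(targets)) {
    i <- targets[r]
    rref <- which(d$obs$i == i & d$obs$k == kref)
    ralt <- which(d$obs$i == i & d$obs$k == kalt)
    if (!length(rref) || !length(ralt)) next
    C[r, ] <- Matrix::colMeans(d$X[rref, , drop = FALSE]) -
      Matrix::colMeans(d$X[ralt, , drop = FALSE])
  }
  ok <- !is.na(C[, 1L])
  if (fit@spec@variant == "reference") {
    ## excess over the reference genes' group difference (zeta contrast)
    zc <- numeric(d$p_mean)
    if (length(d$blocks$zeta)) {
      w <- ifelse(d$group_of_sample == kref,
                  1 / sum(d$group_of_sample == kref),
                  ifelse(d$group_of_sample == kalt,
                         -1 / sum(d$group_of_sample == kalt), 0))
      ## zeta_J = -sum(zeta_free): free zeta_j carries w_j - w_J
      zc[d$blocks$zeta] <- w[seq_len(d$J - 1L)] - w[d$J]
    }
    C[ok, ] <- sweep(C[ok, , drop = FALSE], 2L, zc)
  } else if (sum(ok) >= 2L) {
    ## centered over targets: the global-mean normalization attributes the
    ## average group difference to the per-sample factors (with a single
    ## target no normalization is defined and the raw difference is used)
    C[ok, ] <- sweep(C[ok, , drop = FALSE], 2L,
                     colMeans(C[ok, , drop = FALSE]))
  }
  est <- as.vector(C %*% eta)
  v <- rowSums((C %*% Vm) * C)
  se <- sqrt(pmax(v, 0))
  if (smallSample)
    se <- se * sqrt(nrow(d$obs) / (nrow(d$obs) - d$p_mean))
  data.frame(target_id = d$target_ids[targets],
             delta_hat = if (flip) -est else est,
             se = se, stringsAsFactors = FALSE)
}

resolve_comparison <- function(d, comparison) {
  if (is.null(comparison)) comparison <- d$group_ids[1:2]
  if (length(comparison) != 2L || !all(comparison %in% d$group_ids))
    stop("comparison must name two existing groups")
  comparison
}

#' Generalized Wald test for differential expression
#'
#' Tests H0: delta = 0 with the asymptotic standard normal reference for
#' `delta_hat / se` (maximum-likelihood asymptotics).  A finite-sample t
#' reference with explicit degrees of freedom is available via `df`.
#'
#' @param delta_hat estimate(s) of the log2 fold change.
#' @param se standard error(s), strictly positive.
#' @param df optional degrees of freedom for a t reference (default normal).
#' @return A data.frame with columns `wald_stat` and `p_value`.
#' @export
waldTest <- function(delta_hat, se, df = NULL) {
  if (any(!is.na(se) & se <= 0)) stop("degenerate fit: standard error is zero")
  stat <- delta_hat / se
  p <- if (is.null(df)) 2 * pnorm(-abs(stat)) else 2 * stats::pt(-abs(stat), df)
  data.frame(wald_stat = stat, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' False-coverage-rate adjusted fold-change intervals
#'
#' Confidence intervals reported only for targets selected at FDR level `q`
#' need widening to keep the expected proportion of non-covering intervals
#' among those selected below `q`.  Following the false coverage-statement
#' rate construction, with R of m targets selected each selected target gets
#' a (1 - R q / m) normal-theory interval for delta, transformed to the
#' fold-change scale as `(2^lo, 2^hi)`.  Unselected targets get `NA`
#' intervals.  With `reciprocal = TRUE` intervals of negative estimates are
#' reported on the reciprocal (fold-down) scale.
#'
#' @param delta_hat,se per-target estimates and standard errors.
#' @param p_adj BH-adjusted p-values (selection is `p_adj <= q`).
#' @param q FDR / FCR level (default 0.05).
#' @param reciprocal report fold-down intervals for negative estimates.
#' @return A data.frame with columns `fc_ci_low`, `fc_ci_high`.
#' @export
fcrAdjustedCI <- function(delta_hat, se, p_adj, q = 0.05,
                          reciprocal = FALSE) {
  m <- length(delta_hat)
  sel <- !is.na(p_adj) & p_adj <= q
  lo <- hi <- rep(NA_real_, m)
  R <- sum(sel)
  if (R > 0) {
    z <- qnorm(1 - R * q / (2 * m))
    dlo <- delta_hat[sel] - z * se[sel]
    dhi <- delta_hat[sel] + z * se[sel]
    if (reciprocal) {
      neg <- delta_hat[sel] < 0
      tmp <- dlo
      dlo[neg] <- -dhi[neg]
      dhi[neg] <- -tmp[neg]
    }
    lo[sel] <- 2^dlo
    hi[sel] <- 2^dhi
  }
  data.frame(fc_ci_low = lo, fc_ci_high = hi)
}

#' Differential expression table from a unified model fit
#'
#' Combines [deltaContrasts()], [waldTest()], [bhAdjust()] and
#' [fcrAdjustedCI()] into the standard per-target results table.
#'
#' @param fit a converged [UCNRFit-class].
#' @param comparison `c(reference_group, comparison_group)`.
#' @param q FDR level for adjustment and interval selection.
#' @param flip reverse the fold-change sign convention.
#' @param df optional degrees of freedom for a t reference.
#' @param reciprocal see [fcrAdjustedCI()].
#' @param smallSample see [deltaContrasts()].
#' @return A data.frame with columns `target_id`, `delta_hat`, `se`,
#'   `wald_stat`, `p_value`, `p_adj`, `fc` (`2^delta_hat`), `fc_ci_low`,
#'   `fc_ci_high` and `n_censored_per_group` (counts joined by "/" in group
#'   order of the comparison).
#' @export
testDE <- function(fit, comparison = NULL, q = 0.05, flip = FALSE,
                   df = NULL, reciprocal = FALSE, smallSample = TRUE) {
  d <- fit@design
  comparison <- resolve_comparison(d, comparison)
  dc <- deltaContrasts(fit, comparison, flip = flip,
                       smallSample = smallSample)
  ok <- !is.na(dc$se) & dc$se > 0
  wt <- data.frame(wald_stat = rep(NA_real_, nrow(dc)),
                   p_value = rep(NA_real_, nrow(dc)))
  wt[ok, ] <- waldTest(dc$delta_hat[ok], dc$se[ok], df = df)
  p_adj <- rep(NA_real_, nrow(dc))
  p_adj[ok] <- bhAdjust(wt$p_value[ok])
  ci <- fcrAdjustedCI(dc$delta_hat, dc$se, p_adj, q = q,
                      reciprocal = reciprocal)
  cen <- isCensored(fit@data)
  grp <- groupLabels(fit@data)
  ncen <- vapply(dc$target_id, function(t) {
    row <- cen[t, ]
    paste(vapply(comparison, function(g)
      sum(row[grp == g], na.rm = TRUE), numeric(1)), collapse = "/")
  }, character(1))
  data.frame(target_id = dc$target_id, delta_hat = dc$delta_hat, se = dc$se,
             wald_stat = wt$wald_stat, p_value = wt$p_value, p_adj = p_adj,
             fc = 2^dc$delta_hat, fc_ci_low = ci$fc_ci_low,
             fc_ci_high = ci$fc_ci_high, n_censored_per_group = ncen,
             row.names = NULL, stringsAsFactors = FALSE)
}
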