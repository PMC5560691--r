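#' Fit the unified censored normal regression by maximum likelihood
#'
#' Normalization and differential expression are estimated jointly from the
#' raw Cq values: undetermined wells enter the likelihood as right-censored
#' terms instead of being imputed.  Targets whose overall censoring fraction
#' reaches `spec@removalThreshold` are removed first (and recorded); every
#' remaining target must retain at least one expressed well.  Optimization
#' is quasi-Newton (L-BFGS-B) on an analytic gradient, started from a
#' least-squares fit of the LOD-imputed data, and polished with Newton steps
#' on the observed information.  Standard errors come from the inverse of
#' the observed information matrix (central-difference Hessian of the
#' negative log-likelihood at the optimum).
#'
#' When a target has no expressed well at all in one group, its interaction
#' with that group is only one-sidedly identified: the likelihood increases
#' monotonically as the group's latent mean grows, so the maximizer sits at
#' infinity and any finite value an optimizer stops at is arbitrary.  The
#' target stays in the fit (its censored wells still inform the sample
#' effects and its noise scale) with a note attached, and the reported
#' group mean is pinned at the plausibility boundary `LOD + z0 * sigma_i`,
#' with `z0 = qnorm(0.95^(1/n))` the smallest standardized excess under
#' which observing all `n` wells censored has probability at least 95%.
#' The observed information is evaluated on the unpenalized likelihood, so
#' such targets keep their honest (very large) standard errors.
#'
#' @param object a [CqExperiment-class].
#' @param spec a [ModelSpec-class].
#' @param hessian compute the observed-information covariance matrix
#'   (needed for Wald tests); set `FALSE` to skip it when only point
#'   estimates are required.
#' @param control list of optimizer settings: `maxit` (default 2000),
#'   `gtol` (gradient infinity-norm target, default 1e-6), `sigma_floor`
#'   (lower bound on the noise SD, default 0.05 cycles -- technical qPCR
#'   noise below a twentieth of a cycle is not measurable, and the
#'   unbounded heteroskedastic likelihood has degenerate spikes at
#'   sigma -> 0 that the floor keeps benign), `newton_steps` (maximum
#'   polish iterations, default 12).
#' @return A [UCNRFit-class] object.
#' @examples
#' sim <- simulateCqExperiment(nTargets = 8, groupSizes = c(A = 6, B = 6),
#'                             nDE = 2, seed = 1)
#' fit <- fitUCNR(censorAtFraction(sim, 0.2))
#' fit
#' @export
setMethod("fitUCNR", "CqExperiment", function(object, spec = modelSpec(),
                                              hessian = TRUE,
                                              control = list()) {
  ctrl <- modifyList(list(maxit = 2000L, gtol = 1e-6, sigma_floor = 0.05,
                          newton_steps = 12L), control)
  grp <- groupLabels(object)
  if (any(table(grp) < 2L))
    warning("group(s) with a single sample: estimates are low-information")

  rm <- removeHeavilyCensored(object, spec@removalThreshold)
  dat <- rm$data
  if (nrow(dat) == 0L) stop("all targets exceed the censoring threshold")
  notes <- character(0)
  cen <- isCensored(dat)
  nonc <- rowSums(!cen, na.rm = TRUE)
  if (any(nonc == 0L))
    stop("target(s) without any expressed observation after removal: ",
         paste(rownames(dat)[nonc == 0L], collapse = ", "))
  for (g in levels(grp)) {
    sub <- cen[, grp == g, drop = FALSE]
    full <- rowSums(!sub, na.rm = TRUE) == 0L & rowSums(sub, na.rm = TRUE) > 0L
    if (any(full))
      notes <- c(notes, paste0("target ", rownames(dat)[full],
                               ": group ", g, " fully censored"))
  }

  d <- buildDesign(dat, spec)
  ## initialization: LOD-imputed least squares (censored wells already sit
  ## at the LOD), per-target residual SD floored at 0.05 cycles
  XtX <- Matrix::crossprod(d$X)
  eta0 <- tryCatch(
    as.vector(Matrix::solve(XtX, Matrix::crossprod(d$X, d$obs$y))),
    error = function(e) stop("design is rank deficient: ", conditionMessage(e)))
  res <- d$obs$y - as.vector(d$X %*% eta0)
  lower <- c(rep(-Inf, d$p_mean), rep(log(ctrl$sigma_floor), d$n_sigma))
  niter <- 0L
  if (d$n_sigma > 1L) {
    ## stage 1: common-sigma fit.  The heteroskedastic likelihood has
    ## degenerate spikes (a target interpolated by the sample effects sends
    ## its sigma to zero); starting the per-target fit from the common-sigma
    ## optimum keeps the optimizer in the regular basin.
    dc <- d
    dc$n_sigma <- 1L
    dc$sigma_map <- rep(1L, nrow(d$obs))
    t0 <- c(eta0, log(max(sd(res), 0.05)))
    oc <- optim(t0, fn = ucnr_negll, gr = ucnr_neggrad, d = dc,
                method = "L-BFGS-B",
                lower = c(rep(-Inf, d$p_mean), log(ctrl$sigma_floor)),
                control = list(maxit = ctrl$maxit, factr = 1e6))
    eta0 <- oc$par[seq_len(d$p_mean)]
    niter <- niter + oc$counts[["function"]]
    res <- d$obs$y - as.vector(d$X %*% eta0)
    s_all <- max(sd(res), 0.05)
    rs <- vapply(seq_len(d$I), function(t) {
      r <- res[d$obs$i == t & !d$obs$cens]
      if (length(r) >= 2L) sd(r) else s_all
    }, numeric(1))
    rs[!is.finite(rs)] <- s_all
    ls0 <- log(pmax(rs, 0.05))
  } else {
    ls0 <- log(max(sd(res), 0.05))
  }
  theta0 <- c(eta0, ls0)

  opt <- optim(theta0, fn = ucnr_negll, gr = ucnr_neggrad, d = d,
               method = "L-BFGS-B", lower = lower,
               control = list(maxit = ctrl$maxit, factr = 1e6))
  theta <- opt$par
  niter <- niter + opt$counts[["function"]]

  ## one-sidedly identified cells: (target, group) with censored wells only
  pen <- NULL
  gi <- which(!d$is_reference)
  if (length(gi)) {
    cells <- do.call(rbind, lapply(gi, function(i) {
      do.call(rbind, lapply(seq_len(d$K), function(k) {
        rows <- d$obs$i == i & d$obs$k == k
        data.frame(i = i, k = k, n_unc = sum(rows & !d$obs$cens),
                   n_cen = sum(rows & d$obs$cens))
      }))
    }))
    flat <- cells[cells$n_unc == 0L & cells$n_cen > 0L, , drop = FALSE]
    if (nrow(flat)) {
      sig_hat <- exp(theta[d$p_mean + seq_len(d$n_sigma)])
      sig_of <- function(i) if (d$n_sigma == 1L) sig_hat else sig_hat[i]
      C <- matrix(0, nrow(flat), d$p_mean)
      mstar <- numeric(nrow(flat))
      for (r in seq_len(nrow(flat))) {
        rows <- which(d$obs$i == flat$i[r] & d$obs$k == flat$k[r])
        C[r, ] <- Matrix::colMeans(d$X[rows, , drop = FALSE])
        z0 <- qnorm(0.95^(1 / flat$n_cen[r]))
        mstar[r] <- d$lod + z0 * sig_of(flat$i[r])
        notes <- c(notes, paste0(
          "target ", d$target_ids[flat$i[r]], ": group ",
          d$group_ids[flat$k[r]], " fully censored; latent mean pinned ",
          "at the plausibility boundary ", format(mstar[r], digits = 5)))
      }
      pen <- list(C = C, mstar = mstar, w = 1e4)
    }
  }
  fn_obj <- function(th) {
    v <- ucnr_negll(th, d)
    if (!is.null(pen))
      v <- v + pen$w * sum((as.vector(pen$C %*% th[seq_len(d$p_mean)]) -
                              pen$mstar)^2)
    v
  }
  gr_obj <- function(th) {
    g <- ucnr_neggrad(th, d)
    if (!is.null(pen)) {
      r <- as.vector(pen$C %*% th[seq_len(d$p_mean)]) - pen$mstar
      g[seq_len(d$p_mean)] <- g[seq_len(d$p_mean)] +
        2 * pen$w * as.vector(crossprod(pen$C, r))
    }
    g
  }
  hess_obj <- function(th) {
    H <- ucnr_obsinfo(th, d)
    if (!is.null(pen)) {
      pm <- seq_len(d$p_mean)
      H[pm, pm] <- H[pm, pm] + 2 * pen$w * crossprod(pen$C)
    }
    H
  }
  if (!is.null(pen)) {
    opt <- optim(theta, fn = fn_obj, gr = gr_obj, method = "L-BFGS-B",
                 lower = lower,
                 control = list(maxit = ctrl$maxit, factr = 1e6))
    theta <- opt$par
    niter <- niter + opt$counts[["function"]]
  }
  nll <- fn_obj(theta)
  ## KKT projected gradient: components pinned at an active lower bound
  ## (sigma floor) legitimately carry an inward-pointing gradient
  proj <- function(th, g) {
    g[th <= lower + 1e-12 & g > 0] <- 0
    g
  }
  g <- gr_obj(theta)
  relchange <- Inf
  stalled <- FALSE
  if (hessian) {
    it <- 0L
    for (it in seq_len(ctrl$newton_steps)) {     # Newton polish
      if (max(abs(proj(theta, g))) <= ctrl$gtol) break
      H <- hess_obj(theta)
      ## Newton in the subspace of inactive bounds
      free <- !(theta <= lower + 1e-12 & g > 0)
      step <- numeric(length(theta))
      sf <- tryCatch(solve(H[free, free, drop = FALSE], g[free]),
                     error = function(e)
        tryCatch(solve(H[free, free, drop = FALSE] +
                         diag(1e-8 * (1 + abs(diag(H)[free])),
                              sum(free)), g[free]),
                 error = function(e2) NULL))
      if (is.null(sf)) { stalled <- TRUE; break }
      step[free] <- sf
      ## trust region: cap ill-determined steps
      if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
      lam <- 1
      repeat {
        cand <- pmax(theta - lam * step, lower)
        nl <- fn_obj(cand)
        if (is.finite(nl) && nl <= nll + 1e-12) break
        lam <- lam / 2
        if (lam < 1e-6) { cand <- theta; nl <- nll; break }
      }
      relchange <- abs(nl - nll) / (abs(nll) + 1)
      moved <- max(abs(cand - theta))
      theta <- cand; nll <- nl
      g <- gr_obj(theta)
      niter <- niter + 1L
      if (moved < 1e-10) { stalled <- TRUE; break }
    }
    if (it == ctrl$newton_steps &&
        max(abs(proj(theta, g))) > ctrl$gtol) stalled <- TRUE
    ## covariance from the unpenalized observed information: pinned
    ## directions keep their honest, large uncertainty.  Parameters held at
    ## an active bound (sigma floor) are treated as fixed -- through the
    ## bound the likelihood is not at a maximum, so no asymptotic variance
    ## exists for them -- and get zero rows/columns.
    Hv <- ucnr_obsinfo(theta, d)
    act <- theta <= lower + 1e-12
    V <- matrix(0, length(theta), length(theta))
    Vf <- tryCatch(solve(Hv[!act, !act, drop = FALSE]), error = function(e) {
      notes <<- c(notes, "observed information singular: pseudo-inverse used")
      MASS::ginv(Hv[!act, !act, drop = FALSE])
    })
    V[!act, !act] <- Vf
    V <- (V + t(V)) / 2
  } else {
    V <- matrix(NA_real_, length(theta), length(theta))
  }
  dimnames(V) <- list(d$par_names, d$par_names)
  names(theta) <- d$par_names

  gradnorm <- max(abs(proj(theta, g)))
  ## the strict gradient target is unreachable along near-flat directions
  ## (e.g. a group fully censored for one target): accept a small gradient
  ## when the polish has stalled or the likelihood has stopped moving
  converged <- (opt$convergence == 0L) &&
    (gradnorm <= ctrl$gtol ||
       (gradnorm <= 1e-4 && (relchange <= 1e-10 || stalled)) ||
       (!hessian && gradnorm <= 1e-3 * (1 + abs(nll))))
  atfloor <- exp(theta[d$p_mean + seq_len(d$n_sigma)]) <=
    ctrl$sigma_floor * (1 + 1e-8)
  if (any(atfloor)) {
    which_t <- if (d$n_sigma == d$I) d$target_ids[atfloor] else "common"
    notes <- c(notes, paste0("sigma at lower bound for: ",
                             paste(which_t, collapse = ", ")))
    warning("noise SD at its lower bound for ",
            paste(which_t, collapse = ", "))
  }
  if (!converged && opt$convergence != 0L)
    warning("optimizer did not converge: ", opt$message)

  new("UCNRFit", theta = theta, design = d, spec = spec,
      loglik = -ucnr_negll(theta, d), vcov = as.matrix(V),
      converged = converged,
      niter = as.integer(niter), gradnorm = gradnorm, data = dat,
      removed = rm$removed, notes = notes)
})

#' Extract the fitted model parameters in full (constrained) form
#'
#' @param fit a [UCNRFit-class].
#' @return A list with `mu`, `alpha` (per target), `beta` (per sample),
#'   `gamma` (target x group interaction matrix), `zeta` (per sample,
#'   reference variant only) and `sigma` (per target noise SDs).
#' @export
ucnrCoef <- function(fit) par2full(fit@design, fit@theta)

#' Fitted latent means
#'
#' Predicted latent mean for every (target, sample) cell, including wells
#' missing from the input (the linear predictor is defined for all cells).
#'
#' @param fit a [UCNRFit-class].
#' @return A targets x samples matrix of latent means.
#' @export
ucnrFitted <- function(fit) {
  d <- fit@design
  co <- par2full(d, fit@theta)
  k <- d$group_of_sample
  out <- co$mu + outer(co$alpha, co$beta, "+") +
    co$gamma[, k, drop = FALSE]        # gamma rows of reference genes are 0
  if (!is.null(co$zeta) && any(d$is_reference))
    out[d$is_reference, ] <- sweep(out[d$is_reference, , drop = FALSE],
                                   2L, co$zeta, "+")
  dimnames(out) <- list(d$target_ids, d$sample_ids)
  out
}

#' @describeIn ucnrCoef Maximized censored log-likelihood.
#' @export
ucnrLogLik <- function(fit) fit@loglik

#' Flat table of free parameters with standard errors
#'
#' @param fit a [UCNRFit-class].
#' @return A data.frame with columns `name`, `estimate`, `se` (one row per
#'   free parameter; noise scales are reported on the log scale, as
#'   estimated).  Suitable for serialization with [write.table()].
#' @export
ucnrParameters <- function(fit) {
  se <- sqrt(pmax(diag(fit@vcov), 0))
  data.frame(name = names(fit@theta), estimate = unname(fit@theta),
             se = unname(se), stringsAsFactors = FALSE)
}
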