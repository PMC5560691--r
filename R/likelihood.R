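#' Censored normal log-likelihood
#'
#' Evaluates the log-likelihood of a censored normal regression at given
#' parameter values: each expressed well contributes the normal log-density
#' of its Cq at the latent mean, each censored well the log survival
#' probability \eqn{\log\{1 - \Phi((LOD - m)/\sigma)\}} of exceeding the
#' LOD.  Survival terms use the log-scale normal tail, so the evaluation is
#' stable for standardized distances up to about \eqn{\pm 40}.
#'
#' @param object a [CqExperiment-class].
#' @param params a list of full (constrained) parameters: `mu` scalar,
#'   `alpha` length-I, `beta` length-J, `gamma` I x K matrix, optional
#'   `zeta` length-J (reference variant), and `sigma` (length I, or a
#'   scalar shared by all targets).
#' @param spec a [ModelSpec-class].
#' @return The log-likelihood (a single number).
#' @export
censoredLogLik <- function(object, params, spec = modelSpec()) {
  d <- buildDesign(object, spec)
  sig <- params$sigma
  if (length(sig) == 1L) sig <- rep(sig, d$I)
  if (any(!is.finite(c(params$mu, params$alpha, params$beta, params$gamma,
                       params$zeta, sig))) || any(sig <= 0))
    stop("parameters must be finite with positive sigma")
  obs <- d$obs
  m <- params$mu + params$alpha[obs$i] + params$beta[obs$j] +
    params$gamma[cbind(obs$i, obs$k)]
  if (!is.null(params$zeta))
    m <- m + ifelse(d$is_reference[obs$i], params$zeta[obs$j], 0)
  s <- sig[obs$i]
  z <- (obs$y - m) / s
  sum(dnorm(z[!obs$cens], log = TRUE) - log(s[!obs$cens])) +
    sum(pnorm(z[obs$cens], lower.tail = FALSE, log.p = TRUE))
}

## internal: negative log-likelihood and analytic gradient in free parameters
ucnr_negll <- function(theta, d) {
  eta <- theta[seq_len(d$p_mean)]
  ls <- theta[d$p_mean + seq_len(d$n_sigma)]
  m <- as.vector(d$X %*% eta)
  s <- exp(ls)[d$sigma_map]
  z <- (d$obs$y - m) / s
  cen <- d$obs$cens
  ll <- sum(dnorm(z[!cen], log = TRUE) - log(s[!cen])) +
    sum(pnorm(z[cen], lower.tail = FALSE, log.p = TRUE))
  -ll
}

ucnr_neggrad <- function(theta, d) {
  eta <- theta[seq_len(d$p_mean)]
  ls <- theta[d$p_mean + seq_len(d$n_sigma)]
  m <- as.vector(d$X %*% eta)
  s <- exp(ls)[d$sigma_map]
  z <- (d$obs$y - m) / s
  cen <- d$obs$cens
  gm <- numeric(length(z))      # d loglik / d m, per observation
  gl <- numeric(length(z))      # d loglik / d log sigma, per observation
  zu <- z[!cen]
  gm[!cen] <- zu / s[!cen]
  gl[!cen] <- zu * zu - 1
  if (any(cen)) {
    zc <- z[cen]
    lam <- exp(dnorm(zc, log = TRUE) -
                 pnorm(zc, lower.tail = FALSE, log.p = TRUE))
    gm[cen] <- lam / s[cen]
    gl[cen] <- lam * zc
  }
  geta <- as.vector(Matrix::crossprod(d$X, gm))
  glog <- numeric(d$n_sigma)
  agg <- rowsum(gl, d$sigma_map)
  glog[as.integer(rownames(agg))] <- agg[, 1L]
  -c(geta, glog)
}

## internal: observed information (numeric central differences of the
## analytic score), step 1e-5 * (1 + |theta|)
ucnr_obsinfo <- function(theta, d) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (r in seq_len(p)) {
    h <- 1e-5 * (1 + abs(theta[r]))
    tp <- theta; tp[r] <- tp[r] + h
    tm <- theta; tm[r] <- tm[r] - h
    H[, r] <- (ucnr_neggrad(tp, d) - ucnr_neggrad(tm, d)) / (2 * h)
  }
  (H + t(H)) / 2
}
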