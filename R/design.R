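#' Build the full-rank design for the censored regression model
#'
#' Constructs the mapping from free mean parameters to the latent mean of
#' every observed well.  The latent model is
#' \deqn{C^*_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\gamma)_{ik} +
#'   \varepsilon_{ij}}
#' for the global variant, and
#' \deqn{C^*_{ijk} = \mu + \alpha_i + \beta_j + R_i \zeta_j +
#'   (1 - R_i)(\alpha\gamma)_{ik} + \varepsilon_{ij}}
#' for the reference-gene variant, with \eqn{\varepsilon_{ij} \sim
#' N(0, \sigma_i^2)}.  The model as written is over-parameterized; the
#' package uses one fixed full-rank coding:
#' target effects \eqn{\alpha} sum to zero over targets, sample effects
#' \eqn{\beta} sum to zero within each group (so group-level location is
#' carried by the interactions and \eqn{\beta_j} keeps its
#' normalization-factor interpretation), interactions of the first group
#' level are zero, and reference-gene sample effects \eqn{\zeta} sum to zero
#' over samples.  The per-target log2 fold changes are estimable contrasts
#' and therefore do not depend on this choice.
#'
#' With a single target the sample effects are confounded with the noise
#' (one observation per sample would saturate the mean model), so the
#' \eqn{\beta} block is dropped and the design reduces to a two-group
#' location model.
#'
#' @param object a [CqExperiment-class].
#' @param spec a [ModelSpec-class].
#' @return A list with the sparse design matrix `X` (observations x free
#'   mean parameters), the observation table `obs` (target/sample/group
#'   indices, cq, censoring flag), parameter names and block indices, and
#'   bookkeeping (`I`, `J`, `K`, level names, `lod`, `sigma_map`,
#'   `n_sigma`).
#' @export
buildDesign <- function(object, spec = modelSpec()) {
  cq <- cqValues(object)
  cen <- isCensored(object)
  grp <- groupLabels(object)
  if (any(table(grp) == 0L)) stop("every group level needs at least one sample")
  I <- nrow(cq); J <- ncol(cq); K <- nlevels(grp)
  if (K < 2L) stop("at least two groups are required")
  ref <- isReference(object)
  if (spec@variant == "reference") {
    if (!any(ref)) stop("reference variant requires at least one reference gene")
    if (all(ref)) stop("reference variant requires at least one target of interest")
  } else ref <- rep(FALSE, I)

  keep <- which(!is.na(cq))
  obs <- data.frame(i = ((keep - 1L) %% I) + 1L,
                    j = ((keep - 1L) %/% I) + 1L)
  obs$k <- as.integer(grp)[obs$j]
  obs$y <- cq[keep]
  obs$cens <- cen[keep]
  N <- nrow(obs)

  ii <- list(); jj <- list(); xx <- list()
  addcol <- function(rows, cols, vals) {
    ii[[length(ii) + 1L]] <<- rows
    jj[[length(jj) + 1L]] <<- cols
    xx[[length(xx) + 1L]] <<- vals
  }
  blocks <- list()
  pn <- "mu"
  addcol(seq_len(N), rep(1L, N), rep(1, N))
  blocks$mu <- 1L
  p <- 1L

  if (I >= 2L) {                       # alpha: sum-to-zero over targets
    cols <- p + seq_len(I - 1L)
    low <- obs$i < I
    addcol(which(low), cols[obs$i[low]], rep(1, sum(low)))
    hi <- which(!low)
    if (length(hi))
      addcol(rep(hi, each = I - 1L), rep(cols, length(hi)),
             rep(-1, length(hi) * (I - 1L)))
    blocks$alpha <- cols
    pn <- c(pn, paste0("alpha.", rownames(cq)[seq_len(I - 1L)]))
    p <- p + I - 1L
  } else blocks$alpha <- integer(0)

  if (I >= 2L) {                       # beta: sum-to-zero within group
    bcols <- integer(0)
    for (g in seq_len(K)) {
      sg <- which(as.integer(grp) == g)
      ng <- length(sg)
      if (ng < 2L) next
      cols <- p + seq_len(ng - 1L)
      for (m in seq_len(ng - 1L)) {
        rows <- which(obs$j == sg[m])
        addcol(rows, rep(cols[m], length(rows)), rep(1, length(rows)))
      }
      rows <- which(obs$j == sg[ng])
      if (length(rows))
        addcol(rep(rows, each = ng - 1L), rep(cols, length(rows)),
               rep(-1, length(rows) * (ng - 1L)))
      bcols <- c(bcols, cols)
      pn <- c(pn, paste0("beta.", colnames(cq)[sg[seq_len(ng - 1L)]]))
      p <- p + ng - 1L
    }
    blocks$beta <- bcols
  } else blocks$beta <- integer(0)

  if (spec@variant == "reference" && J >= 2L) {  # zeta: sum-to-zero
    cols <- p + seq_len(J - 1L)
    rrows <- which(ref[obs$i])
    low <- rrows[obs$j[rrows] < J]
    if (length(low))
      addcol(low, cols[obs$j[low]], rep(1, length(low)))
    hi <- rrows[obs$j[rrows] == J]
    if (length(hi))
      addcol(rep(hi, each = J - 1L), rep(cols, length(hi)),
             rep(-1, length(hi) * (J - 1L)))
    blocks$zeta <- cols
    pn <- c(pn, paste0("zeta.", colnames(cq)[seq_len(J - 1L)]))
    p <- p + J - 1L
  } else blocks$zeta <- integer(0)

  # interactions: group levels 2..K, non-reference targets only
  gi <- which(!ref)
  gindex <- expand.grid(i = gi, k = 2:K)
  cols <- p + seq_len(nrow(gindex))
  for (r in seq_len(nrow(gindex))) {
    rows <- which(obs$i == gindex$i[r] & obs$k == gindex$k[r])
    if (length(rows))
      addcol(rows, rep(cols[r], length(rows)), rep(1, length(rows)))
  }
  blocks$gamma <- cols
  pn <- c(pn, paste0("gamma.", rownames(cq)[gindex$i], ".",
                     levels(grp)[gindex$k]))
  p <- p + nrow(gindex)

  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, p))
  colnames(X) <- pn

  n_sigma <- if (spec@heteroskedastic) I else 1L
  sigma_map <- if (spec@heteroskedastic) obs$i else rep(1L, N)
  sn <- if (spec@heteroskedastic) paste0("logsigma.", rownames(cq))
        else "logsigma"

  list(X = X, obs = obs, p_mean = p, par_names = c(pn, sn),
       blocks = blocks, gamma_index = gindex,
       I = I, J = J, K = K,
       target_ids = rownames(cq), sample_ids = colnames(cq),
       group_ids = levels(grp), group_of_sample = as.integer(grp),
       is_reference = ref, lod = lodValue(object),
       sigma_map = sigma_map, n_sigma = n_sigma)
}

## expand free mean parameters to the full (constrained) parameter lists
par2full <- function(design, theta) {
  b <- design$blocks
  eta <- theta[seq_len(design$p_mean)]
  I <- design$I; J <- design$J; K <- design$K
  alpha <- numeric(I)
  if (length(b$alpha)) {
    a <- eta[b$alpha]
    alpha <- c(a, -sum(a))
  }
  names(alpha) <- design$target_ids
  beta <- numeric(J)
  if (length(b$beta)) {
    pos <- 1L
    for (g in seq_len(K)) {
      sg <- which(design$group_of_sample == g)
      ng <- length(sg)
      if (ng < 2L) next
      bfree <- eta[b$beta[pos:(pos + ng - 2L)]]
      beta[sg] <- c(bfree, -sum(bfree))
      pos <- pos + ng - 1L
    }
  }
  names(beta) <- design$sample_ids
  zeta <- NULL
  if (length(b$zeta)) {
    z <- eta[b$zeta]
    zeta <- c(z, -sum(z))
    names(zeta) <- design$sample_ids
  }
  gamma <- matrix(0, I, K, dimnames = list(design$target_ids,
                                           design$group_ids))
  if (length(b$gamma))
    gamma[cbind(design$gamma_index$i, design$gamma_index$k)] <- eta[b$gamma]
  sigma <- exp(theta[design$p_mean + seq_len(design$n_sigma)])
  if (design$n_sigma == design$I) names(sigma) <- design$target_ids
  list(mu = unname(eta[1L]), alpha = alpha, beta = beta, zeta = zeta,
       gamma = gamma, sigma = sigma)
}
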