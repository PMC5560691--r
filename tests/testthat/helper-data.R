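## Small fixtures built in code, shared across test files.

toy_matrix <- function() {
  matrix(c(1, 4, 10,
           2, 6, 10,
           3, 8, 13),
         nrow = 3,
         dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
}

## 3 targets x 4 samples, two groups, one well censored at lod
toy_cqe <- function(lod = 35) {
  m <- matrix(c(24.0, 28.5, 31.0,
                24.6, 29.1, 30.2,
                25.9, 30.0, 36.0,
                25.1, 29.4, 33.8),
              nrow = 3,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  CqExperiment(m, group = c("A", "A", "B", "B"), lod = lod)
}

write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

## independent step-up BH oracle (hand computation of the rule):
## sort ascending, adj_(i) = min over j >= i of m * p_(j) / j, cap at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * sorted[i] / i)
    adj[i] <- run
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## independent tie-corrected rank-sum z-approximation oracle
wilcox_z_oracle <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(x)
  mu <- n1 * n2 / 2
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu) / sqrt(v)
  2 * pnorm(-abs(z))
}
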