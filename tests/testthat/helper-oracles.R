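#  Independent oracles used across tests. These deliberately use a different
#  computational route than the package (binomial-coefficient enumeration,
#  explicit loops) so they can serve as cross-checks.

#  Two-sided Fisher p by full enumeration over the hypergeometric support,
#  point probabilities from binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k1 <- a + c
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || k1 == 0 || k1 == N) return(1)
  ks <- max(0, k1 - m2):min(k1, m1)
  pr <- choose(m1, ks) * choose(m2, k1 - ks) / choose(N, k1)
  pobs <- choose(m1, a) * choose(m2, c) / choose(N, k1)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#  Exhaustive label-permutation p for a single site, loop implementation.
perm_oracle_p <- function(x, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  obs <- abs(mean(x[labels]) - mean(x[!labels]))
  idx <- combn(length(x), n1)
  stats <- apply(idx, 2, function(ii) {
    abs(mean(x[ii]) - mean(x[-ii]))
  })
  mean(stats >= obs - 1e-12)
}

#  Small meth_matrix builder from plain matrices.
make_mm <- function(vals, cov = NULL, is_cgi = NULL) {
  sites <- tibble::tibble(site_id = sprintf("S%05d", seq_len(nrow(vals))))
  if (!is.null(is_cgi)) sites$is_cgi <- is_cgi
  rownames(vals) <- sites$site_id
  if (!is.null(cov)) rownames(cov) <- sites$site_id
  as_meth_matrix(vals, cov, sites)
}

#  Tiny clinical table builder.
make_patients <- function(response, survival_days = NULL, event = NULL,
                          ...) {
  n <- length(response)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    response = response,
    survival_days = survival_days %||% rep(100, n),
    event = event %||% rep(1L, n),
    ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
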