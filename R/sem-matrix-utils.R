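# Half-vectorization helpers used by the covariance-structure machinery.
# vech stacks the lower triangle (including the diagonal) column-wise;
# the duplication matrix D satisfies vec(M) = D vech(M) for symmetric M.

vech <- function(M) M[lower.tri(M, diag = TRUE)]

vech_index <- function(p) which(lower.tri(matrix(0, p, p), diag = TRUE))

duplication_matrix <- function(p) {
  pv <- p * (p + 1) / 2
  D <- matrix(0, p * p, pv)
  k <- 0L
  for (j in seq_len(p)) {
    for (i in j:p) {
      k <- k + 1L
      D[(j - 1L) * p + i, k] <- 1
      D[(i - 1L) * p + j, k] <- 1
    }
  }
  D
}

# Normal-theory weight matrix on vech coordinates:
#   W = 0.5 * t(D) (Sigma^-1 kron Sigma^-1) D,
# the inverse of the asymptotic covariance of vech(S) under normality.
normal_theory_weight <- function(Sigma_inv) {
  p <- nrow(Sigma_inv)
  D <- duplication_matrix(p)
  0.5 * t(D) %*% (Sigma_inv %x% Sigma_inv) %*% D
}

is_spd <- function(M, tol = 1e-10) {
  if (any(!is.finite(M))) return(FALSE)
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  all(is.finite(ev)) && min(ev) > tol * max(abs(ev), 1)
}
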