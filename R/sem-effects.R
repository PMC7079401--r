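#' Standardized solution of a fitted model
#'
#' Rescales every path coefficient by the ratio of implied standard
#' deviations, \eqn{b^{std}_{j\to i} = b_{j\to i}\, sd_j / sd_i}, and every
#' (co)variance to the correlation metric, using the implied covariance over
#' all variables (latents included).  The standardized solution is invariant
#' to linear rescaling of any observed variable.
#'
#' @param fit a `sem_fit`.
#' @return list with `A_std` (standardized path matrix), `S_std`,
#'   `sd` (implied standard deviations), and `estimates`, a named vector of
#'   standardized values for every free parameter.
#' @export
standardize <- function(fit) {
  std_solution(fit$spec, fit$theta)
}

std_solution <- function(spec, theta) {
  mats <- ram_matrices(spec, theta)
  Sigma_all <- implied_covariance(spec, theta, observed_only = FALSE)
  sd_all <- sqrt(pmax(diag(Sigma_all), 0))
  if (any(sd_all <= 0)) stop("zero implied variance; cannot standardize")
  names(sd_all) <- spec$all_vars
  A_std <- mats$A * outer(1 / sd_all, sd_all)
  S_std <- mats$S / outer(sd_all, sd_all)
  est <- numeric(spec$n_free)
  Aidx <- which(spec$A_free != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(Aidx))) {
    est[spec$A_free[Aidx[r, 1], Aidx[r, 2]]] <- A_std[Aidx[r, 1], Aidx[r, 2]]
  }
  Sidx <- which(spec$S_free != 0L & lower.tri(spec$S_free, diag = TRUE),
                arr.ind = TRUE)
  for (r in seq_len(nrow(Sidx))) {
    est[spec$S_free[Sidx[r, 1], Sidx[r, 2]]] <- S_std[Sidx[r, 1], Sidx[r, 2]]
  }
  names(est) <- spec$parameter_labels
  list(A_std = A_std, S_std = S_std, sd = sd_all, estimates = est)
}

#' Variables taking part in the structural (path) portion of a model
#'
#' All variables except pure indicators of latent factors.
#'
#' @param spec a `sem_spec`.
#' @return character vector.
#' @export
structural_variables <- function(spec) {
  indicators <- unique(unlist(spec$measurement, use.names = FALSE))
  setdiff(spec$all_vars, indicators)
}

#' Total effects of a recursive coefficient matrix
#'
#' For a structural coefficient matrix `B` (`B[i, j]` = path j -> i) of a
#' recursive system, the total-effect matrix is \eqn{(I-B)^{-1} - I}, equal
#' to the sum over every directed path of the product of its coefficients
#' (the series terminates because recursive B is nilpotent).
#'
#' @param B square numeric matrix, acyclic.
#' @return matrix of total effects.
#' @export
total_effects <- function(B) {
  if (!is_acyclic(B != 0)) stop("B must be recursive (acyclic)")
  solve(diag(nrow(B)) - B) - diag(nrow(B))
}

#' Direct, indirect and total standardized effects on an outcome
#'
#' Evaluates the effect decomposition on the standardized structural
#' coefficients: the direct effect of each predictor on the outcome is its
#' path coefficient; the total effect is the corresponding entry of
#' \eqn{(I-B)^{-1} - I}; the indirect effect is their difference (the sum of
#' all mediated path products).  Standard errors follow from the first-order
#' delta method through the full estimation covariance, with central-
#' difference derivatives of each standardized effect with respect to the
#' free parameters.
#'
#' @param fit a converged `sem_fit`.
#' @param outcome name of the outcome variable (latent or observed).
#' @param sources predictors to report; default every structural variable
#'   except the outcome.
#' @return data frame of class `effect_table` with columns `source`,
#'   `outcome`, `direct`, `se_direct`, `p_direct`, `indirect`,
#'   `se_indirect`, `p_indirect`, `total`, `se_total`, `p_total`.
#' @export
decompose_effects <- function(fit, outcome, sources = NULL) {
  spec <- fit$spec
  svars <- structural_variables(spec)
  if (!outcome %in% svars) stop("outcome must be a structural variable")
  if (is.null(sources)) sources <- setdiff(svars, outcome)
  eff_fun <- function(theta) {
    std <- std_solution(spec, theta)
    B <- std$A_std[svars, svars, drop = FALSE]
    total <- total_effects(B)[outcome, sources]
    direct <- B[outcome, sources]
    c(direct, total - direct, total)
  }
  est <- eff_fun(fit$theta)
  J <- num_jacobian(eff_fun, fit$theta)
  V <- J %*% fit$acov %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  k <- length(sources)
  z <- ifelse(se > 0, est / se, NA_real_)
  pv <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    source = sources, outcome = outcome,
    direct = est[seq_len(k)], se_direct = se[seq_len(k)],
    p_direct = pv[seq_len(k)],
    indirect = est[k + seq_len(k)], se_indirect = se[k + seq_len(k)],
    p_indirect = pv[k + seq_len(k)],
    total = est[2 * k + seq_len(k)], se_total = se[2 * k + seq_len(k)],
    p_total = pv[2 * k + seq_len(k)],
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# central-difference Jacobian; step scaled to parameter magnitude
num_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    hk <- h * max(1, abs(x[k]))
    xp <- x; xp[k] <- x[k] + hk
    xm <- x; xm[k] <- x[k] - hk
    J[, k] <- (f(xp) - f(xm)) / (2 * hk)
  }
  J
}
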