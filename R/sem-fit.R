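#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy \eqn{F_{ML}} over the free
#' parameters with a quasi-Newton iteration (analytic gradient via the RAM
#' derivative identities).  Start values are deterministic: free loadings
#' 0.5, structural paths 0, free variances at half the corresponding sample
#' variances and free covariances at half the sample covariances, so
#' repeated runs are identical.
#'
#' Standard errors come from the inverse normal-theory information
#' \eqn{(\Delta^T W \Delta)^{-1}/(n-1)} with
#' \eqn{W = \frac12 D^T(\Sigma^{-1}\otimes\Sigma^{-1})D} and
#' \eqn{\Delta = \partial vech\,\Sigma(\theta)/\partial\theta}.  A Heywood
#' case (negative estimated residual variance) is reported via
#' `heywood`, not constrained away; `constrain_variances = TRUE` retries
#' with variances bounded at a small positive floor.
#'
#' @param spec a [build_spec()] model.
#' @param data data frame or matrix containing every observed variable
#'   (complete cases; `n > p`).
#' @param constrain_variances bound free variances below at `1e-6` during
#'   optimization (off by default).
#' @param max_iter iteration cap passed to the optimizer.
#' @return object of class `sem_fit`: estimates `theta` (named), `se`,
#'   sample and implied covariances, `F_ML`, `chi2_ml`, `df`, `n`,
#'   convergence and Heywood flags, the parameter covariance `acov`, and
#'   the Jacobian `Delta` used for robust statistics.
#' @export
fit_ml <- function(spec, data, constrain_variances = FALSE, max_iter = 500L) {
  X <- as.matrix(as.data.frame(data)[, spec$observed_vars, drop = FALSE])
  if (anyNA(X)) stop("complete cases required for all observed variables")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n > p observations")
  S_sample <- stats::cov(X)  # n-1 denominator; chi2 uses (n-1) consistently
  if (!is_spd(S_sample)) stop("sample covariance is not positive-definite")

  theta0 <- start_values(spec, S_sample)
  obj <- function(th) {
    Sigma <- tryCatch(implied_covariance(spec, th), error = function(e) NULL)
    if (is.null(Sigma) || !is_spd(Sigma)) return(1e10)
    ml_discrepancy_fast(S_sample, Sigma)
  }
  grad <- function(th) {
    g <- tryCatch(fml_gradient(spec, th, S_sample), error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) rep(0, length(th)) else g
  }
  lower <- rep(-Inf, spec$n_free)
  if (constrain_variances) {
    lower[variance_parameters(spec)] <- 1e-6
  }
  opt <- stats::nlminb(theta0, obj, gradient = grad, lower = lower,
                       control = list(iter.max = max_iter, eval.max = 4L * max_iter,
                                      rel.tol = 1e-12, abs.tol = 1e-14))
  # polish: restart until the gradient criterion is met (quasi-Newton often
  # stalls on the relative-change test a hair short of stationarity)
  iters <- opt$iterations
  for (restart in 1:3) {
    gn <- sqrt(sum(grad(opt$par)^2))
    if (gn < 1e-6) break
    if (all(!is.finite(lower))) {   # BFGS polish only when unconstrained
      o2 <- stats::optim(opt$par, obj, grad, method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-14))
      if (o2$value <= opt$objective) {
        opt$par <- o2$par; opt$objective <- o2$value
      }
    }
    o3 <- stats::nlminb(opt$par, obj, gradient = grad, lower = lower,
                        control = list(iter.max = max_iter,
                                       rel.tol = 1e-12, abs.tol = 1e-14))
    if (o3$objective <= opt$objective) {
      iters <- iters + o3$iterations
      opt$par <- o3$par; opt$objective <- o3$objective
    }
  }
  theta <- opt$par
  names(theta) <- spec$parameter_labels
  Sigma_hat <- implied_covariance(spec, theta)
  F_ML <- ml_discrepancy_fast(S_sample, Sigma_hat)
  gnorm <- sqrt(sum(fml_gradient(spec, theta, S_sample)^2))
  converged <- gnorm < 1e-6 || (opt$convergence == 0 && gnorm < 1e-4)

  Delta <- delta_jacobian(spec, theta)
  Sigma_inv <- solve(Sigma_hat)
  W <- normal_theory_weight(Sigma_inv)
  info <- t(Delta) %*% W %*% Delta
  acov <- tryCatch(solve(info) / (n - 1), error = function(e) {
    matrix(NA_real_, spec$n_free, spec$n_free)
  })
  se <- sqrt(pmax(diag(acov), 0))
  names(se) <- spec$parameter_labels

  vpar <- variance_parameters(spec)
  heywood <- spec$parameter_labels[vpar][theta[vpar] < 0]

  fit <- structure(list(
    spec = spec, n = n, S_sample = S_sample, theta = theta, se = se,
    acov = acov, Sigma_hat = Sigma_hat, F_ML = F_ML,
    chi2_ml = (n - 1) * F_ML, df = spec$df,
    Delta = Delta, W = W, data = X,
    converged = converged, gradient_norm = gnorm, iterations = iters,
    heywood = heywood), class = "sem_fit")
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit: n =", x$n, " chi2_ml =", round(x$chi2_ml, 3),
      "on df =", x$df, "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (length(x$heywood)) {
    cat("  Heywood case(s):", paste(x$heywood, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Satorra-Bentler scaled chi-square
#'
#' Robust correction of the ML chi-square for non-normal data.  With
#' \eqn{\hat\Gamma} the sample asymptotic covariance of the vectorized
#' second moments (built from fourth-order moments of the raw data), the
#' residual weight \eqn{U = W - W\Delta(\Delta^TW\Delta)^{-1}\Delta^TW}
#' gives the scaling factor \eqn{c = tr(U\hat\Gamma)/df} and the scaled
#' statistic \eqn{\chi^2_{SB} = \chi^2_{ML}/c}.
#'
#' @param fit a converged [fit_ml()] result (the raw data are retained on
#'   the fit object).
#' @return list with `chi2_sb`, `scaling_c`, `df`, `p_value`.
#' @export
satorra_bentler <- function(fit) {
  if (fit$df <= 0) stop("scaling undefined at df = 0")
  Gamma <- fourth_moment_gamma(fit$data)
  W <- fit$W; Delta <- fit$Delta
  WD <- W %*% Delta
  bread <- solve(t(Delta) %*% WD)
  U <- W - WD %*% bread %*% t(WD)
  c_hat <- sum(U * t(Gamma)) / fit$df  # tr(U Gamma); both symmetric
  if (!is.finite(c_hat) || c_hat <= 0) stop("non-positive scaling factor")
  chi2_sb <- fit$chi2_ml / c_hat
  list(chi2_sb = chi2_sb, scaling_c = c_hat, df = fit$df,
       p_value = stats::pchisq(chi2_sb, fit$df, lower.tail = FALSE))
}

#' Independence-baseline fit for incremental indices
#'
#' The baseline model frees every observed variance and fixes all
#' covariances to zero; its ML solution is closed-form (variances equal the
#' sample variances), giving \eqn{F_b = \ln|diag(S)| - \ln|S|} on
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param fit a `sem_fit` (baseline uses its sample covariance and data).
#' @return a list shaped like a minimal `sem_fit` for use in
#'   [fit_indices()], including its own Satorra-Bentler scaling.
#' @export
baseline_fit <- function(fit) {
  S <- fit$S_sample; p <- nrow(S); n <- fit$n
  F_b <- as.numeric(sum(log(diag(S))) -
                      determinant(S, logarithm = TRUE)$modulus)
  df_b <- p * (p - 1) / 2
  # Delta for the diagonal model: columns are vech(e_i e_i^T)
  iv <- vech_index(p)
  Delta <- matrix(0, length(iv), p)
  for (i in seq_len(p)) {
    E <- matrix(0, p, p); E[i, i] <- 1
    Delta[, i] <- vech(E)
  }
  Sigma_inv <- diag(1 / diag(S))
  W <- normal_theory_weight(Sigma_inv)
  WD <- W %*% Delta
  U <- W - WD %*% solve(t(Delta) %*% WD) %*% t(WD)
  Gamma <- fourth_moment_gamma(fit$data)
  c_b <- sum(U * t(Gamma)) / df_b
  list(chi2_ml = (n - 1) * F_b, df = df_b, scaling_c = c_b,
       chi2_sb = (n - 1) * F_b / c_b, n = n)
}

#' Covariance-structure fit indices
#'
#' RMSEA, CFI, TLI, SRMR and the coefficient of determination (CD), in both
#' ML and Satorra-Bentler scaled variants (SRMR and CD do not depend on the
#' chi-square and are common to both).
#'
#' \itemize{
#' \item RMSEA = sqrt(max(chi2 - df, 0) / (df (n-1)))
#' \item CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)
#' \item TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)
#' \item SRMR: root mean square of the correlation-metric residuals
#'   (s_ij - sigma_ij) / (s_i s_j) over the lower triangle incl. diagonal
#' \item CD = 1 - det(residual covariance of endogenous observed variables)
#'   / det(their model-implied covariance)
#' }
#'
#' @param fit a `sem_fit`.
#' @param baseline result of [baseline_fit()]; computed if missing.
#' @param sb result of [satorra_bentler()]; computed if missing.
#' @return list with elements `ml` and `sb` (each RMSEA/CFI/TLI), plus
#'   `srmr`, `cd` and the inputs' chi-squares.
#' @export
fit_indices <- function(fit, baseline = NULL, sb = NULL) {
  if (is.null(baseline)) baseline <- baseline_fit(fit)
  if (is.null(sb) && fit$df > 0) sb <- satorra_bentler(fit)
  one_set <- function(chi2, df, chi2_b, df_b, n) {
    rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else 0
    denom <- max(chi2_b - df_b, chi2 - df, 0)
    cfi <- if (denom > 0) 1 - max(chi2 - df, 0) / denom else 1
    tli <- if (df > 0 && df_b > 0 && (chi2_b / df_b) > 1) {
      ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
    } else 1
    list(rmsea = rmsea, cfi = cfi, tli = min(tli, 1 + 1e-12), chi2 = chi2, df = df)
  }
  ml <- one_set(fit$chi2_ml, fit$df, baseline$chi2_ml, baseline$df, fit$n)
  sb_set <- if (!is.null(sb)) {
    one_set(sb$chi2_sb, fit$df, baseline$chi2_sb, baseline$df, fit$n)
  } else ml

  S <- fit$S_sample; Sg <- fit$Sigma_hat
  s_sd <- sqrt(diag(S))
  res <- (S - Sg) / outer(s_sd, s_sd)
  srmr <- sqrt(mean(vech(res)^2))

  cd <- coefficient_of_determination(fit)
  list(ml = ml, sb = sb_set, srmr = srmr, cd = cd,
       scaling_c = if (!is.null(sb)) sb$scaling_c else NA_real_)
}

#' Proportion of variance explained per endogenous variable
#'
#' `1 - residual variance / implied variance` for every endogenous variable
#' (latent included), from the full implied covariance over all variables.
#'
#' @param fit a `sem_fit`.
#' @return named numeric vector.
#' @export
r_squared <- function(fit) {
  spec <- fit$spec
  mats <- ram_matrices(spec, fit$theta)
  Sigma_all <- implied_covariance(spec, fit$theta, observed_only = FALSE)
  endo <- names(spec$endogenous)[spec$endogenous]
  out <- vapply(endo, function(v) {
    i <- match(v, spec$all_vars)
    1 - mats$S[i, i] / Sigma_all[i, i]
  }, numeric(1))
  out
}

# ---- internal ---------------------------------------------------------------

# determinant-based coefficient of determination:
# 1 - det(residual covariance of the endogenous observed variables) /
#     det(their model-implied covariance)
coefficient_of_determination <- function(fit) {
  spec <- fit$spec
  mats <- ram_matrices(spec, fit$theta)
  endo_obs <- intersect(names(spec$endogenous)[spec$endogenous],
                        spec$observed_vars)
  if (!length(endo_obs)) return(NA_real_)
  i <- match(endo_obs, spec$all_vars)
  Theta <- mats$S[i, i, drop = FALSE]
  Sigma_all <- implied_covariance(spec, fit$theta, observed_only = FALSE)
  Sg <- Sigma_all[i, i, drop = FALSE]
  1 - det(Theta) / det(Sg)
}

ml_discrepancy_fast <- function(S_sample, Sigma) {
  # same value as ml_discrepancy() without the SPD guards (hot loop)
  p <- nrow(S_sample)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ld_sigma <- 2 * sum(log(diag(ch)))
  ld_s <- determinant(S_sample, logarithm = TRUE)$modulus
  Sigma_inv <- chol2inv(ch)
  as.numeric(ld_sigma + sum(S_sample * Sigma_inv) - ld_s - p)
}

start_values <- function(spec, S_sample) {
  theta <- numeric(spec$n_free)
  labels <- spec$parameter_labels
  theta[grepl("^lambda:", labels)] <- 0.5
  theta[grepl("^beta:", labels)] <- 0
  obs_idx <- match(spec$observed_vars, spec$all_vars)
  # proxy variance for a latent: its first indicator's sample variance
  proxy_var <- function(v) {
    if (v %in% spec$observed_vars) return(S_sample[v, v])
    i <- match(v, spec$all_vars)
    ind <- spec$all_vars[which(spec$A_free[, i] != 0L | spec$A_fixed[, i] != 0)]
    ind <- intersect(ind, spec$observed_vars)
    if (length(ind)) S_sample[ind[1], ind[1]] else 1
  }
  for (k in seq_along(labels)) {
    lab <- labels[k]
    if (startsWith(lab, "psi:")) {
      body <- sub("^psi:", "", lab)
      if (grepl("~~", body, fixed = TRUE)) {
        pair <- strsplit(body, "~~", fixed = TRUE)[[1]]
        theta[k] <- if (all(pair %in% spec$observed_vars)) {
          S_sample[pair[1], pair[2]] / 2
        } else 0
      } else {
        theta[k] <- proxy_var(body) / 2
      }
    }
  }
  theta
}

variance_parameters <- function(spec) {
  labels <- spec$parameter_labels
  which(startsWith(labels, "psi:") & !grepl("~~", labels, fixed = TRUE))
}

# Gradient of F_ML via RAM derivatives:
#  dF = sum(G * dSigma), G = Sigma^-1 - Sigma^-1 S Sigma^-1,
#  dSigma/dA_ij = M E_ij Sigma_all + transpose  (M = (I-A)^-1)
#  dSigma/dS_ij = M_.i M_.j^T (+ transpose off-diagonal)
fml_gradient <- function(spec, theta, S_sample) {
  mats <- ram_matrices(spec, theta)
  m <- length(spec$all_vars)
  M <- solve(diag(m) - mats$A)
  Sigma_all <- M %*% mats$S %*% t(M)
  obs <- match(spec$observed_vars, spec$all_vars)
  Sigma <- Sigma_all[obs, obs, drop = FALSE]
  ch <- chol(Sigma)
  Sigma_inv <- chol2inv(ch)
  G <- Sigma_inv - Sigma_inv %*% S_sample %*% Sigma_inv
  Mo <- M[obs, , drop = FALSE]          # observed rows of M
  So <- Sigma_all[, obs, drop = FALSE]  # columns at observed vars
  g <- numeric(spec$n_free)
  Afree <- which(spec$A_free != 0L, arr.ind = TRUE)
  if (nrow(Afree)) {
    for (r in seq_len(nrow(Afree))) {
      i <- Afree[r, 1]; j <- Afree[r, 2]
      k <- spec$A_free[i, j]
      u <- Mo[, i]           # F M e_i
      v <- So[j, ]           # e_j^T Sigma_all F^T
      g[k] <- g[k] + 2 * as.numeric(t(u) %*% G %*% v)
    }
  }
  done <- rep(FALSE, spec$n_free)
  idx <- which(spec$S_free != 0L, arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      k <- spec$S_free[i, j]
      if (done[k] && i != j) next
      if (i == j) {
        u <- Mo[, i]
        g[k] <- g[k] + as.numeric(t(u) %*% G %*% u)
      } else if (!done[k]) {
        u <- Mo[, i]; v <- Mo[, j]
        g[k] <- g[k] + 2 * as.numeric(t(u) %*% G %*% v)
        done[k] <- TRUE
      }
    }
  }
  g
}

# Jacobian Delta = d vech(Sigma_obs) / d theta at theta
delta_jacobian <- function(spec, theta) {
  mats <- ram_matrices(spec, theta)
  m <- length(spec$all_vars)
  M <- solve(diag(m) - mats$A)
  Sigma_all <- M %*% mats$S %*% t(M)
  obs <- match(spec$observed_vars, spec$all_vars)
  p <- length(obs)
  Mo <- M[obs, , drop = FALSE]
  So <- Sigma_all[, obs, drop = FALSE]
  lt <- lower.tri(matrix(0, p, p), diag = TRUE)
  Delta <- matrix(0, sum(lt), spec$n_free)
  add_col <- function(k, dS) Delta[, k] <<- Delta[, k] + dS[lt]
  Aidx <- which(spec$A_free != 0L, arr.ind = TRUE)
  if (nrow(Aidx)) {
    for (r in seq_len(nrow(Aidx))) {
      i <- Aidx[r, 1]; j <- Aidx[r, 2]
      k <- spec$A_free[i, j]
      u <- Mo[, i]; v <- So[j, ]
      dS <- u %o% v; dS <- dS + t(dS)
      add_col(k, dS)
    }
  }
  done <- rep(FALSE, spec$n_free)
  Sidx <- which(spec$S_free != 0L, arr.ind = TRUE)
  if (nrow(Sidx)) {
    for (r in seq_len(nrow(Sidx))) {
      i <- Sidx[r, 1]; j <- Sidx[r, 2]
      k <- spec$S_free[i, j]
      if (i == j) {
        add_col(k, Mo[, i] %o% Mo[, i])
      } else if (!done[k]) {
        dS <- Mo[, i] %o% Mo[, j]; dS <- dS + t(dS)
        add_col(k, dS)
        done[k] <- TRUE
      }
    }
  }
  Delta
}

# Sample asymptotic covariance of vech(S): fourth-order moment matrix
#   Gamma_hat = (1/n) sum_i (d_i - dbar)(d_i - dbar)^T,
#   d_i = vech((x_i - xbar)(x_i - xbar)^T)
fourth_moment_gamma <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  iv <- vech_index(p)
  ii <- ((iv - 1L) %% p) + 1L   # row index of each vech element
  jj <- ((iv - 1L) %/% p) + 1L  # column index
  D <- Xc[, ii, drop = FALSE] * Xc[, jj, drop = FALSE]
  Dc <- scale(D, center = TRUE, scale = FALSE)
  crossprod(Dc) / n
}
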