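#' Build a RAM-form structural equation model specification
#'
#' The model is held in reticular-action-model (RAM) form: a directed-path
#' matrix `A` (loadings and structural coefficients; `A[i, j]` is the path
#' j -> i), a symmetric matrix `S` of exogenous variances/covariances and
#' residual variances, and an implicit filter selecting the observed rows.
#' The implied covariance of the observed variables is
#' \deqn{\Sigma(\theta) = F (I-A)^{-1} S (I-A)^{-T} F^T.}
#'
#' Free parameters are labelled `lambda:<indicator>`, `beta:<from>-><to>`,
#' `psi:<var>` (variances) and `psi:<a>~~<b>` (covariances).  Each latent is
#' identified either by fixing its first loading to 1 (default) or by fixing
#' its variance to 1.
#'
#' @param measurement named list: latent name -> character vector of
#'   indicator variables (first indicator carries the fixed loading under
#'   the default identification).
#' @param structural data frame (or 2-column matrix) of directed paths with
#'   columns `from`, `to`; optionally a `fixed` column giving a fixed value
#'   (NA = free).
#' @param covariances optional data frame with columns `a`, `b` of variable
#'   pairs whose covariance is free.  Defaults to all pairs of exogenous
#'   observed variables.
#' @param identification `"first_loading_fixed_1"` or
#'   `"latent_variance_fixed_1"`.
#' @return object of class `sem_spec`: variable lists, pattern matrices
#'   (`A_fixed`, `A_free`, `S_fixed`, `S_free`), `parameter_labels`, and
#'   the model degrees of freedom `df = p(p+1)/2 - q`.
#' @export
build_spec <- function(measurement, structural, covariances = NULL,
                       identification = c("first_loading_fixed_1",
                                          "latent_variance_fixed_1")) {
  identification <- match.arg(identification)
  structural <- as.data.frame(structural, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(structural))) {
    stop("structural needs columns 'from' and 'to'")
  }
  if (is.null(structural$fixed)) {
    structural$fixed <- rep(NA_real_, nrow(structural))
  }

  latent_vars <- names(measurement)
  indicators <- unique(unlist(measurement, use.names = FALSE))
  struct_vars <- unique(c(structural$from, structural$to))
  if (any(indicators %in% struct_vars)) {
    stop("indicator variables cannot also appear in structural paths: ",
         paste(intersect(indicators, struct_vars), collapse = ", "))
  }
  observed_vars <- c(setdiff(struct_vars, latent_vars), indicators)
  all_vars <- c(observed_vars, latent_vars)
  m <- length(all_vars)
  p <- length(observed_vars)

  A_fixed <- matrix(0, m, m, dimnames = list(all_vars, all_vars))
  A_free <- matrix(0L, m, m, dimnames = list(all_vars, all_vars))
  S_fixed <- matrix(0, m, m, dimnames = list(all_vars, all_vars))
  S_free <- matrix(0L, m, m, dimnames = list(all_vars, all_vars))
  labels <- character(0)
  add_par <- function(lab) {
    if (lab %in% labels) stop("duplicate parameter label: ", lab)
    labels <<- c(labels, lab)
    length(labels)
  }

  for (lat in latent_vars) {
    ind <- measurement[[lat]]
    if (length(ind) < 1L) stop("latent '", lat, "' has no indicators")
    for (s in seq_along(ind)) {
      i <- match(ind[s], all_vars); j <- match(lat, all_vars)
      if (s == 1L && identification == "first_loading_fixed_1") {
        A_fixed[i, j] <- 1
      } else {
        A_free[i, j] <- add_par(paste0("lambda:", ind[s]))
      }
    }
  }
  for (r in seq_len(nrow(structural))) {
    i <- match(structural$to[r], all_vars)
    j <- match(structural$from[r], all_vars)
    if (i == j) stop("self-loop path on ", structural$to[r])
    if (A_free[i, j] != 0L || A_fixed[i, j] != 0) {
      stop("duplicate path ", structural$from[r], " -> ", structural$to[r])
    }
    if (is.na(structural$fixed[r])) {
      A_free[i, j] <- add_par(paste0("beta:", structural$from[r], "->",
                                     structural$to[r]))
    } else {
      A_fixed[i, j] <- structural$fixed[r]
    }
  }

  # acyclicity of the full directed graph (loadings + structural paths)
  if (!is_acyclic(A_free != 0L | A_fixed != 0)) {
    stop("directed paths contain a cycle; the model must be recursive")
  }

  endo <- vapply(seq_len(m), function(i) any(A_free[i, ] != 0L) ||
                   any(A_fixed[i, ] != 0), logical(1))
  names(endo) <- all_vars

  # variances: every variable gets one (residual variance if endogenous),
  # except latents identified by a fixed variance
  for (v in all_vars) {
    i <- match(v, all_vars)
    if (v %in% latent_vars && identification == "latent_variance_fixed_1" &&
        !endo[i]) {
      S_fixed[i, i] <- 1
    } else {
      S_free[i, i] <- add_par(paste0("psi:", v))
    }
  }

  if (is.null(covariances)) {
    exo_obs <- observed_vars[!endo[observed_vars]]
    covariances <- if (length(exo_obs) >= 2L) {
      pairs <- utils::combn(exo_obs, 2L)
      data.frame(a = pairs[1L, ], b = pairs[2L, ], stringsAsFactors = FALSE)
    } else data.frame(a = character(0), b = character(0))
  }
  covariances <- as.data.frame(covariances, stringsAsFactors = FALSE)
  if (nrow(covariances)) {
    for (r in seq_len(nrow(covariances))) {
      i <- match(covariances$a[r], all_vars)
      j <- match(covariances$b[r], all_vars)
      if (anyNA(c(i, j))) stop("covariance names unknown variable")
      if (i == j) stop("use a variance, not a self-covariance, for ",
                       covariances$a[r])
      k <- add_par(paste0("psi:", covariances$a[r], "~~", covariances$b[r]))
      S_free[i, j] <- k; S_free[j, i] <- k
    }
  }

  q <- length(labels)
  df <- p * (p + 1) / 2 - q
  if (df < 0) stop("model under-identified: ", q, " free parameters but only ",
                   p * (p + 1) / 2, " observed moments")
  structure(list(observed_vars = observed_vars, latent_vars = latent_vars,
                 all_vars = all_vars, A_fixed = A_fixed, A_free = A_free,
                 S_fixed = S_fixed, S_free = S_free,
                 parameter_labels = labels, endogenous = endo,
                 measurement = measurement, structural = structural,
                 identification = identification, n_free = q, df = df),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("sem_spec:", length(x$observed_vars), "observed,",
      length(x$latent_vars), "latent,", x$n_free, "free parameters, df =",
      x$df, "\n")
  invisible(x)
}

#' Materialize the RAM matrices for a parameter vector
#'
#' @param spec a `sem_spec`.
#' @param theta numeric vector matching `spec$parameter_labels`.
#' @return list with full `A` and `S` matrices over all variables.
#' @export
ram_matrices <- function(spec, theta) {
  if (length(theta) != spec$n_free) {
    stop("theta has length ", length(theta), ", expected ", spec$n_free)
  }
  A <- spec$A_fixed
  A[spec$A_free != 0L] <- theta[spec$A_free[spec$A_free != 0L]]
  S <- spec$S_fixed
  S[spec$S_free != 0L] <- theta[spec$S_free[spec$S_free != 0L]]
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' \eqn{\Sigma(\theta) = F (I-A)^{-1} S (I-A)^{-T} F^T}, returned over the
#' observed variables (set `observed_only = FALSE` for the full matrix
#' including latents).
#'
#' @param spec a `sem_spec`.
#' @param theta free-parameter vector.
#' @param observed_only return only observed rows/columns (default).
#' @return symmetric covariance matrix.
#' @export
implied_covariance <- function(spec, theta, observed_only = TRUE) {
  mats <- ram_matrices(spec, theta)
  m <- length(spec$all_vars)
  IA <- diag(m) - mats$A
  M <- tryCatch(solve(IA), error = function(e) {
    stop("(I - A) is singular; check the path structure")
  })
  Sigma <- M %*% mats$S %*% t(M)
  Sigma <- (Sigma + t(Sigma)) / 2
  if (observed_only) {
    idx <- match(spec$observed_vars, spec$all_vars)
    Sigma <- Sigma[idx, idx, drop = FALSE]
  }
  Sigma
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' \eqn{F_{ML} = \ln|\Sigma| + tr(S \Sigma^{-1}) - \ln|S| - p}; non-negative,
#' zero exactly when the implied and sample covariance matrices coincide.
#'
#' @param S_sample sample covariance (symmetric positive-definite).
#' @param Sigma implied covariance (symmetric positive-definite).
#' @return scalar discrepancy.
#' @export
ml_discrepancy <- function(S_sample, Sigma) {
  p <- nrow(S_sample)
  if (!is_spd(Sigma) || !is_spd(S_sample)) {
    stop("both covariance matrices must be symmetric positive-definite")
  }
  ld_sigma <- determinant(Sigma, logarithm = TRUE)$modulus
  ld_s <- determinant(S_sample, logarithm = TRUE)$modulus
  as.numeric(ld_sigma + sum(diag(S_sample %*% solve(Sigma))) - ld_s - p)
}

#' Read a model specification from a declarative YAML file
#'
#' The file carries `latents:` (latent -> indicator list), `paths:` (list
#' of `from -> to` strings, optionally `from -> to = value` to fix a
#' coefficient), and optional `covariances:` (`a ~~ b` strings) and
#' `identification:` entries.
#'
#' @param path YAML file path.
#' @return a `sem_spec` via [build_spec()].
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$latents) || is.null(y$paths)) {
    stop("model file needs 'latents' and 'paths' blocks")
  }
  parse_path <- function(s) {
    fixed <- NA_real_
    if (grepl("=", s, fixed = TRUE)) {
      parts <- strsplit(s, "=", fixed = TRUE)[[1]]
      fixed <- as.numeric(trimws(parts[2]))
      s <- parts[1]
    }
    ft <- trimws(strsplit(s, "->", fixed = TRUE)[[1]])
    if (length(ft) != 2L) stop("malformed path: ", s)
    data.frame(from = ft[1], to = ft[2], fixed = fixed,
               stringsAsFactors = FALSE)
  }
  structural <- do.call(rbind, lapply(unlist(y$paths), parse_path))
  covariances <- NULL
  if (!is.null(y$covariances)) {
    covariances <- do.call(rbind, lapply(unlist(y$covariances), function(s) {
      ab <- trimws(strsplit(s, "~~", fixed = TRUE)[[1]])
      if (length(ab) != 2L) stop("malformed covariance: ", s)
      data.frame(a = ab[1], b = ab[2], stringsAsFactors = FALSE)
    }))
  }
  build_spec(measurement = lapply(y$latents, unlist),
             structural = structural, covariances = covariances,
             identification = if (!is.null(y$identification))
               y$identification else "first_loading_fixed_1")
}

# ---- internal ---------------------------------------------------------------

is_acyclic <- function(adj) {
  # adj[i, j] TRUE means edge j -> i; peel sink-free nodes (Kahn)
  m <- nrow(adj)
  alive <- rep(TRUE, m)
  repeat {
    # nodes with no incoming edges among alive
    src <- which(alive & rowSums(adj[, alive, drop = FALSE]) == 0)
    if (!length(src)) break
    alive[src] <- FALSE
    if (!any(alive)) return(TRUE)
  }
  !any(alive)
}
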