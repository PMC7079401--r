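# shared fixtures: tiny models and data built in code

# single-factor triad: 3 indicators, first loading fixed at 1
triad_spec <- function() {
  build_spec(measurement = list(f = c("y1", "y2", "y3")),
             structural = data.frame(from = character(0), to = character(0)))
}

# closed-form single-factor solution for 3 indicators (loading 1 on y1)
triad_closed_form <- function(S) {
  psi <- S[1, 2] * S[1, 3] / S[2, 3]
  lam2 <- S[2, 3] / S[1, 3]
  lam3 <- S[2, 3] / S[1, 2]
  theta <- diag(S) - c(1, lam2, lam3)^2 * psi
  list(psi = psi, lambda = c(1, lam2, lam3), theta = theta)
}

# draw a random recursive coefficient matrix on n nodes (upper bounded
# coefficients; edges only from earlier to later variables)
random_recursive_B <- function(n_nodes, p_edge = 0.5) {
  B <- matrix(0, n_nodes, n_nodes)
  for (i in 2:n_nodes) for (j in 1:(i - 1)) {
    if (stats::runif(1) < p_edge) B[i, j] <- stats::runif(1, -0.8, 0.8)
  }
  B
}

# brute-force total effects: enumerate every directed path j -> ... -> i
# and sum the products of its coefficients
brute_force_total_effects <- function(B) {
  n <- nrow(B)
  total <- matrix(0, n, n)
  walk <- function(start, current, prod) {
    for (nxt in which(B[, current] != 0)) {
      total[nxt, start] <<- total[nxt, start] + prod * B[nxt, current]
      walk(start, nxt, prod * B[nxt, current])
    }
  }
  for (j in 1:n) walk(j, j, 1)
  total
}

# small scored cohort with hand-set EPDS totals
cohort_with_totals <- function(totals) {
  data.frame(subject_id = seq_along(totals), epds_total = totals,
             epds_item10 = 0L)
}
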