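#' Build an EPDS item-parcel scheme
#'
#' Parceling aggregates scale items into composite indicators of the latent
#' factor, which stabilises the measurement model for coarse ordinal items.
#' Two schemes are supported: the fixed assignment used for the antenatal
#' depression measurement model -- parcel 1 = items {1, 4, 9}, parcel 2 =
#' {6, 7, 8}, parcel 3 = {2, 3, 5, 10} -- and seeded uniform random
#' partitions with sizes as equal as possible.
#'
#' The random draw uses only integer permutation of item indices, so a given
#' seed reproduces the same scheme on any platform.
#'
#' @param n_items number of items (10 for the EPDS).
#' @param k number of parcels, `1 <= k <= n_items`.
#' @param scheme `"paper_fixed"` (only valid for 10 items into 3) or
#'   `"random"`.
#' @param seed integer seed for the random scheme.
#' @return object of class `parcel_scheme`: list with `assignment` (integer
#'   vector, `assignment[i]` = parcel of item i), `k`, `scheme`, `seed`.
#' @export
make_parcels <- function(n_items, k, scheme = c("paper_fixed", "random"),
                         seed = NULL) {
  scheme <- match.arg(scheme)
  if (k < 1 || k > n_items) stop("need 1 <= k <= n_items")
  if (scheme == "paper_fixed") {
    if (n_items != 10L || k != 3L) {
      stop("the fixed scheme is defined only for 10 items into 3 parcels")
    }
    assignment <- integer(10)
    assignment[c(1, 4, 9)] <- 1L
    assignment[c(6, 7, 8)] <- 2L
    assignment[c(2, 3, 5, 10)] <- 3L
    sd_used <- NULL
  } else {
    sizes <- rep(n_items %/% k, k)
    extra <- n_items %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    perm <- if (is.null(seed)) {
      sample.int(n_items)
    } else {
      withr_seed(seed, sample.int(n_items))
    }
    assignment <- integer(n_items)
    assignment[perm] <- rep(seq_len(k), times = sizes)
    sd_used <- seed
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 scheme = scheme, seed = sd_used),
            class = "parcel_scheme")
}

#' Parcel scores for one subject's EPDS responses
#'
#' Each parcel score is the sum of its items' distress-coded responses, so
#' the parcel scores always sum to the EPDS total.
#'
#' @param epds_items numeric vector of coded responses, length matching the
#'   scheme.
#' @param scheme a `parcel_scheme`.
#' @return numeric vector of length `scheme$k`.
#' @export
parcel_scores <- function(epds_items, scheme) {
  stopifnot(inherits(scheme, "parcel_scheme"))
  if (length(epds_items) != length(scheme$assignment)) {
    stop("scheme covers ", length(scheme$assignment), " items, got ",
         length(epds_items))
  }
  vapply(seq_len(scheme$k),
         function(p) sum(epds_items[scheme$assignment == p]),
         numeric(1))
}

#' Add parcel-score columns to a scored cohort
#'
#' @param cohort data frame with `epds_1..epds_10` columns.
#' @param scheme a `parcel_scheme` over 10 items (default: the fixed one).
#' @return cohort with columns `parcel_1..parcel_k` appended.
#' @export
parcel_cohort <- function(cohort, scheme = make_parcels(10, 3, "paper_fixed")) {
  items <- as.matrix(cohort[paste0("epds_", seq_along(scheme$assignment))])
  for (p in seq_len(scheme$k)) {
    cohort[[paste0("parcel_", p)]] <-
      rowSums(items[, scheme$assignment == p, drop = FALSE])
  }
  cohort
}

#' Serialize a parcel scheme as JSON
#'
#' @param scheme a `parcel_scheme`.
#' @return JSON string of the form `{"P1":[1,4,9],...}`.
#' @export
parcels_to_json <- function(scheme) {
  lst <- lapply(seq_len(scheme$k),
                function(p) which(scheme$assignment == p))
  names(lst) <- paste0("P", seq_len(scheme$k))
  as.character(jsonlite::toJSON(lst))
}

#' @export
print.parcel_scheme <- function(x, ...) {
  for (p in seq_len(x$k)) {
    cat("P", p, ": {", paste(which(x$assignment == p), collapse = ", "),
        "}\n", sep = "")
  }
  invisible(x)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
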