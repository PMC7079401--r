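#' Score the Edinburgh Postnatal Depression Scale (EPDS)
#'
#' Sums ten item responses already coded 0--3 toward distress and applies the
#' screening cutoffs used for urban Ethiopian populations: totals of 12--16
#' indicate possible antenatal depression, totals of 17 or more are classed
#' for exclusion (high likelihood of serious depression).  A referral flag is
#' raised at a total of 13 or more, or whenever item 10 (thoughts of
#' self-harm) is endorsed at any level.
#'
#' The scorer expects responses in the distress direction; the packaged
#' coding key ([epds_direction_key()]) records which raw items are reverse
#' scored so that CSV readers can apply the convention before scoring.
#'
#' @param responses integer vector of length 10, each element in 0..3.
#' @return An object of class `scale_score`: a list with `total`, `category`
#'   (`"none"`, `"possible_depression"` or `"excluded_high"`) and `flags`
#'   (character vector, possibly empty, drawn from `"self_harm_flag"`,
#'   `"referral_flag"`, `"exclusion_flag"`).
#' @examples
#' score_epds(c(2, 1, 2, 1, 2, 1, 1, 1, 1, 0))
#' @export
score_epds <- function(responses) {
  check_items(responses, n = 10L, lo = 0L, hi = 3L, scale = "EPDS")
  total <- sum(responses)
  category <- if (total >= 17L) "excluded_high"
  else if (total >= 12L) "possible_depression"
  else "none"
  flags <- character(0)
  if (responses[10L] > 0L) flags <- c(flags, "self_harm_flag")
  if (total >= 13L || responses[10L] > 0L) flags <- c(flags, "referral_flag")
  if (total >= 17L) flags <- c(flags, "exclusion_flag")
  new_scale_score("EPDS", total, category, flags)
}

#' Score the Oslo Social Support Scale (OSSS-3)
#'
#' Sums the three items (first item scored 1--4, the remaining two 1--5,
#' total range 3--14) and classifies support as `"poor"` for totals below 9
#' and `"moderate_to_strong"` for 9--14.
#'
#' @param responses integer vector of length 3 on the instrument's Likert
#'   scales (item 1 in 1..4, items 2--3 in 1..5).
#' @return A `scale_score` with `total` in 3..14 and `category`.
#' @export
score_osss3 <- function(responses) {
  if (length(responses) != 3L) {
    stop("OSSS-3 requires exactly 3 item responses, got ", length(responses))
  }
  check_items(responses[1L], n = 1L, lo = 1L, hi = 4L, scale = "OSSS-3 item 1")
  check_items(responses[2:3], n = 2L, lo = 1L, hi = 5L, scale = "OSSS-3 items 2-3")
  total <- sum(responses)
  category <- if (total < 9L) "poor" else "moderate_to_strong"
  new_scale_score("OSSS-3", total, category, character(0))
}

#' Score the four-item perinatal coping inventory (PCI-4)
#'
#' Sums four coping-style items (preparation, avoidance, positive appraisal,
#' prayer), each rated 0 (never) to 3 (most of the time); totals range 0--12.
#' The instrument is summarised by median and interquartile range, so no
#' cutoff category is assigned.
#'
#' @param responses integer vector of length 4, each element in 0..3.
#' @return A `scale_score` with `total` in 0..12 and `category = NA`.
#' @export
score_pci4 <- function(responses) {
  check_items(responses, n = 4L, lo = 0L, hi = 3L, scale = "PCI-4")
  new_scale_score("PCI-4", sum(responses), NA_character_, character(0))
}

#' Classify maternal nutritional status from MUAC
#'
#' Applies a named mid-upper-arm-circumference rule set.  The default
#' `"printed"` rule reproduces the cutoffs exactly as the source protocol
#' prints them -- 18--22 cm "normal", 22.5--31 cm "underweight" -- even
#' though that labelling inverts usual anthropometric practice; a
#' `"conventional"` rule set with the labels the other way around is
#' provided for sensitivity analyses.  Values assigned by neither interval
#' (including the unassigned 22--22.5 cm gap) return `"out_of_range"`.
#'
#' @param muac_cm positive numeric, arm circumference in centimetres.
#' @param rule_set `"printed"` (default) or `"conventional"`.
#' @return character label: `"normal"`, `"underweight"` or `"out_of_range"`.
#' @export
classify_muac <- function(muac_cm, rule_set = c("printed", "conventional")) {
  rule_set <- match.arg(rule_set)
  if (!is.numeric(muac_cm) || length(muac_cm) != 1L || is.na(muac_cm) ||
      muac_cm <= 0) {
    stop("muac_cm must be a single positive number")
  }
  in_low <- muac_cm >= 18 && muac_cm <= 22
  in_high <- muac_cm >= 22.5 && muac_cm <= 31
  if (!in_low && !in_high) return("out_of_range")
  if (rule_set == "printed") {
    if (in_low) "normal" else "underweight"
  } else {
    if (in_low) "underweight" else "normal"
  }
}

#' Cronbach's alpha internal consistency
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i var(item_i) / var(total))}, with all
#' variances taken with the population (divide-by-n) convention so that the
#' estimate agrees with direct evaluation of the formula on small matrices.
#'
#' @param item_matrix numeric matrix, subjects in rows, items in columns;
#'   at least 3 subjects, 2 items, no missing values.
#' @return numeric alpha, or `NA` (with a warning) when the total score has
#'   zero variance.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  if (ncol(item_matrix) < 2L) stop("alpha requires at least 2 items")
  if (nrow(item_matrix) < 3L) stop("alpha requires at least 3 subjects")
  if (anyNA(item_matrix)) stop("alpha requires complete data")
  n <- nrow(item_matrix)
  pop_var <- function(x) sum((x - mean(x))^2) / length(x)
  v_items <- apply(item_matrix, 2L, pop_var)
  v_total <- pop_var(rowSums(item_matrix))
  if (v_total <= .Machine$double.eps * n) {
    warning("total score has zero variance; alpha undefined")
    return(NA_real_)
  }
  k <- ncol(item_matrix)
  k / (k - 1) * (1 - sum(v_items) / v_total)
}

#' Partition a scored cohort into analysis, excluded and referral sets
#'
#' Records whose EPDS total is 17 or more are excluded from analysis (serious
#' depression likely; consent concerns); the remainder form the analysis set.
#' Referral collects every record whose EPDS flags include `referral_flag`
#' (total >= 13 or any endorsement of the self-harm item), regardless of
#' exclusion status.
#'
#' @param records a data frame containing a numeric `epds_total` column (as
#'   produced by [score_cohort()]), one row per participant.
#' @return list with data frames `analysis`, `excluded`, `referral`.
#' @export
apply_eligibility <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (nrow(records) == 0L) {
    return(list(analysis = records, excluded = records, referral = records))
  }
  if (is.null(records$epds_total) || anyNA(records$epds_total)) {
    stop("records must carry a complete epds_total column; score them first")
  }
  excl <- records$epds_total >= 17
  self_harm <- if (!is.null(records$epds_item10)) records$epds_item10 > 0
  else rep(FALSE, nrow(records))
  refer <- records$epds_total >= 13 | self_harm
  list(
    analysis = records[!excl, , drop = FALSE],
    excluded = records[excl, , drop = FALSE],
    referral = records[refer, , drop = FALSE]
  )
}

#' EPDS item scoring directions
#'
#' The standard EPDS key: items 1, 2 and 4 are scored forward (raw response
#' 0--3 taken as-is toward distress) and items 3 and 5--10 reverse scored
#' (coded value = 3 - raw).  [read_cohort()] applies this key when a cohort
#' file carries raw responses.
#'
#' @return integer vector of length 10; +1 forward, -1 reverse.
#' @export
epds_direction_key <- function() {
  c(1L, 1L, -1L, 1L, -1L, -1L, -1L, -1L, -1L, -1L)
}

#' Score every instrument for a cohort table
#'
#' Adds EPDS, OSSS-3 and PCI-4 totals, categories and flags, and the MUAC
#' label, to a cohort data frame whose item columns follow the packaged
#' naming convention (`epds_1..epds_10`, `osss3_1..osss3_3`,
#' `pci4_1..pci4_4`, `muac_cm`).  Records with missing items are rejected:
#' the analysis is complete-case by design.
#'
#' @param cohort data frame of subject records (see [generate_cohort()] or
#'   [read_cohort()]).
#' @return the cohort with columns `epds_total`, `epds_category`,
#'   `epds_item10`, `referral_flag`, `self_harm_flag`, `osss3_total`,
#'   `osss3_category`, `pci4_total`, `muac_label` appended.
#' @export
score_cohort <- function(cohort) {
  epds_cols <- paste0("epds_", 1:10)
  osss_cols <- paste0("osss3_", 1:3)
  pci_cols <- paste0("pci4_", 1:4)
  need <- c(epds_cols, osss_cols, pci_cols)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks item columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(cohort[need])) stop("missing item responses; complete cases only")
  ep <- lapply(seq_len(nrow(cohort)), function(i) {
    score_epds(as.integer(cohort[i, epds_cols]))
  })
  os <- lapply(seq_len(nrow(cohort)), function(i) {
    score_osss3(as.integer(cohort[i, osss_cols]))
  })
  cohort$epds_total <- vapply(ep, `[[`, numeric(1), "total")
  cohort$epds_category <- vapply(ep, `[[`, character(1), "category")
  cohort$epds_item10 <- cohort$epds_10
  cohort$self_harm_flag <- vapply(ep, function(s) "self_harm_flag" %in% s$flags, logical(1))
  cohort$referral_flag <- vapply(ep, function(s) "referral_flag" %in% s$flags, logical(1))
  cohort$osss3_total <- vapply(os, `[[`, numeric(1), "total")
  cohort$osss3_category <- vapply(os, `[[`, character(1), "category")
  cohort$pci4_total <- rowSums(cohort[pci_cols])
  if (!is.null(cohort$muac_cm)) {
    cohort$muac_label <- vapply(cohort$muac_cm, classify_muac, character(1))
  }
  cohort
}

#' Read a cohort CSV with optional column mapping and EPDS direction coding
#'
#' @param path CSV file of one row per participant.
#' @param column_map optional named character vector mapping file column
#'   names to the packaged convention (`c(file_name = "epds_1", ...)`).
#' @param epds_raw logical; if `TRUE` the EPDS columns carry raw instrument
#'   responses and [epds_direction_key()] is applied to produce
#'   distress-coded 0--3 values.
#' @return a cohort data frame.
#' @export
read_cohort <- function(path, column_map = NULL, epds_raw = FALSE) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(cohort))
    if (anyNA(idx)) {
      stop("column_map names absent from file: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "))
    }
    names(cohort)[idx] <- unname(column_map)
  }
  if (epds_raw) {
    key <- epds_direction_key()
    for (i in 1:10) {
      col <- paste0("epds_", i)
      if (key[i] < 0) cohort[[col]] <- 3L - cohort[[col]]
    }
  }
  cohort
}

# ---- internal helpers -------------------------------------------------------

new_scale_score <- function(scale, total, category, flags) {
  structure(list(scale = scale, total = total, category = category,
                 flags = flags),
            class = "scale_score")
}

#' @export
print.scale_score <- function(x, ...) {
  cat(x$scale, "total:", x$total)
  if (!is.na(x$category)) cat(" [", x$category, "]", sep = "")
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = ","))
  cat("\n")
  invisible(x)
}

check_items <- function(x, n, lo, hi, scale) {
  if (length(x) != n) {
    stop(scale, " requires exactly ", n, " item responses, got ", length(x))
  }
  if (anyNA(x)) stop(scale, ": missing item response; records with missing items are rejected")
  if (!is.numeric(x) || any(x != as.integer(x))) {
    stop(scale, ": responses must be integer codes")
  }
  if (any(x < lo | x > hi)) {
    stop(scale, ": response out of range ", lo, "..", hi)
  }
  invisible(TRUE)
}
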