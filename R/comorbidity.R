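#' Build a 2x2 person-level contingency table for one condition code
#'
#' Counts distinct persons (a person with repeated admissions of the same
#' code counts once per cell). A person is index-positive when they have
#' at least one admission with any of the `index_codes`. Cells: a = index
#' and code, b = index without code, c = code without index, d = neither.
#'
#' @param admissions data.frame (person_id, icd10_code)
#' @param index_codes character vector of index-condition codes
#' @param code the condition code to cross-tabulate
#' @return named integer vector c(a, b, c, d)
#' @export
build_contingency <- function(admissions, index_codes, code) {
  assert_columns(admissions, c("person_id", "icd10_code"), "admission table")
  if (nrow(admissions) == 0) stop_input("admission table is empty")
  if (code %in% index_codes) {
    stop_input("code ", code, " is an index code (self-comparison)")
  }
  persons <- unique(admissions$person_id)
  idx <- unique(admissions$person_id[admissions$icd10_code %in% index_codes])
  has <- unique(admissions$person_id[admissions$icd10_code == code])
  a <- length(intersect(idx, has))
  b <- length(idx) - a
  cc <- length(has) - a
  d <- length(persons) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Fisher exact test and sample odds ratio for a 2x2 table
#'
#' The odds ratio is the sample ratio `(a d) / (b c)` (Inf when `b c = 0`
#' with a positive numerator; NaN when both products are 0 - an undefined
#' OR). The two-sided p-value is the Fisher exact probability: the sum of
#' hypergeometric table probabilities no larger than the observed one.
#' The 95% confidence interval uses the log-OR normal approximation, with
#' a 0.5 continuity correction added to every cell when any cell is 0.
#'
#' @param a,b,c,d non-negative integer cell counts (index&code,
#'   index&!code, !index&code, neither); alternatively `a` may be a 2x2
#'   matrix
#' @return list(odds_ratio, p, ci_low, ci_high)
#' @export
fisher_or <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_input("cell counts must be non-negative integers")
  }
  or <- (as.numeric(a) * as.numeric(d)) / (as.numeric(b) * as.numeric(c))
  p <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  log_or <- log((cc[1] * cc[4]) / (cc[2] * cc[3]))
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(0.975)
  list(odds_ratio = or, p = p,
       ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se))
}

#' Condition co-occurrence with an index condition
#'
#' For every non-index condition code present in the admission records,
#' builds the person-level 2x2 table against the index condition, computes
#' the sample odds ratio and Fisher exact p, applies multiple-testing
#' correction over all tested codes, and flags records with adjusted
#' p <= `alpha`.
#'
#' @param admissions data.frame (person_id, icd10_code)
#' @param index_codes character vector of index-condition codes
#'   (e.g. c("F840", "F845"))
#' @param alpha adjusted-p significance threshold
#' @param correction p-value adjustment method: "BH" (default) or
#'   "bonferroni" (any method of [stats::p.adjust()])
#' @param min_count skip codes carried by fewer persons than this
#' @return data.frame (code, a, b, c, d, odds_ratio, p_fisher, p_adjusted,
#'   ci_low, ci_high, significant), sorted by adjusted p then code
#' @export
run_comorbidity <- function(admissions, index_codes, alpha = 0.05,
                            correction = "BH", min_count = 1) {
  assert_columns(admissions, c("person_id", "icd10_code"), "admission table")
  u <- unique(admissions[c("person_id", "icd10_code")])
  persons <- unique(u$person_id)
  n_total <- length(persons)
  idx <- unique(u$person_id[u$icd10_code %in% index_codes])
  n_idx <- length(idx)
  codes <- setdiff(sort(unique(u$icd10_code)), index_codes)
  is_idx <- u$person_id %in% idx
  a_by_code <- table(factor(u$icd10_code[is_idx], levels = codes))
  n_by_code <- table(factor(u$icd10_code, levels = codes))
  keep <- as.integer(n_by_code) >= min_count
  codes <- codes[keep]
  a <- as.integer(a_by_code)[keep]
  n_code <- as.integer(n_by_code)[keep]
  b <- n_idx - a
  cc <- n_code - a
  d <- n_total - n_idx - cc
  stats_list <- lapply(seq_along(codes), function(i) {
    fisher_or(a[i], b[i], cc[i], d[i])
  })
  res <- data.frame(
    code = codes, a = a, b = b, c = cc, d = d,
    odds_ratio = vapply(stats_list, `[[`, numeric(1), "odds_ratio"),
    p_fisher = vapply(stats_list, `[[`, numeric(1), "p"),
    ci_low = vapply(stats_list, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(stats_list, `[[`, numeric(1), "ci_high"),
    stringsAsFactors = FALSE
  )
  res$p_adjusted <- stats::p.adjust(res$p_fisher, method = correction)
  res$significant <- res$p_adjusted <= alpha
  res <- res[order(res$p_adjusted, res$code), , drop = FALSE]
  rownames(res) <- NULL
  res
}
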