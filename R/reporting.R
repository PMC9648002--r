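#' Category accounting report
#'
#' Turns a named vector of category counts into the standard
#' count-and-percentage accounting used throughout the comparison
#' figures: raw percentages are `100 * count / total` (summing to 100
#' exactly over a partition) and the rendered two-decimal labels use
#' round-half-up.
#'
#' @param counts Named non-negative counts; total must be positive.
#' @return A data frame of class `classification_report`: `category`,
#'   `count`, `percent` (raw), `percent_label` (two-decimal string);
#'   total in attribute `total`.
#' @examples
#' classification_report(c(identical = 36773, equivalent = 3995,
#'                         mapped_no_call = 682, unmapped = 219))
#' @export
classification_report <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  pct <- 100 * counts / total
  out <- data.frame(category = names(counts), count = as.numeric(counts),
                    percent = as.numeric(pct),
                    percent_label = sprintf("%.2f", round_half_up(pct, 2)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- total
  class(out) <- c("classification_report", "data.frame")
  out
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percent reduction between two counts
#'
#' `100 * (before - after) / before`, the "X% less" arithmetic used
#' when comparing callset sizes between references.
#'
#' @param count_before,count_after Counts; `count_before` must be
#'   positive.
#' @return A list: `percent` (raw), `label` (one-decimal string).
#' @examples
#' reduction_report(7475, 3154) # 57.8% less
#' @export
reduction_report <- function(count_before, count_after) {
  if (count_before <= 0) stop("count_before must be positive")
  pct <- 100 * (count_before - count_after) / count_before
  list(percent = pct, label = sprintf("%.1f", round_half_up(pct, 1)))
}

#' Validation rate
#'
#' `100 * confirmed / tested`, e.g. for orthogonal (Sanger)
#' confirmation of selected variant calls.
#'
#' @param confirmed,tested Non-negative counts with
#'   `confirmed <= tested` and `tested > 0`.
#' @return Percent confirmed (numeric).
#' @examples
#' validation_rate(8, 10) # 80
#' @export
validation_rate <- function(confirmed, tested) {
  if (tested <= 0) stop("tested must be positive")
  if (confirmed < 0 || confirmed > tested)
    stop("confirmed must be in [0, tested]")
  100 * confirmed / tested
}
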