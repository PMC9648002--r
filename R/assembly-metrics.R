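#' Assembly contiguity statistics (N50, L50, Top-k)
#'
#' Computes the standard contiguity summary of a scaffold length
#' distribution plus the Top50 statistic: the summed length of the 50
#' longest scaffolds. For a human-scale assembly with 48 chromosome
#' arms, Top50 approaches the total assembly size as scaffolds reach
#' arm scale, which makes it a convenient single-number monitor during
#' scaffolding. N50 is the length of the scaffold at which the
#' cumulative sum of descending-sorted lengths first reaches half the
#' total (ties resolved toward the smaller rank), and L50 is that
#' scaffold's rank.
#'
#' @param x A [ScaffoldSet] or a numeric vector of scaffold lengths.
#' @param top_k Number of longest scaffolds summed (default 50).
#' @param min_len Scaffolds shorter than this are dropped before any
#'   statistic is computed (fractions therefore use the post-filter
#'   total). Default 0; a 10 kb floor is conventional for scaffold-level
#'   reporting.
#' @return A one-row data frame: `n_scaffolds`, `total_bp`, `top50_bp`,
#'   `top50_fraction`, `n50_bp`, `l50`, `largest_bp`.
#' @examples
#' compute_scaffold_stats(c(10, 5, 3, 2))
#' @export
compute_scaffold_stats <- function(x, top_k = 50L, min_len = 0L) {
  lengths <- if (inherits(x, "ScaffoldSet")) scaffold_lengths(x) else x
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0) stop("no scaffolds")
  if (any(is.na(lengths) | lengths <= 0))
    stop("scaffold lengths must be positive")
  lengths <- lengths[lengths >= min_len]
  if (length(lengths) == 0)
    stop("no scaffolds pass the min_len filter")
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  cum <- cumsum(srt)
  l50 <- which(cum >= total / 2)[1]
  top <- sum(srt[seq_len(min(top_k, length(srt)))])
  data.frame(n_scaffolds = length(srt), total_bp = total,
             top50_bp = top, top50_fraction = top / total,
             n50_bp = srt[l50], l50 = l50, largest_bp = srt[1])
}
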