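# Euclidean-distance (ED) association statistic for pooled sequencing.

#' Euclidean distance between the two pools' allele-frequency vectors
#'
#' For a biallelic site with allele frequency `p` in one pool and `q`
#' in the other, the ED statistic is the Euclidean distance between
#' the two pools' (allele, other-allele) frequency vectors,
#' `sqrt((p - q)^2 + ((1 - p) - (1 - q))^2)`, which ranges from 0
#' (identical pools) to `sqrt(2)` (pools fixed for opposite alleles).
#' The statistic is symmetric in the pools and independent of which
#' allele the frequencies refer to.
#'
#' @param p,q Allele frequencies of the same allele in the two pools
#'   (vectorised).
#' @return ED values in \[0, sqrt(2)\].
#' @examples
#' ed_statistic(1, 0)       # sqrt(2)
#' ed_statistic(0.8, 0.3)   # sqrt(0.5)
#' @export
ed_statistic <- function(p, q) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE),
            all(q >= 0 & q <= 1, na.rm = TRUE))
  sqrt((p - q)^2 + ((1 - p) - (1 - q))^2)
}

#' Power transform of the ED statistic
#'
#' Raising ED to a power `k > 1` suppresses background noise relative
#' to true peaks before track fitting; `k = 1` disables the transform.
#'
#' @param ed Non-negative ED values.
#' @param k Exponent, at least 1 (default 5).
#' @return `ed^k`.
#' @export
ed_power <- function(ed, k = 5) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("`k` must be a single number >= 1", call. = FALSE)
  }
  if (any(ed < 0, na.rm = TRUE)) stop("`ed` must be >= 0", call. = FALSE)
  ed^k
}

#' Per-site ED statistic for a variant table
#'
#' Computes each pool's alternate-allele frequency, the ED statistic
#' and its power transform. Sites with zero depth in either pool get
#' missing values.
#'
#' @param variants Variant table as in a `bsa_dataset`.
#' @param k Exponent for [ed_power()] (default 5).
#' @return The input with `freq_sterile`, `freq_fertile`, `ed` and
#'   `ed_pow` appended.
#' @export
compute_ed <- function(variants, k = 5) {
  variants <- tibble::as_tibble(variants)
  tot_s <- variants$ref_sterile + variants$alt_sterile
  tot_f <- variants$ref_fertile + variants$alt_fertile
  p <- ifelse(tot_s > 0, variants$alt_sterile / tot_s, NA_real_)
  q <- ifelse(tot_f > 0, variants$alt_fertile / tot_f, NA_real_)
  variants$freq_sterile <- p
  variants$freq_fertile <- q
  variants$ed <- ifelse(is.na(p) | is.na(q), NA_real_, ed_statistic(
    ifelse(is.na(p), 0, p), ifelse(is.na(q), 0, q)))
  variants$ed_pow <- ed_power(variants$ed, k)
  variants
}

#' Median + 3 SD threshold
#'
#' Threshold rule for the ED scan: the median of the fitted values
#' plus three sample standard deviations (n - 1 denominator).
#'
#' @param fitted Fitted values (a `scan_track` or a numeric vector);
#'   missing values are dropped.
#' @return The threshold value.
#' @examples
#' median_3sd_threshold(c(0, 0, 0, 0, 1))   # 0 + 3 * 0.4472 = 1.3416
#' @export
median_3sd_threshold <- function(fitted) {
  if (inherits(fitted, "scan_track")) fitted <- fitted$windows$fitted
  fitted <- fitted[!is.na(fitted)]
  if (length(fitted) < 2) {
    stop("need at least two non-missing fitted values", call. = FALSE)
  }
  stats::median(fitted) + 3 * stats::sd(fitted)
}
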