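# End-to-end scan driver: filter -> statistic -> fitted track ->
# threshold -> candidate regions.

#' Run a bulked-segregant association scan
#'
#' Applies the four-rule variant filter, computes the chosen per-site
#' statistic (delta-SNP-index or powered ED), fits sliding-window
#' tracks per chromosome, derives the threshold, and extracts
#' candidate regions.
#'
#' Threshold rules:
#' * `"theoretical"` — the cross model's expected delta at the causal
#'   locus (2/3 for the default selfed-F2 recessive design); only
#'   meaningful for `stat = "delta"`.
#' * `"percentile"` — genome-wide `q`-th percentile of the fitted
#'   values (default `q = 99`).
#' * `"median3sd"` — median + 3 SD of the fitted values (the usual ED
#'   rule).
#' * `"fixed"` — a user-supplied value (e.g. a relaxed 0.56 delta
#'   threshold).
#'
#' @param variants Variant table (a `bsa_dataset$variants` or the
#'   output of [read_bsa_vcf()]).
#' @param stat `"delta"` (delta-SNP-index) or `"ed"` (powered ED).
#' @param threshold Threshold rule, one of `"theoretical"`,
#'   `"percentile"`, `"median3sd"`, `"fixed"`.
#' @param fixed_value Threshold value when `threshold = "fixed"`.
#' @param q Percentile when `threshold = "percentile"` (default 99).
#' @param cross [cross_model()] for the theoretical threshold.
#' @param ed_k Exponent for the ED power transform (default 5).
#' @param window_bp,step_bp,min_sites Window-fitting parameters, see
#'   [fit_track()].
#' @param min_support,het_band,support_mode,parent_rule Filter
#'   parameters, see [filter_variants()].
#' @return List of class `bsa_scan` with `sites` (per-site statistics
#'   of surviving variants), `track` (`scan_track`), `threshold`
#'   (value), `threshold_rule`, `regions` and `filter_report`.
#' @export
bsa_scan <- function(variants,
                     stat = c("delta", "ed"),
                     threshold = c("theoretical", "percentile",
                                   "median3sd", "fixed"),
                     fixed_value = NULL, q = 99,
                     cross = cross_model(), ed_k = 5,
                     window_bp = 1e6, step_bp = 1e4, min_sites = 3,
                     min_support = 4, het_band = c(0.2, 0.8),
                     support_mode = "pool", parent_rule = TRUE) {
  stat <- match.arg(stat)
  threshold <- match.arg(threshold)
  filt <- filter_variants(variants, min_support = min_support,
                          het_band = het_band,
                          support_mode = support_mode,
                          parent_rule = parent_rule)
  if (stat == "delta") {
    sites <- compute_snp_index(filt$variants)
    value_col <- "delta"
  } else {
    sites <- compute_ed(filt$variants, k = ed_k)
    value_col <- "ed_pow"
  }
  track <- fit_scan_track(sites, value_col = value_col,
                          window_bp = window_bp, step_bp = step_bp,
                          min_sites = min_sites)
  thr <- switch(threshold,
    theoretical = {
      if (stat != "delta") {
        stop("the theoretical threshold applies to the delta-SNP-index ",
             "scan only", call. = FALSE)
      }
      theoretical_delta(cross)
    },
    percentile = percentile_threshold(track, q),
    median3sd = median_3sd_threshold(track),
    fixed = {
      if (is.null(fixed_value)) {
        stop("`fixed_value` is required for a fixed threshold",
             call. = FALSE)
      }
      fixed_value
    }
  )
  regions <- extract_regions(track, thr)
  structure(
    list(sites = sites, track = track, threshold = thr,
         threshold_rule = threshold, regions = regions,
         filter_report = filt$report, stat = stat),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  counts <- filter_report_counts(x$filter_report)
  cat("<bsa_scan> statistic:", x$stat,
      "| sites:", counts[["output"]], "of", counts[["input"]],
      "| threshold:", format(x$threshold, digits = 4),
      paste0("(", x$threshold_rule, ")"),
      "| regions:", nrow(x$regions), "\n")
  invisible(x)
}

#' Top-peak candidate region
#'
#' @param scan A `bsa_scan` (or a regions tibble).
#' @return The single region row with the highest peak, or an empty
#'   tibble when no region was found.
#' @export
top_region <- function(scan) {
  regions <- if (inherits(scan, "bsa_scan")) scan$regions else scan
  if (nrow(regions) == 0) return(regions)
  regions[which.max(regions$peak), ]
}
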