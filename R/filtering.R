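# Four-rule variant filter applied to pooled SNP calls before the
# association scan:
#   R1 multiallelic     - more than one alternate allele at the site
#   R2 low support      - insufficient read support in a pool
#   R3 same genotype    - both pools have the same inferred pool genotype
#   R4 parent mismatch  - the allele fixed in the recessive (sterile)
#                         pool is not carried by the recessive parent
# Rules are applied in that fixed order and each removed site is
# attributed to the first rule it fails.

#' Call a pool genotype from allele depths
#'
#' Coarse per-pool genotype from the alternate-allele read fraction
#' `f = alt / (ref + alt)`: `ref_fixed` when `f` is below the
#' heterozygous band, `alt_fixed` above it, `het_like` inside it, and
#' `no_call` at zero depth. This operationalises "same genotype between
#' mixed pools" for rule R3.
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorised).
#' @param het_band Numeric `(low, high)` frequency band called
#'   heterozygous-like; default `c(0.2, 0.8)`, chosen to be robust at
#'   ~34x pool depth.
#' @return Character vector in
#'   `{"ref_fixed", "het_like", "alt_fixed", "no_call"}`.
#' @examples
#' infer_pool_genotype(0, 30)    # alt_fixed
#' infer_pool_genotype(15, 15)   # het_like
#' infer_pool_genotype(27, 9)    # f = 0.25: het_like
#' @export
infer_pool_genotype <- function(ref_depth, alt_depth,
                                het_band = c(0.2, 0.8)) {
  stopifnot(length(het_band) == 2, het_band[1] < het_band[2])
  if (any(ref_depth < 0 | alt_depth < 0, na.rm = TRUE)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  total <- ref_depth + alt_depth
  f <- alt_depth / total
  out <- rep("het_like", length(f))
  out[f < het_band[1]] <- "ref_fixed"
  out[f > het_band[2]] <- "alt_fixed"
  out[total == 0] <- "no_call"
  out
}

# allele carried by a diploid "a/b"-style genotype string, as a list of
# allele indices (0 = REF, 1 = first ALT, ...)
.gt_alleles <- function(gt) {
  lapply(strsplit(gt, "[/|]"), function(x) {
    suppressWarnings(as.integer(x[x != "."]))
  })
}

#' Filter variants with the four BSA-seq rules
#'
#' Applies, in order: (R1) drop sites with more than one alternate
#' allele; (R2) drop sites with insufficient read support (by default,
#' either pool's total depth below `min_support`); (R3) drop sites
#' where both pools have the same inferred pool genotype (see
#' [infer_pool_genotype()]); (R4) drop sites where the allele fixed in
#' the sterile pool is not carried by the sterile (recessive) parent.
#' Input order is preserved in the output.
#'
#' `support_mode = "allele"` reads the support rule per allele instead:
#' a site is dropped if, in either pool, an allele observed in at least
#' one read has fewer than `min_support` supporting reads.
#'
#' @param variants Variant table as in a `bsa_dataset`: columns
#'   `chrom`, `pos`, `n_alt`, `gt_parent_sterile`, `gt_parent_fertile`,
#'   `ref_sterile`, `alt_sterile`, `ref_fertile`, `alt_fertile`.
#' @param min_support Minimum read support (default 4).
#' @param het_band Passed to [infer_pool_genotype()].
#' @param support_mode `"pool"` (per-pool total depth, default) or
#'   `"allele"` (per observed allele).
#' @param parent_rule Apply R4? Requires parental genotypes; default
#'   `TRUE`.
#' @return List with `variants` (the surviving rows) and `report`
#'   (tibble: `rule`, `removed`, plus attributes via
#'   [filter_report_counts()]).
#' @export
filter_variants <- function(variants, min_support = 4,
                            het_band = c(0.2, 0.8),
                            support_mode = c("pool", "allele"),
                            parent_rule = TRUE) {
  support_mode <- match.arg(support_mode)
  variants <- tibble::as_tibble(variants)
  n <- nrow(variants)
  if (n == 0) {
    report <- tibble::tibble(
      rule = c("R1_multiallelic", "R2_low_support",
               "R3_same_pool_genotype", "R4_not_from_recessive_parent"),
      removed = 0L
    )
    attr(report, "input_count") <- 0L
    attr(report, "output_count") <- 0L
    return(list(variants = variants, report = report))
  }

  fail_r1 <- variants$n_alt > 1L

  tot_s <- variants$ref_sterile + variants$alt_sterile
  tot_f <- variants$ref_fertile + variants$alt_fertile
  if (support_mode == "pool") {
    fail_r2 <- tot_s < min_support | tot_f < min_support
  } else {
    low <- function(d) d > 0 & d < min_support
    fail_r2 <- low(variants$ref_sterile) | low(variants$alt_sterile) |
      low(variants$ref_fertile) | low(variants$alt_fertile) |
      tot_s == 0 | tot_f == 0
  }

  gt_s <- infer_pool_genotype(variants$ref_sterile, variants$alt_sterile,
                              het_band)
  gt_f <- infer_pool_genotype(variants$ref_fertile, variants$alt_fertile,
                              het_band)
  fail_r3 <- gt_s == gt_f

  if (parent_rule) {
    if (!all(c("gt_parent_sterile", "gt_parent_fertile") %in%
               names(variants)) ||
        anyNA(variants$gt_parent_sterile)) {
      stop("parental genotypes are required for the recessive-parent ",
           "rule (R4); disable it with `parent_rule = FALSE`",
           call. = FALSE)
    }
    parent_alleles <- .gt_alleles(variants$gt_parent_sterile)
    fixed_allele <- rep(NA_integer_, n)    # 0 = REF, 1 = ALT
    fixed_allele[gt_s == "ref_fixed"] <- 0L
    fixed_allele[gt_s == "alt_fixed"] <- 1L
    fail_r4 <- !is.na(fixed_allele) &
      !mapply(function(a, alleles) a %in% alleles,
              fixed_allele, parent_alleles)
  } else {
    fail_r4 <- rep(FALSE, n)
  }

  # attribute each removal to the first failing rule
  removed_by <- rep(NA_character_, n)
  removed_by[fail_r4] <- "R4_not_from_recessive_parent"
  removed_by[fail_r3] <- "R3_same_pool_genotype"
  removed_by[fail_r2] <- "R2_low_support"
  removed_by[fail_r1] <- "R1_multiallelic"

  keep <- is.na(removed_by)
  report <- tibble::tibble(
    rule = c("R1_multiallelic", "R2_low_support",
             "R3_same_pool_genotype", "R4_not_from_recessive_parent"),
    removed = c(sum(removed_by == "R1_multiallelic", na.rm = TRUE),
                sum(removed_by == "R2_low_support", na.rm = TRUE),
                sum(removed_by == "R3_same_pool_genotype", na.rm = TRUE),
                sum(removed_by == "R4_not_from_recessive_parent",
                    na.rm = TRUE))
  )
  attr(report, "input_count") <- n
  attr(report, "output_count") <- sum(keep)
  list(variants = variants[keep, , drop = FALSE], report = report)
}

#' Summarise a filter report
#'
#' @param report The `report` element returned by [filter_variants()].
#' @return Named vector with input count, per-rule removals and output
#'   count.
#' @export
filter_report_counts <- function(report) {
  c(input = attr(report, "input_count"),
    stats::setNames(report$removed, report$rule),
    output = attr(report, "output_count"))
}
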