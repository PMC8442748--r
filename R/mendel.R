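#' Describe the mapping cross
#'
#' A cross model captures the Mendelian design behind a bulked-segregant
#' experiment: how the segregating population was produced, whether the
#' trait allele is recessive or dominant, and the penetrance of the
#' trait genotype. All theoretical expectations used by the association
#' scan (segregation ratios, expected bulk allele frequencies, the
#' theoretical delta-SNP-index threshold) derive from this object.
#'
#' @param design Either `"F2_self"` (selfed F1 hybrids, genotypes
#'   segregating 1:2:1) or `"backcross"` (F1 crossed back to the
#'   recessive parent, genotypes 1:1).
#' @param dominance Mode of action of the trait allele. Only
#'   `"recessive"` is currently supported; the trait phenotype then
#'   requires two copies of the trait allele.
#' @param penetrance Probability in (0, 1] that the trait genotype
#'   expresses the trait phenotype. Default 1 (full penetrance).
#'
#' @return An object of class `cross_model`.
#' @examples
#' cross_model()                      # selfed F2, recessive, fully penetrant
#' cross_model("backcross")
#' @export
cross_model <- function(design = c("F2_self", "backcross"),
                        dominance = "recessive",
                        penetrance = 1) {
  design <- match.arg(design)
  dominance <- match.arg(dominance, "recessive")
  if (!is.numeric(penetrance) || length(penetrance) != 1 ||
      penetrance <= 0 || penetrance > 1) {
    stop("`penetrance` must be a single value in (0, 1]", call. = FALSE)
  }
  structure(
    list(design = design, dominance = dominance, penetrance = penetrance),
    class = "cross_model"
  )
}

#' @export
print.cross_model <- function(x, ...) {
  cat("<cross_model> ", x$design, ", ", x$dominance,
      ", penetrance ", format(x$penetrance), "\n", sep = "")
  invisible(x)
}

#' Expected phenotypic segregation ratio
#'
#' Expected ratio of dominant-phenotype to recessive-phenotype plants
#' under the cross model. For a selfed F2 with a fully penetrant
#' recessive trait this is the classical 3:1; a backcross to the
#' recessive parent gives 1:1. Penetrance below one moves plants from
#' the recessive-phenotype class into the dominant-phenotype class
#' (e.g. penetrance 0.5 in an F2 gives 7:1).
#'
#' @param cross A [cross_model()].
#' @return Named numeric vector `c(dominant = , recessive = )`, scaled
#'   so the recessive-class weight is 1.
#' @examples
#' expected_ratio(cross_model())                 # 3:1
#' expected_ratio(cross_model("backcross"))      # 1:1
#' @export
expected_ratio <- function(cross) {
  stopifnot(inherits(cross, "cross_model"))
  p <- cross$penetrance
  rec_frac <- switch(cross$design,
    F2_self   = p / 4,
    backcross = p / 2
  )
  c(dominant = (1 - rec_frac) / rec_frac, recessive = 1)
}

#' Chi-square goodness-of-fit test for a two-class segregation ratio
#'
#' Pearson chi-square test of observed phenotype counts against the
#' counts implied by an expected ratio, with 1 degree of freedom. Used
#' to test whether a segregating family is consistent with Mendelian
#' expectations (e.g. fertile:sterile 3:1 in an F2).
#'
#' No continuity correction is applied by default; set `yates = TRUE`
#' for the Yates-corrected statistic.
#'
#' @param observed Integer vector of length 2: counts in the
#'   (dominant, recessive) phenotype classes.
#' @param ratio Expected weights for the two classes, e.g. `c(3, 1)` or
#'   the output of [expected_ratio()].
#' @param yates Apply Yates' continuity correction? Default `FALSE`.
#' @return List with `chi2`, `df` (always 1) and `p`.
#' @examples
#' chi_square_gof(c(45, 15), c(3, 1))   # perfect 3:1 fit: chi2 = 0
#' chi_square_gof(c(178, 62), c(3, 1))
#' @export
chi_square_gof <- function(observed, ratio = c(3, 1), yates = FALSE) {
  if (length(observed) != 2 || any(observed < 0)) {
    stop("`observed` must be two non-negative counts", call. = FALSE)
  }
  if (length(ratio) != 2 || any(ratio <= 0)) {
    stop("`ratio` must be two positive weights", call. = FALSE)
  }
  n <- sum(observed)
  if (n == 0) stop("total observed count is zero", call. = FALSE)
  expected <- n * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Expected trait-allele frequency within a phenotype-selected bulk
#'
#' The frequency of the recessive (trait) allele expected among plants
#' of one phenotype class, at the causal locus and at infinite
#' sequencing depth. For a fully penetrant recessive trait in an F2:
#' the recessive-phenotype bulk is entirely `aa`, frequency 1; the
#' dominant-phenotype bulk is `AA:Aa = 1:2`, frequency 1/3.
#'
#' @param cross A [cross_model()].
#' @param bulk_class `"recessive"` or `"dominant"`: which phenotype
#'   class the bulk was drawn from.
#' @return Expected allele frequency in \[0, 1\].
#' @examples
#' expected_bulk_freq(cross_model(), "recessive")  # 1
#' expected_bulk_freq(cross_model(), "dominant")   # 1/3
#' @export
expected_bulk_freq <- function(cross, bulk_class = c("recessive", "dominant")) {
  stopifnot(inherits(cross, "cross_model"))
  bulk_class <- match.arg(bulk_class)
  p <- cross$penetrance
  if (bulk_class == "recessive") {
    # the trait-phenotype class is always pure aa under a recessive model
    return(1)
  }
  switch(cross$design,
    # dominant-phenotype class: AA 1/4, Aa 1/2, non-penetrant aa (1-p)/4
    F2_self   = (2 - p) / (4 - p),
    # backcross to aa: Aa 1/2, non-penetrant aa (1-p)/2
    backcross = (3 - 2 * p) / (2 * (2 - p))
  )
}

#' Theoretical delta-SNP-index at the causal locus
#'
#' The expected difference between the two bulks' SNP indices at the
#' causal locus, at infinite depth: the theoretical association
#' threshold of a QTL-seq style scan. For the default selfed-F2 fully
#' penetrant recessive design this is 1 - 1/3 = 2/3 (0.667 to three
#' decimals).
#'
#' @param cross A [cross_model()].
#' @return The expected delta-SNP-index in \[0, 1\].
#' @examples
#' theoretical_delta(cross_model())   # 2/3
#' @export
theoretical_delta <- function(cross = cross_model()) {
  expected_bulk_freq(cross, "recessive") - expected_bulk_freq(cross, "dominant")
}
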