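# SNP-index / delta-SNP-index association scan: per-site indices
# oriented on the sterile-parent allele, sliding-window fitting,
# thresholds and candidate-region extraction.

# Which allele (0 = REF, 1 = ALT) is the sterile-parent allele at each
# site, from the two homozygous parental genotypes. Errors when a
# parent is not homozygous or the parents do not differ.
.sterile_allele <- function(variants) {
  a_s <- .gt_alleles(variants$gt_parent_sterile)
  a_f <- .gt_alleles(variants$gt_parent_fertile)
  hom <- function(a) length(a) > 0 && length(unique(a)) == 1
  ok_s <- vapply(a_s, hom, TRUE)
  ok_f <- vapply(a_f, hom, TRUE)
  if (!all(ok_s & ok_f)) {
    i <- which(!(ok_s & ok_f))[1]
    stop("parent genotypes at ", variants$chrom[i], ":", variants$pos[i],
         " are not homozygous; cannot orient the SNP index", call. = FALSE)
  }
  s <- vapply(a_s, `[`, 0L, 1L)
  f <- vapply(a_f, `[`, 0L, 1L)
  if (any(s == f)) {
    i <- which(s == f)[1]
    stop("parents share the same genotype at ", variants$chrom[i], ":",
         variants$pos[i], "; SNP-index orientation is undefined",
         call. = FALSE)
  }
  s
}

#' Per-site SNP index and delta-SNP-index
#'
#' The SNP index of a pool at a biallelic site is the fraction of its
#' reads carrying the sterile-parent allele (the allele homozygous in
#' the sterile parent); the delta-SNP-index is the sterile bulk's index
#' minus the fertile bulk's. Near a recessive causal locus the sterile
#' bulk's index approaches 1, the fertile bulk's 1/3, and the delta
#' 2/3; away from it both indices hover around 1/2 and the delta
#' around 0.
#'
#' Sites where a pool has zero depth get a missing index (and delta),
#' and are ignored by track fitting.
#'
#' @param variants Variant table as in a `bsa_dataset` (parental
#'   genotype columns are required to orient the index).
#' @return The input with `index_sterile`, `index_fertile` and `delta`
#'   columns appended.
#' @export
compute_snp_index <- function(variants) {
  variants <- tibble::as_tibble(variants)
  sa <- .sterile_allele(variants)
  idx <- function(ref_d, alt_d) {
    total <- ref_d + alt_d
    carrier <- ifelse(sa == 1L, alt_d, ref_d)
    ifelse(total > 0, carrier / total, NA_real_)
  }
  variants$index_sterile <- idx(variants$ref_sterile, variants$alt_sterile)
  variants$index_fertile <- idx(variants$ref_fertile, variants$alt_fertile)
  variants$delta <- variants$index_sterile - variants$index_fertile
  variants
}

#' Sliding-window fit of a per-site statistic
#'
#' Fits one chromosome's raw per-site values with a physical
#' sliding-window mean: windows of width `window_bp` advanced by
#' `step_bp`, each summarising the sites whose positions fall in the
#' half-open interval `[center - window_bp/2, center + window_bp/2)`.
#' Windows holding fewer than `min_sites` sites are reported missing.
#' Window centers run from the first to the last covered site.
#'
#' @param pos Sorted 1-based site positions of one chromosome.
#' @param values Raw statistic per site (missing values are dropped).
#' @param chrom Chromosome name carried into the output.
#' @param window_bp Window width in bp (default 1e6).
#' @param step_bp Step between window centers in bp (default 1e4).
#' @param min_sites Minimum sites per window (default 3).
#' @return A `scan_track`: list with `windows` (tibble `chrom`,
#'   `center`, `fitted`, `n_sites`), `sites` (tibble `chrom`, `pos`,
#'   `value`) and the window parameters.
#' @export
fit_track <- function(pos, values, chrom = "chr", window_bp = 1e6,
                      step_bp = 1e4, min_sites = 3) {
  if (window_bp <= 0 || step_bp <= 0) {
    stop("`window_bp` and `step_bp` must be positive", call. = FALSE)
  }
  if (is.unsorted(pos)) stop("`pos` must be sorted", call. = FALSE)
  ok <- !is.na(values)
  pos_ok <- pos[ok]
  val_ok <- values[ok]
  if (length(pos_ok) == 0) {
    centers <- numeric(0)
  } else {
    centers <- seq(pos_ok[1], pos_ok[length(pos_ok)], by = step_bp)
  }
  half <- window_bp / 2
  lo <- findInterval(centers - half, pos_ok, left.open = TRUE) + 1
  hi <- findInterval(centers + half - 1e-9, pos_ok)
  n_sites <- hi - lo + 1
  csum <- c(0, cumsum(val_ok))
  fitted <- ifelse(n_sites >= min_sites,
                   (csum[hi + 1] - csum[lo]) / n_sites, NA_real_)
  structure(
    list(
      windows = tibble::tibble(chrom = chrom, center = centers,
                               fitted = fitted,
                               n_sites = pmax(n_sites, 0L)),
      sites = tibble::tibble(chrom = chrom, pos = pos, value = values),
      window_bp = window_bp, step_bp = step_bp, min_sites = min_sites
    ),
    class = "scan_track"
  )
}

#' Fit scan tracks for every chromosome
#'
#' Applies [fit_track()] chromosome by chromosome to a per-site
#' statistic column and combines the results.
#'
#' @param df Per-site table with `chrom`, `pos` and the statistic.
#' @param value_col Name of the statistic column (e.g. `"delta"`).
#' @inheritParams fit_track
#' @return A `scan_track` whose `windows` and `sites` span all
#'   chromosomes (chromosomes in order of first appearance).
#' @export
fit_scan_track <- function(df, value_col = "delta", window_bp = 1e6,
                           step_bp = 1e4, min_sites = 3) {
  stopifnot(value_col %in% names(df))
  chroms <- unique(df$chrom)
  parts <- lapply(chroms, function(cn) {
    d <- df[df$chrom == cn, ]
    d <- d[order(d$pos), ]
    fit_track(d$pos, d[[value_col]], chrom = cn, window_bp = window_bp,
              step_bp = step_bp, min_sites = min_sites)
  })
  structure(
    list(
      windows = dplyr::bind_rows(lapply(parts, `[[`, "windows")),
      sites = dplyr::bind_rows(lapply(parts, `[[`, "sites")),
      window_bp = window_bp, step_bp = step_bp, min_sites = min_sites
    ),
    class = "scan_track"
  )
}

#' Genome-wide percentile threshold
#'
#' The q-th percentile of all non-missing fitted values, computed with
#' the standard linear-interpolation convention
#' (`stats::quantile(type = 7)`).
#'
#' @param fitted Fitted values (a `scan_track` or a numeric vector).
#' @param q Percentile in \[0, 100\]; default 99.
#' @return The threshold value.
#' @export
percentile_threshold <- function(fitted, q = 99) {
  if (inherits(fitted, "scan_track")) fitted <- fitted$windows$fitted
  fitted <- fitted[!is.na(fitted)]
  if (length(fitted) == 0) {
    stop("no non-missing fitted values", call. = FALSE)
  }
  unname(stats::quantile(fitted, q / 100, type = 7))
}

#' Extract candidate regions from a fitted track
#'
#' Finds the maximal runs of consecutive windows whose fitted value
#' strictly exceeds the threshold (missing windows break runs) and
#' reports each run as a candidate region. Region boundaries are the
#' outermost window edges clipped to the positions of the sites they
#' actually cover; the peak is the highest fitted value in the run.
#'
#' @param track A `scan_track`.
#' @param threshold Finite threshold; windows with `fitted > threshold`
#'   are above it (ties fall below).
#' @return Tibble with one row per region: `chrom`, `start`, `end`
#'   (1-based inclusive), `peak`, `peak_pos`, `n_windows`, `n_sites`,
#'   `start_center`, `end_center`.
#' @export
extract_regions <- function(track, threshold) {
  stopifnot(inherits(track, "scan_track"), is.finite(threshold))
  w <- track$windows
  half <- track$window_bp / 2
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    peak = numeric(), peak_pos = numeric(), n_windows = integer(),
    n_sites = integer(), start_center = numeric(), end_center = numeric()
  )
  if (nrow(w) == 0) return(empty)
  out <- list()
  for (cn in unique(w$chrom)) {
    wc <- w[w$chrom == cn, ]
    above <- !is.na(wc$fitted) & wc$fitted > threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    sites <- track$sites[track$sites$chrom == cn & !is.na(track$sites$value), ]
    for (k in which(runs$values)) {
      i <- starts[k]; j <- ends[k]
      span_lo <- wc$center[i] - half
      span_hi <- wc$center[j] + half
      in_span <- sites$pos >= span_lo & sites$pos < span_hi
      covered <- sites$pos[in_span]
      peak_idx <- i - 1 + which.max(wc$fitted[i:j])
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = cn,
        start = if (length(covered)) min(covered) else span_lo,
        end = if (length(covered)) max(covered) else span_hi,
        peak = wc$fitted[peak_idx],
        peak_pos = wc$center[peak_idx],
        n_windows = j - i + 1L,
        n_sites = sum(in_span),
        start_center = wc$center[i],
        end_center = wc$center[j]
      )
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Fitted value at (or nearest) a genomic position
#'
#' Convenience accessor: the fitted value of the window whose center
#' is closest to a position of interest (e.g. the simulated causal
#' locus).
#'
#' @param track A `scan_track`.
#' @param chrom,pos The position of interest.
#' @return The fitted value (possibly `NA`).
#' @export
fitted_at <- function(track, chrom, pos) {
  w <- track$windows[track$windows$chrom == chrom, ]
  if (nrow(w) == 0) return(NA_real_)
  w$fitted[which.min(abs(w$center - pos))]
}
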