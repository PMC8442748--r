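test_that("SNP index is the sterile-parent allele read fraction", {
  v <- make_variants(ref_sterile = c(0, 0), alt_sterile = c(34, 34),
                     ref_fertile = c(20, 0), alt_fertile = c(10, 0))
  idx <- compute_snp_index(v)
  expect_equal(idx$index_sterile, c(1, 1))
  expect_equal(idx$index_fertile[1], 1 / 3)
  expect_true(is.na(idx$index_fertile[2]))   # zero depth -> missing
  expect_equal(idx$delta[1], 1 - 1 / 3)
  expect_true(is.na(idx$delta[2]))

  # orientation flips with the parental genotypes
  v_flip <- make_variants(ref_sterile = 30, alt_sterile = 0,
                          ref_fertile = 10, alt_fertile = 20,
                          gt_parent_sterile = "0/0",
                          gt_parent_fertile = "1/1")
  idx_flip <- compute_snp_index(v_flip)
  expect_equal(idx_flip$index_sterile, 1)
  expect_equal(idx_flip$index_fertile, 1 / 3)
})

test_that("identical or non-homozygous parents are orientation errors", {
  same <- make_variants(ref_sterile = 1, alt_sterile = 1,
                        ref_fertile = 1, alt_fertile = 1,
                        gt_parent_sterile = "1/1",
                        gt_parent_fertile = "1/1")
  expect_error(compute_snp_index(same), "same genotype")
  het <- make_variants(ref_sterile = 1, alt_sterile = 1,
                       ref_fertile = 1, alt_fertile = 1,
                       gt_parent_sterile = "0/1")
  expect_error(compute_snp_index(het), "not homozygous")
})

test_that("index and delta stay in bounds and delta is antisymmetric", {
  set.seed(33)
  n <- 500
  v <- make_variants(pos = seq_len(n) * 10,
                     ref_sterile = rpois(n, 15), alt_sterile = rpois(n, 15),
                     ref_fertile = rpois(n, 15), alt_fertile = rpois(n, 15))
  idx <- compute_snp_index(v)
  ok <- !is.na(idx$delta)
  expect_true(all(idx$index_sterile[ok] >= 0 & idx$index_sterile[ok] <= 1))
  expect_true(all(idx$delta[ok] >= -1 & idx$delta[ok] <= 1))
  expect_equal(idx$delta, idx$index_sterile - idx$index_fertile)
  # swapping the two pools negates delta everywhere
  v_sw <- v
  v_sw[c("ref_sterile", "alt_sterile", "ref_fertile", "alt_fertile")] <-
    v[c("ref_fertile", "alt_fertile", "ref_sterile", "alt_sterile")]
  idx_sw <- compute_snp_index(v_sw)
  expect_equal(idx_sw$delta, -idx$delta)
})

test_that("window fitting reproduces means, constants and edge rules", {
  # 5 sites in a single window: fitted value is the arithmetic mean
  t1 <- fit_track(c(10, 20, 30, 40, 50), c(0.1, 0.2, 0.3, 0.4, 0.5),
                  window_bp = 200, step_bp = 100, min_sites = 1)
  expect_equal(t1$windows$fitted[1], 0.3)
  # constant raw values give constant fitted values
  t2 <- fit_track(seq(100, 2000, by = 100), rep(0.7, 20),
                  window_bp = 500, step_bp = 100, min_sites = 1)
  expect_true(all(abs(t2$windows$fitted - 0.7) < 1e-12, na.rm = TRUE))
  # single covered site: fitted equals the raw value
  t3 <- fit_track(500, 0.42, window_bp = 100, step_bp = 50, min_sites = 1)
  expect_equal(t3$windows$fitted, 0.42)
  # windows below min_sites are missing
  t4 <- fit_track(c(10, 5000), c(0.1, 0.9), window_bp = 100,
                  step_bp = 100, min_sites = 2)
  expect_true(all(is.na(t4$windows$fitted)))
  expect_error(fit_track(1:3, 1:3, window_bp = 0), "positive")
  expect_error(fit_track(c(3, 1), 1:2), "sorted")
})

test_that("fitted values stay within the hull of their window's raw values", {
  set.seed(12)
  pos <- sort(sample(1:10000, 300))
  val <- runif(300)
  tr <- fit_track(pos, val, window_bp = 800, step_bp = 200, min_sites = 1)
  w <- tr$windows
  for (i in seq_len(nrow(w))) {
    in_w <- pos >= w$center[i] - 400 & pos < w$center[i] + 400
    if (!any(in_w)) next
    expect_gte(w$fitted[i], min(val[in_w]) - 1e-12)
    expect_lte(w$fitted[i], max(val[in_w]) + 1e-12)
  }
})

test_that("percentile threshold uses linear interpolation and is monotone in q", {
  expect_equal(percentile_threshold(seq(0, 1, by = 0.1), q = 50), 0.5)
  expect_equal(percentile_threshold(rep(0.3, 10), q = 99), 0.3)
  vals <- runif(50)
  qs <- c(10, 50, 90, 99)
  th <- vapply(qs, function(q) percentile_threshold(vals, q), 0)
  expect_false(is.unsorted(th))
  expect_error(percentile_threshold(c(NA_real_, NA_real_)), "non-missing")
})

test_that("region extraction finds maximal above-threshold runs", {
  tr <- make_track(c(0.1, 0.7, 0.8, 0.2))
  regions <- extract_regions(tr, 0.56)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$peak, 0.8)
  expect_equal(regions$start_center, tr$windows$center[2])
  expect_equal(regions$end_center, tr$windows$center[3])
  expect_equal(regions$n_windows, 2L)
  # nothing above threshold -> empty
  expect_equal(nrow(extract_regions(tr, 0.9)), 0L)
  # ties at the threshold are excluded (strict inequality)
  expect_equal(nrow(extract_regions(make_track(c(0.5, 0.5)), 0.5)), 0L)
  # missing windows break runs
  tr_na <- make_track(c(0.9, NA, 0.9))
  expect_equal(nrow(extract_regions(tr_na, 0.5)), 2L)
})

test_that("region extraction matches the exhaustive interval oracle", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(1:50, 1)
    fitted <- runif(n)
    fitted[runif(n) < 0.15] <- NA
    thr <- runif(1)
    tr <- make_track(fitted)
    got <- extract_regions(tr, thr)
    want <- oracle_regions(fitted, thr)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      want_idx <- do.call(rbind, want)
      expect_equal(got$start_center, tr$windows$center[want_idx[, "start"]])
      expect_equal(got$end_center, tr$windows$center[want_idx[, "end"]])
      for (k in seq_along(want)) {
        expect_equal(got$peak[k],
                     max(fitted[want_idx[k, "start"]:want_idx[k, "end"]]))
      }
    }
  }
})

test_that("region boundaries clip to covered site positions", {
  tr <- make_track(c(0.9, 0.9, 0.1), sites_per_window = 3)
  regions <- extract_regions(tr, 0.5)
  span_lo <- tr$windows$center[1] - tr$window_bp / 2
  span_hi <- tr$windows$center[2] + tr$window_bp / 2
  in_span <- tr$sites$pos >= span_lo & tr$sites$pos < span_hi
  expect_equal(regions$start, min(tr$sites$pos[in_span]))
  expect_equal(regions$end, max(tr$sites$pos[in_span]))
})

test_that("fitted_at returns the nearest window's value", {
  tr <- make_track(c(0.1, 0.2, 0.3))
  expect_equal(fitted_at(tr, "chr1", tr$windows$center[2] + 1), 0.2)
  expect_true(is.na(fitted_at(tr, "chrX", 5)))
})
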