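test_that("layout validation rejects inconsistent inputs", {
  chroms <- tibble::tibble(name = "chr1", length = 1000L)
  expect_error(genome_layout(chroms, list(chr1 = c(10, 10, 30)),
                             list("chr1", 10)), "strictly increasing")
  expect_error(genome_layout(chroms, list(chr1 = c(10, 2000)),
                             list("chr1", 10)), "strictly increasing")
  expect_error(genome_layout(chroms, list(chr1 = c(10, 20)),
                             list("chr1", 15)), "causal")
  expect_error(genome_layout(chroms[0, ], list(), list("chr1", 10)),
               "chromosome")
  expect_error(genome_layout(chroms, list(chr1 = integer(0)),
                             list("chr1", 1)), "SNP")
  l <- default_layout()
  expect_equal(nrow(l$chromosomes), 11L)
  expect_equal(l$causal$chrom, "chr6")
  expect_true(l$causal$pos %in% l$snp_positions$chr6)
})

test_that("config validation enforces parameter ranges", {
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(base_error = 0.5), "base_error")
  expect_error(sim_config(recomb_rate = -1), "recomb_rate")
  cfg <- sim_config()
  expect_equal(cfg$bulk_size, 30L)
  expect_equal(cfg$mean_depth, 34)
})

test_that("YAML config round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_f2: 150", "bulk_size: 20", "mean_depth: 50",
               "seed: 9"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_f2, 150L)
  expect_equal(cfg$mean_depth, 50)
  expect_equal(cfg$base_error, 0.01)  # default preserved
  writeLines("bulk_depth: 3", path)
  expect_error(read_sim_config(path), "unknown config key")
})

test_that("without recombination every chromosome is an intact parental pair", {
  layout <- tiny_layout()
  pop <- simulate_f2_population(
    layout, sim_config(n_f2 = 40, recomb_rate = 0, seed = 3))
  for (cn in layout$chromosomes$name) {
    cols <- which(pop$sites$chrom == cn)
    per_chrom <- pop$genotypes[, cols, drop = FALSE]
    expect_true(all(apply(per_chrom, 1, function(g) length(unique(g)) == 1)))
  }
  expect_true(all(pop$genotypes %in% 0:2))
})

test_that("single-locus genotypes segregate 1:2:1 and phenotypes 3:1", {
  layout <- tiny_layout()
  n <- 4000
  pop <- simulate_f2_population(layout, sim_config(n_f2 = n, seed = 11))
  causal_col <- which(pop$sites$chrom == layout$causal$chrom &
                        pop$sites$pos == layout$causal$pos)
  g <- pop$genotypes[, causal_col]
  counts <- table(factor(g, levels = 0:2))
  # binomial oracle: each class within 4 sd of its 1:2:1 expectation
  for (k in 0:2) {
    p <- c(0.25, 0.5, 0.25)[k + 1]
    expect_lt(abs(counts[[k + 1]] - n * p), 4 * sqrt(n * p * (1 - p)))
  }
  sterile_frac <- mean(pop$phenotype == "sterile")
  expect_lt(abs(sterile_frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # phenotype rule is exactly genotype == 2 at the causal locus
  expect_identical(pop$phenotype == "sterile", unname(g == 2L))
})

test_that("bulks are disjoint class subsets and errors name the deficient class", {
  layout <- tiny_layout()
  pop <- simulate_f2_population(layout, sim_config(n_f2 = 1000, seed = 5))
  bulks <- form_bulks(pop, bulk_size = 30, seed = 1)
  expect_length(bulks$sterile, 30)
  expect_length(bulks$fertile, 30)
  expect_length(intersect(bulks$sterile, bulks$fertile), 0)
  expect_true(all(pop$phenotype[bulks$sterile] == "sterile"))
  expect_true(all(pop$phenotype[bulks$fertile] == "fertile"))
  # the recessive bulk is homozygous at the causal locus
  expect_equal(
    unname(bulk_allele_freq(pop, bulks$sterile)[
      which(pop$sites$chrom == layout$causal$chrom &
              pop$sites$pos == layout$causal$pos)]), 1)
  small <- simulate_f2_population(layout, sim_config(n_f2 = 40, seed = 5))
  n_sterile <- sum(small$phenotype == "sterile")
  expect_error(form_bulks(small, bulk_size = n_sterile + 1),
               "sterile")
})

test_that("pool depth model follows Poisson totals and binomial allele split", {
  set.seed(99)
  # fixed bulk, no error: every read carries the sterile-parent allele
  d <- simulate_pool_depths(rep(1, 500), mean_depth = 34, base_error = 0)
  expect_true(all(d$depth_sterile_allele == d$depth_total))
  expect_true(all(d$depth_other == 0))
  # mean depth recovers the configured value over many sites
  d2 <- simulate_pool_depths(rep(0.5, 2e4), mean_depth = 34,
                             base_error = 0)
  expect_lt(abs(mean(d2$depth_total) - 34), 4 * sqrt(34 / 2e4))
  # binomial oracle on the aggregated allele fraction at freq 1/3
  d3 <- simulate_pool_depths(rep(1 / 3, 1000), mean_depth = 30,
                             base_error = 0)
  frac <- sum(d3$depth_sterile_allele) / sum(d3$depth_total)
  expect_lt(abs(frac - 1 / 3), 0.01)
  expect_true(all(d3$depth_other + d3$depth_sterile_allele ==
                    d3$depth_total))
})

test_that("same seed reproduces the dataset byte for byte, different seeds differ", {
  layout <- tiny_layout()
  cfg <- sim_config(n_f2 = 120, bulk_size = 20, seed = 21)
  ds1 <- simulate_bsa_dataset(layout, cfg)
  ds2 <- simulate_bsa_dataset(layout, cfg)
  expect_identical(ds1$variants, ds2$variants)
  expect_identical(ds1$truth, ds2$truth)
  ds3 <- simulate_bsa_dataset(layout, sim_config(n_f2 = 120, bulk_size = 20,
                                                 seed = 22))
  expect_false(identical(ds1$variants$alt_sterile,
                         ds3$variants$alt_sterile))
})

test_that("class allele frequencies approach the Mendelian limits in large populations", {
  layout <- tiny_layout()
  pop <- simulate_f2_population(layout, sim_config(n_f2 = 4000, seed = 8))
  causal_col <- which(pop$sites$chrom == layout$causal$chrom &
                        pop$sites$pos == layout$causal$pos)
  sterile <- which(pop$phenotype == "sterile")
  fertile <- which(pop$phenotype == "fertile")
  f_s <- bulk_allele_freq(pop, sterile)[causal_col]
  f_f <- bulk_allele_freq(pop, fertile)[causal_col]
  expect_equal(unname(f_s), 1)
  expect_lt(abs(f_f - 1 / 3), 3 * sqrt((1 / 18) / length(fertile)))
})
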