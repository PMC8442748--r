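# Synthetic F2 bulk-sequencing simulator: two inbred parents, a selfed
# F1, phenotype-selected bulks, and Poisson/binomial pooled read depths.

#' Define a genome layout for simulation
#'
#' @param chromosomes Tibble/data frame with columns `name` and
#'   `length` (bp), in karyotype order.
#' @param snp_positions Named list (one element per chromosome) of
#'   strictly increasing 1-based SNP positions.
#' @param causal List or vector `(chrom, pos)`: the causal locus, which
#'   must be one of the SNP positions.
#' @return An object of class `genome_layout`.
#' @seealso [default_layout()] for the desk-scale default.
#' @export
genome_layout <- function(chromosomes, snp_positions, causal) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0) {
    stop("layout needs at least one chromosome", call. = FALSE)
  }
  if (!setequal(names(snp_positions), chromosomes$name)) {
    stop("`snp_positions` must be named by chromosome", call. = FALSE)
  }
  if (sum(lengths(snp_positions)) == 0) {
    stop("layout needs at least one SNP", call. = FALSE)
  }
  for (cn in chromosomes$name) {
    p <- snp_positions[[cn]]
    len <- chromosomes$length[chromosomes$name == cn]
    if (length(p) && (is.unsorted(p, strictly = TRUE) ||
                      p[1] < 1 || p[length(p)] > len)) {
      stop("SNP positions on ", cn,
           " must be strictly increasing within [1, ", len, "]",
           call. = FALSE)
    }
  }
  causal <- list(chrom = as.character(causal[[1]]),
                 pos = as.integer(causal[[2]]))
  if (!causal$chrom %in% chromosomes$name ||
      !causal$pos %in% snp_positions[[causal$chrom]]) {
    stop("causal locus must be one of the layout's SNP positions",
         call. = FALSE)
  }
  structure(
    list(chromosomes = chromosomes, snp_positions = snp_positions,
         causal = causal),
    class = "genome_layout"
  )
}

#' Desk-scale default genome layout
#'
#' Eleven chromosomes (mirroring a 2n = 22 cucurbit karyotype) of 1 Mb
#' each, carrying ~2000 evenly spaced SNPs in total, with the causal
#' locus at the central SNP of chromosome 6. Each scaled chromosome
#' stands in for a window-scale slice of a real chromosome.
#'
#' @param n_chrom Number of chromosomes (default 11).
#' @param chrom_length Chromosome length in bp (default 1e6).
#' @param n_snps Total SNP count across the genome (default 2000).
#' @param causal_chrom Chromosome carrying the causal locus
#'   (default `"chr6"`).
#' @return A [genome_layout()].
#' @export
default_layout <- function(n_chrom = 11, chrom_length = 1e6,
                           n_snps = 2000, causal_chrom = "chr6") {
  names <- paste0("chr", seq_len(n_chrom))
  per_chrom <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
  pos <- lapply(seq_len(n_chrom), function(i) {
    k <- per_chrom[i]
    unique(as.integer(round(seq(chrom_length / (k + 1), by =
                                  chrom_length / (k + 1), length.out = k))))
  })
  names(pos) <- names
  cp <- pos[[causal_chrom]]
  genome_layout(
    tibble::tibble(name = names, length = as.integer(chrom_length)),
    pos,
    causal = list(causal_chrom, cp[ceiling(length(cp) / 2)])
  )
}

#' Simulation parameters
#'
#' @param n_f2 Number of F2 plants to simulate (default 200).
#' @param bulk_size Plants per phenotype bulk (default 30).
#' @param mean_depth Expected reads per site per pool (default 34).
#' @param base_error Per-read allele-flip probability in \[0, 0.5)
#'   (default 0.01).
#' @param recomb_rate Expected crossovers per chromosome per meiosis
#'   (default 0.05, i.e. 5 cM over a 1 Mb scaled chromosome,
#'   preserving a typical plant per-base recombination density).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_f2 = 200, bulk_size = 30, mean_depth = 34,
                       base_error = 0.01, recomb_rate = 0.05, seed = 1) {
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  if (base_error < 0 || base_error >= 0.5) {
    stop("`base_error` must be in [0, 0.5)", call. = FALSE)
  }
  if (recomb_rate < 0) stop("`recomb_rate` must be >= 0", call. = FALSE)
  if (n_f2 < 1 || bulk_size < 1) {
    stop("`n_f2` and `bulk_size` must be positive", call. = FALSE)
  }
  structure(
    list(n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
         mean_depth = mean_depth, base_error = base_error,
         recomb_rate = recomb_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read simulation parameters from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

# One gamete for one chromosome: a recombinant mosaic of the two
# parental haplotypes. Crossover count ~ Poisson(recomb_rate),
# positions uniform (Haldane, no interference). Returns 0/1 per SNP:
# 1 = sterile-parent allele.
.sim_gamete <- function(snp_pos, chrom_length, recomb_rate) {
  start <- stats::rbinom(1, 1, 0.5)
  k <- stats::rpois(1, recomb_rate)
  if (k == 0 || length(snp_pos) == 0) {
    return(rep(start, length(snp_pos)))
  }
  breaks <- sort(stats::runif(k, 0, chrom_length))
  # parental phase switches at each crossover
  (start + findInterval(snp_pos, breaks)) %% 2L
}

#' Simulate an F2 population
#'
#' Simulates `n_f2` plants from a cross between two fully homozygous
#' inbred parents that differ at every SNP of the layout. Each plant is
#' the fusion of two independent gametes; each gamete is a recombinant
#' mosaic of the parental haplotypes (Poisson crossover count, uniform
#' positions). Genotypes count copies of the sterile-parent allele
#' (0, 1 or 2). The phenotype is sterile if and only if the plant is
#' homozygous for the sterile-parent allele at the causal locus
#' (fully penetrant recessive).
#'
#' @param layout A [genome_layout()].
#' @param config A [sim_config()]. `config$seed` seeds the RNG.
#' @return An object of class `f2_population`: list with `genotypes`
#'   (matrix, plants x SNPs), `phenotype` (`"sterile"`/`"fertile"`),
#'   `sites` (tibble `chrom`, `pos` aligned to genotype columns) and
#'   `layout`.
#' @export
simulate_f2_population <- function(layout, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- layout$chromosomes
  sites <- tibble::tibble(
    chrom = rep(chroms$name, lengths(layout$snp_positions[chroms$name])),
    pos = unlist(layout$snp_positions[chroms$name], use.names = FALSE)
  )
  n_snp <- nrow(sites)
  geno <- matrix(0L, nrow = config$n_f2, ncol = n_snp)
  col_of <- split(seq_len(n_snp), factor(sites$chrom, levels = chroms$name))
  for (ind in seq_len(config$n_f2)) {
    for (ci in seq_len(nrow(chroms))) {
      cols <- col_of[[chroms$name[ci]]]
      p <- layout$snp_positions[[chroms$name[ci]]]
      g <- .sim_gamete(p, chroms$length[ci], config$recomb_rate) +
        .sim_gamete(p, chroms$length[ci], config$recomb_rate)
      geno[ind, cols] <- as.integer(g)
    }
  }
  causal_col <- which(sites$chrom == layout$causal$chrom &
                        sites$pos == layout$causal$pos)
  phenotype <- ifelse(geno[, causal_col] == 2L, "sterile", "fertile")
  structure(
    list(genotypes = geno, phenotype = phenotype, sites = sites,
         layout = layout),
    class = "f2_population"
  )
}

#' Draw the two phenotype bulks from an F2 population
#'
#' Samples `bulk_size` plants of each phenotype class, without
#' replacement, into a sterile and a fertile bulk (disjoint by
#' construction since the classes are).
#'
#' @param population An `f2_population`.
#' @param bulk_size Plants per bulk.
#' @param seed Optional seed for the bulk draw; `NULL` leaves the RNG
#'   state untouched.
#' @return List with `sterile` and `fertile`: integer vectors of plant
#'   indices.
#' @export
form_bulks <- function(population, bulk_size = 30, seed = NULL) {
  stopifnot(inherits(population, "f2_population"))
  if (!is.null(seed)) set.seed(seed)
  idx <- list(sterile = which(population$phenotype == "sterile"),
              fertile = which(population$phenotype == "fertile"))
  for (cls in names(idx)) {
    if (length(idx[[cls]]) < bulk_size) {
      stop("cannot form the ", cls, " bulk: only ", length(idx[[cls]]),
           " ", cls, " plants for a bulk of ", bulk_size, call. = FALSE)
    }
  }
  list(sterile = sort(sample(idx$sterile, bulk_size)),
       fertile = sort(sample(idx$fertile, bulk_size)))
}

#' True sterile-parent allele frequencies of a bulk
#'
#' @param population An `f2_population`.
#' @param members Plant indices (one bulk from [form_bulks()]).
#' @return Numeric vector of per-site allele frequencies in \[0, 1\].
#' @export
bulk_allele_freq <- function(population, members) {
  colMeans(population$genotypes[members, , drop = FALSE]) / 2
}

#' Simulate pooled sequencing depths for one bulk
#'
#' Per site, the total read depth is Poisson(`mean_depth`); each read
#' carries the sterile-parent allele with probability equal to the
#' bulk's true allele frequency and is then flipped with probability
#' `base_error` (so the observed per-read probability is
#' `f (1 - e) + (1 - f) e`).
#'
#' @param true_freq Per-site true sterile-parent allele frequencies.
#' @param mean_depth Expected reads per site.
#' @param base_error Per-read allele-flip probability.
#' @param seed Optional seed; `NULL` leaves the RNG state untouched.
#' @return Tibble with `depth_other` (reads carrying the fertile-parent
#'   allele), `depth_sterile_allele` and `depth_total`.
#' @export
simulate_pool_depths <- function(true_freq, mean_depth = 34,
                                 base_error = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_freq)
  total <- stats::rpois(n, mean_depth)
  p_obs <- true_freq * (1 - base_error) + (1 - true_freq) * base_error
  alt <- stats::rbinom(n, total, p_obs)
  tibble::tibble(depth_other = total - alt,
                 depth_sterile_allele = alt,
                 depth_total = total)
}

#' Simulate a full BSA-seq dataset
#'
#' Runs the whole generative model: F2 population, phenotype bulks,
#' and pooled read depths for both bulks, and packages the result as a
#' variant table in the four-sample layout the scan consumes
#' (two parents, two bulks). REF/ALT orientation is randomised per
#' site (the sterile parent carries ALT at roughly half the sites), so
#' downstream code must orient alleles from the parental genotypes.
#'
#' @param layout A [genome_layout()]; default [default_layout()].
#' @param config A [sim_config()].
#' @return A list of class `bsa_dataset` with elements
#'   `variants` (tibble: `chrom`, `pos`, `ref`, `alt`, `n_alt`,
#'   `gt_parent_sterile`, `gt_parent_fertile`, `ref_sterile`,
#'   `alt_sterile`, `ref_fertile`, `alt_fertile`),
#'   `truth` (tibble: `chrom`, `pos`, `true_freq_sterile`,
#'   `true_freq_fertile`, `is_causal`), `layout` and `config`.
#' @export
simulate_bsa_dataset <- function(layout = default_layout(),
                                 config = sim_config()) {
  pop <- simulate_f2_population(layout, config)
  bulks <- form_bulks(pop, config$bulk_size)
  f_s <- bulk_allele_freq(pop, bulks$sterile)
  f_f <- bulk_allele_freq(pop, bulks$fertile)
  d_s <- simulate_pool_depths(f_s, config$mean_depth, config$base_error)
  d_f <- simulate_pool_depths(f_f, config$mean_depth, config$base_error)
  n <- nrow(pop$sites)
  # random REF/ALT orientation; sterile parent carries ALT where flip is FALSE
  flip <- stats::runif(n) < 0.5
  base_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                       ncol = 2, byrow = TRUE)
  pair <- base_pairs[sample.int(4, n, replace = TRUE), , drop = FALSE]
  variants <- tibble::tibble(
    chrom = pop$sites$chrom,
    pos = pop$sites$pos,
    ref = pair[, 1],
    alt = pair[, 2],
    n_alt = 1L,
    gt_parent_sterile = ifelse(flip, "0/0", "1/1"),
    gt_parent_fertile = ifelse(flip, "1/1", "0/0"),
    ref_sterile = ifelse(flip, d_s$depth_sterile_allele, d_s$depth_other),
    alt_sterile = ifelse(flip, d_s$depth_other, d_s$depth_sterile_allele),
    ref_fertile = ifelse(flip, d_f$depth_sterile_allele, d_f$depth_other),
    alt_fertile = ifelse(flip, d_f$depth_other, d_f$depth_sterile_allele)
  )
  truth <- tibble::tibble(
    chrom = pop$sites$chrom,
    pos = pop$sites$pos,
    true_freq_sterile = f_s,
    true_freq_fertile = f_f,
    is_causal = pop$sites$chrom == layout$causal$chrom &
      pop$sites$pos == layout$causal$pos
  )
  structure(
    list(variants = variants, truth = truth, layout = layout,
         config = config),
    class = "bsa_dataset"
  )
}
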