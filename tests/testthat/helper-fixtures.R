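# Shared fixture builders: everything is generated in code.

# small genome for fast simulations: 2 chromosomes, 40 SNPs
tiny_layout <- function(n_chrom = 2, chrom_length = 1e5, n_snps = 40) {
  default_layout(n_chrom = n_chrom, chrom_length = chrom_length,
                 n_snps = n_snps, causal_chrom = paste0("chr", n_chrom))
}

# hand-built variant rows in the bsa_dataset layout
make_variants <- function(pos = seq_along(ref_sterile) * 100,
                          chrom = "chr1",
                          ref_sterile, alt_sterile,
                          ref_fertile, alt_fertile,
                          n_alt = 1L,
                          gt_parent_sterile = "1/1",
                          gt_parent_fertile = "0/0") {
  n <- length(ref_sterile)
  tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = as.integer(pos),
    ref = rep_len("A", n),
    alt = rep_len("G", n),
    n_alt = as.integer(rep_len(n_alt, n)),
    gt_parent_sterile = rep_len(gt_parent_sterile, n),
    gt_parent_fertile = rep_len(gt_parent_fertile, n),
    ref_sterile = as.integer(ref_sterile),
    alt_sterile = as.integer(alt_sterile),
    ref_fertile = as.integer(ref_fertile),
    alt_fertile = as.integer(alt_fertile)
  )
}

# build a scan_track directly from window values (for region tests)
make_track <- function(fitted, chrom = "chr1", step_bp = 10,
                       window_bp = 10, sites_per_window = 2) {
  centers <- seq_len(length(fitted)) * step_bp
  pos <- sort(unlist(lapply(centers, function(cc) {
    cc + seq(-window_bp / 2, window_bp / 2 - 1e-6,
             length.out = sites_per_window + 2)[2:(sites_per_window + 1)]
  })))
  structure(
    list(
      windows = tibble::tibble(chrom = chrom, center = centers,
                               fitted = fitted,
                               n_sites = sites_per_window),
      sites = tibble::tibble(chrom = chrom, pos = pos, value = 0),
      window_bp = window_bp, step_bp = step_bp, min_sites = 1
    ),
    class = "scan_track"
  )
}

# exhaustive oracle: maximal runs of above-threshold windows
oracle_regions <- function(fitted, threshold) {
  above <- !is.na(fitted) & fitted > threshold
  n <- length(fitted)
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(above[i:j]) &&
          (i == 1 || !above[i - 1]) &&
          (j == n || !above[j + 1])) {
        runs[[length(runs) + 1]] <- c(start = i, end = j)
      }
    }
  }
  runs
}

# all 576 single-base codon substitutions
all_codon_changes <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0,
                  collapse = "")
  out <- list()
  for (cod in codons) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        out[[length(out) + 1]] <- c(ref = cod, alt = alt)
      }
    }
  }
  do.call(rbind, out)
}
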