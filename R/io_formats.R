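# Readers and writers for the formats the pipeline touches: VCF 4.x
# (variant interchange), GFF3 (gene models), BED and TSV (scan and
# region outputs), and a truth sidecar for simulations.
#
# Coordinate conventions: 1-based inclusive internally (the VCF
# convention); BED output is 0-based half-open.

.bsa_roles <- c("parent_sterile", "parent_fertile",
                "bulk_sterile", "bulk_fertile")

#' Write a simulated dataset as VCF plus truth sidecar
#'
#' Emits a VCF 4.2 file with four samples
#' (`parent_sterile`, `parent_fertile`, `bulk_sterile`,
#' `bulk_fertile`), `GT:AD` per sample, and contig header lines from
#' the genome layout; and a plain-TSV truth sidecar recording the
#' causal locus and per-site true allele frequencies. The sidecar is
#' never consumed by the pipeline itself — it exists so tests can
#' score recovery without leaking truth into the scan.
#'
#' @param dataset A `bsa_dataset` from [simulate_bsa_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.vcf` and
#'   `<prefix>.truth.tsv`.
#' @return Invisibly, the two paths written.
#' @export
write_simulation <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "bsa_dataset"))
  vcf_path <- paste0(prefix, ".vcf")
  truth_path <- paste0(prefix, ".truth.tsv")
  write_bsa_vcf(dataset$variants, vcf_path, layout = dataset$layout)
  utils::write.table(dataset$truth, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, truth = truth_path))
}

#' Write a variant table as a four-sample VCF
#'
#' @param variants Variant table (columns as in a `bsa_dataset`).
#' @param path Output path.
#' @param layout Optional [genome_layout()] used to emit `##contig`
#'   header lines.
#' @return Invisibly, `path`.
#' @export
write_bsa_vcf <- function(variants, path, layout = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsascan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,Description=',
           '"Allelic depths for the ref and alt alleles">')
  ), con)
  if (!is.null(layout)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       layout$chromosomes$name,
                       as.integer(layout$chromosomes$length)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", .bsa_roles),
                   collapse = "\t"), con)
  if (nrow(variants)) {
    gt_ad <- function(gt, ref_d, alt_d) {
      sprintf("%s:%d,%d", gt, as.integer(ref_d), as.integer(alt_d))
    }
    # parents are modelled as sequenced to fixed depth on their own allele
    pdepth <- 30L
    p_s <- gt_ad(variants$gt_parent_sterile,
                 ifelse(variants$gt_parent_sterile == "0/0", pdepth, 0L),
                 ifelse(variants$gt_parent_sterile == "0/0", 0L, pdepth))
    p_f <- gt_ad(variants$gt_parent_fertile,
                 ifelse(variants$gt_parent_fertile == "0/0", pdepth, 0L),
                 ifelse(variants$gt_parent_fertile == "0/0", 0L, pdepth))
    b_s <- gt_ad("./.", variants$ref_sterile, variants$alt_sterile)
    b_f <- gt_ad("./.", variants$ref_fertile, variants$alt_fertile)
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", ".", "GT:AD",
                     p_s, p_f, b_s, b_f, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a four-sample BSA VCF
#'
#' Loads a VCF with per-sample `AD` allele depths into the variant
#' table the scan consumes. Sample names are mapped to the four roles
#' (two parents, two bulks) through `role_map`. Multi-allelic sites
#' are loaded with `n_alt` set so the filter can remove them; the
#' depths kept for them are the REF and first-ALT counts. Records are
#' sorted by (contig-header order, position); out-of-order input is
#' sorted with a warning.
#'
#' @param path Path to the VCF.
#' @param role_map Named character vector mapping each role
#'   (`parent_sterile`, `parent_fertile`, `bulk_sterile`,
#'   `bulk_fertile`) to a sample name in the file. Defaults to the
#'   roles themselves.
#' @return A tibble in the `bsa_dataset` variant layout.
#' @export
read_bsa_vcf <- function(path, role_map = stats::setNames(.bsa_roles,
                                                          .bsa_roles)) {
  missing_roles <- setdiff(.bsa_roles, names(role_map))
  if (length(missing_roles)) {
    stop("role_map lacks role(s): ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  # vcf@fix stays a matrix even for a single record
  fix <- tibble::as_tibble(as.data.frame(vcf@fix[, 1:5, drop = FALSE],
                                         stringsAsFactors = FALSE))
  names(fix) <- c("CHROM", "POS", "ID", "REF", "ALT")
  samples <- colnames(vcf@gt)[-1]
  for (role in .bsa_roles) {
    if (!role_map[[role]] %in% samples) {
      stop("sample '", role_map[[role]], "' (role ", role,
           ") is missing from the VCF", call. = FALSE)
    }
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF has no per-sample AD (allele depth) field", call. = FALSE)
  }
  ad_split <- function(sample, field) {
    parts <- strsplit(ad[, role_map[[sample]]], ",", fixed = TRUE)
    unname(vapply(parts, function(x) {
      v <- suppressWarnings(as.integer(x[field]))
      if (length(v) == 0 || is.na(v)) NA_integer_ else v
    }, 1L))
  }
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    n_alt = lengths(strsplit(fix$ALT, ",", fixed = TRUE)),
    gt_parent_sterile = unname(gt[, role_map[["parent_sterile"]]]),
    gt_parent_fertile = unname(gt[, role_map[["parent_fertile"]]]),
    ref_sterile = ad_split("bulk_sterile", 1L),
    alt_sterile = ad_split("bulk_sterile", 2L),
    ref_fertile = ad_split("bulk_fertile", 1L),
    alt_fertile = ad_split("bulk_fertile", 2L)
  )
  contigs <- vcfR::queryMETA(vcf, element = "contig")
  contig_order <- unique(out$chrom)
  if (length(contigs)) {
    ids <- vapply(contigs, function(x) {
      sub("^.*ID=", "", x[grepl("ID=", x)][1])
    }, "")
    if (!anyNA(ids) && all(out$chrom %in% ids)) contig_order <- ids
  }
  ord <- order(match(out$chrom, contig_order), out$pos)
  if (is.unsorted(ord)) {
    warning("VCF records were not position-sorted; sorting on load",
            call. = FALSE)
    out <- out[ord, ]
  }
  out
}

#' Read the truth sidecar of a simulated dataset
#'
#' @param path Path to a `.truth.tsv` written by [write_simulation()].
#' @return Tibble with `chrom`, `pos`, `true_freq_sterile`,
#'   `true_freq_fertile`, `is_causal`.
#' @export
read_truth <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read gene models from GFF3
#'
#' Extracts CDS intervals from a GFF3 file into the gene-model table
#' used by [annotate_variants()]. The gene id is taken from the CDS
#' `Parent` attribute (falling back to `ID`).
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gff <- ape::read.gff(path)
  cds <- gff[gff$type == "CDS", ]
  if (nrow(cds) == 0) stop("no CDS features in ", path, call. = FALSE)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    out <- rep(NA_character_, length(attrs))
    out[regexpr(paste0(key, "=[^;]+"), attrs) > 0] <-
      sub(paste0(key, "="), "", m)
    out
  }
  gid <- attr_field(cds$attributes, "Parent")
  gid[is.na(gid)] <- attr_field(cds$attributes[is.na(gid)], "ID")
  tibble::tibble(
    gene_id = gid,
    chrom = as.character(cds$seqid),
    strand = as.character(cds$strand),
    start = as.integer(cds$start),
    end = as.integer(cds$end)
  )
}

#' Write candidate regions as BED
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention (`start - 1`, `end`). The peak value is
#' written in the score column.
#'
#' @param regions Region tibble from [extract_regions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# candidate regions (BED: 0-based half-open)", con)
  if (nrow(regions)) {
    writeLines(sprintf("%s\t%d\t%d\tregion_%d\t%g",
                       regions$chrom,
                       as.integer(regions$start) - 1L,
                       as.integer(regions$end),
                       seq_len(nrow(regions)),
                       regions$peak), con)
  }
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path Path to the BED file.
#' @return Tibble with `chrom`, `start`, `end` (back in 1-based
#'   inclusive coordinates), `name`, `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric()))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  tibble::tibble(
    chrom = parts[, 1],
    start = as.integer(parts[, 2]) + 1L,
    end = as.integer(parts[, 3]),
    name = parts[, 4],
    score = as.numeric(parts[, 5])
  )
}

#' Write a fitted scan track as TSV
#'
#' The header comment lines record the fitting parameters for
#' provenance.
#'
#' @param track A `scan_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track_tsv <- function(track, path) {
  stopifnot(inherits(track, "scan_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# window_bp=%g step_bp=%g min_sites=%d",
                     track$window_bp, track$step_bp,
                     as.integer(track$min_sites)), con)
  utils::write.table(track$windows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a Markdown run summary
#'
#' A compact report of a scan run: filter counts, threshold used, and
#' the candidate regions found.
#'
#' @param report Filter report from [filter_variants()].
#' @param threshold Threshold value used for region extraction.
#' @param threshold_rule Human-readable description of the rule.
#' @param regions Region tibble from [extract_regions()].
#' @return Character vector of Markdown lines.
#' @export
render_run_report <- function(report, threshold, threshold_rule, regions) {
  counts <- filter_report_counts(report)
  c(
    "# BSA scan summary",
    "",
    "## Variant filtering",
    sprintf("- input sites: %d", counts[["input"]]),
    sprintf("- removed by %s: %d", report$rule, report$removed),
    sprintf("- surviving sites: %d", counts[["output"]]),
    "",
    "## Threshold",
    sprintf("- rule: %s", threshold_rule),
    sprintf("- value: %.4f", threshold),
    "",
    "## Candidate regions",
    if (nrow(regions) == 0) "- none" else
      sprintf("- %s:%d-%d (peak %.3f at %d, %d sites)",
              regions$chrom, as.integer(regions$start),
              as.integer(regions$end), regions$peak,
              as.integer(regions$peak_pos), regions$n_sites)
  )
}
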