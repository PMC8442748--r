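# Codon-level variant-effect classification (standard genetic code,
# NCBI translation table 1). Plant nuclear genes need no alternative code.

# 64-codon lookup built from the canonical TCAG-ordered amino-acid string.
.genetic_code <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1]]
  stats::setNames(aa, codons)
})

.codon_effects <- c("synonymous", "non_synonymous", "stop_gained",
                    "stop_lost", "start_lost")

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of 3-letter DNA codons (case-insensitive,
#'   `U` accepted as `T`). Stop codons translate to `"*"`.
#' @return Character vector of one-letter amino acids.
#' @examples
#' translate_codon(c("ATG", "taa", "ctg"))
#' @export
translate_codon <- function(codon) {
  codon <- chartr("u", "t", toupper(codon))
  codon <- chartr("U", "T", codon)
  bad <- nchar(codon) != 3 | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("not a DNA codon: ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(.genetic_code[codon])
}

#' Classify the effect of a single-base codon change
#'
#' Compares the translations of a reference and an alternate codon that
#' differ at exactly one position and returns the variant effect:
#' `synonymous` when both encode the same amino acid, `stop_gained` when
#' the change creates a stop codon, `stop_lost` when it destroys one,
#' `start_lost` when an annotated ATG start codon is disrupted
#' (only when `is_start_codon = TRUE`), otherwise `non_synonymous`.
#'
#' Input is case-insensitive; the convention of marking the mutated base
#' in upper case (e.g. `"aTc"` vs `"aGc"`) is accepted and ignored for
#' classification.
#'
#' @param ref_codon,alt_codon 3-letter DNA codons differing at exactly
#'   one position. Vectorised; the two vectors are recycled to a common
#'   length.
#' @param is_start_codon Logical (recycled): is this the annotated
#'   translation start?
#' @return Character vector of effect labels.
#' @examples
#' classify_codon_change("aTc", "aGc")   # Ile -> Ser: non_synonymous
#' classify_codon_change("ctA", "ctG")   # Leu -> Leu: synonymous
#' classify_codon_change("TAC", "TAA")   # stop_gained
#' @export
classify_codon_change <- function(ref_codon, alt_codon,
                                  is_start_codon = FALSE) {
  n <- max(length(ref_codon), length(alt_codon))
  ref <- toupper(rep_len(ref_codon, n))
  alt <- toupper(rep_len(alt_codon, n))
  is_start <- rep_len(is_start_codon, n)
  if (any(nchar(ref) != 3 | nchar(alt) != 3)) {
    stop("codons must be 3 bases long", call. = FALSE)
  }
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ref, alt, USE.NAMES = FALSE)
  if (any(ndiff != 1)) {
    stop("codon pair must differ at exactly one position: ",
         paste(ref[ndiff != 1], alt[ndiff != 1], sep = "/", collapse = ", "),
         call. = FALSE)
  }
  aa_ref <- translate_codon(ref)
  aa_alt <- translate_codon(alt)
  effect <- rep("non_synonymous", n)
  effect[aa_ref == aa_alt] <- "synonymous"
  effect[aa_alt == "*" & aa_ref != "*"] <- "stop_gained"
  effect[aa_ref == "*" & aa_alt != "*"] <- "stop_lost"
  effect[is_start & ref == "ATG" & alt != "ATG"] <- "start_lost"
  effect
}

#' Parse a mixed-case codon-change string
#'
#' Splits notation such as `"aTc/aGc"` into reference and alternate
#' codons and locates the mutated position. The substituted base is
#' conventionally written in upper case; when the case gives no signal
#' (uniform case on both sides) the position is inferred from the
#' base difference instead.
#'
#' @param x Character vector of `"ref/alt"` codon-change strings.
#' @return A tibble with columns `ref_codon`, `alt_codon` (upper-cased)
#'   and `mut_pos` (1-3).
#' @examples
#' parse_codon_change("aTc/aGc")
#' @export
parse_codon_change <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("not a 'ref/alt' codon change: ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  ref <- vapply(parts, `[`, "", 1L)
  alt <- vapply(parts, `[`, "", 2L)
  mut_pos <- mapply(function(r, a) {
    rc <- strsplit(r, "")[[1]]
    ac <- strsplit(a, "")[[1]]
    if (length(rc) != 3 || length(ac) != 3) {
      stop("codon is not 3 bases: ", r, "/", a, call. = FALSE)
    }
    upper <- which(rc %in% c("A", "C", "G", "T") &
                   ac %in% c("A", "C", "G", "T"))
    # prefer the upper-case convention when exactly one position is marked
    if (length(upper) == 1) return(upper)
    diffs <- which(toupper(rc) != toupper(ac))
    if (length(diffs) == 1) return(diffs)
    stop("cannot locate the mutated base in ", r, "/", a, call. = FALSE)
  }, ref, alt, USE.NAMES = FALSE)
  tibble::tibble(
    ref_codon = toupper(ref),
    alt_codon = toupper(alt),
    mut_pos = as.integer(mut_pos)
  )
}

#' Tally codon-change effects
#'
#' Counts synonymous and non-synonymous changes in a vector of effect
#' labels. With `collapse = TRUE` (default) the rarer effect classes
#' (`stop_gained`, `stop_lost`, `start_lost`) are folded into the
#' non-synonymous tally, matching the two-label reporting convention of
#' BSA candidate-gene tables; otherwise they are counted under `other`.
#'
#' @param effects Character vector of labels as produced by
#'   [classify_codon_change()].
#' @param collapse Fold stop/start effects into `non_synonymous`?
#' @return Named integer vector `c(synonymous, non_synonymous, other)`.
#' @export
count_effects <- function(effects, collapse = TRUE) {
  bad <- setdiff(unique(effects), .codon_effects)
  if (length(bad)) {
    stop("unknown effect label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  syn <- sum(effects == "synonymous")
  nonsyn <- sum(effects == "non_synonymous")
  other <- length(effects) - syn - nonsyn
  if (collapse) {
    nonsyn <- nonsyn + other
    other <- 0L
  }
  c(synonymous = syn, non_synonymous = nonsyn, other = as.integer(other))
}

#' Read a codon-change table
#'
#' Reads a TSV with columns `chrom`, `pos`, `effect`, `codon_change`
#' (the two-label `Non-synonymous coding` / `Synonymous coding`
#' convention in `effect`, mixed-case `ref/alt` codons in
#' `codon_change`), as used for the bundled Cla006625 SNP table.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the parsed codons appended.
#' @examples
#' tsv <- system.file("extdata", "cla006625_codon_changes.tsv",
#'                    package = "bsascan")
#' read_codon_table(tsv)
#' @export
read_codon_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("chrom", "pos", "effect", "codon_change")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("codon table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(tibble::as_tibble(raw),
                   parse_codon_change(raw$codon_change))
}

# -- CDS-aware annotation ----------------------------------------------------

.complement <- function(base) {
  chartr("ACGT", "TGCA", toupper(base))
}

#' Annotate variants against gene models
#'
#' Maps each variant onto the coding sequence of any overlapping gene
#' model and classifies its codon-level effect. Variants outside all
#' CDS intervals are labelled `non_coding`. Minus-strand genes are
#' handled by building the CDS from reverse-complemented genomic
#' sequence, so the reported codons are in the coding orientation.
#'
#' @param variants Tibble/data frame with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (single bases).
#' @param genes Gene models: a tibble with one row per CDS interval and
#'   columns `gene_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`, `end`
#'   (1-based inclusive). Intervals of a gene must not overlap. See
#'   [read_gene_models()] to load these from GFF3.
#' @param genome Named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences.
#' @return The variant table with `gene_id`, `ref_codon`, `alt_codon`,
#'   `codon_pos` (position of the variant within its codon) and
#'   `effect` appended (`effect` is `"non_coding"` outside CDS).
#' @export
annotate_variants <- function(variants, genes, genome) {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  n <- nrow(variants)
  out <- tibble::tibble(
    gene_id = rep(NA_character_, n), ref_codon = NA_character_,
    alt_codon = NA_character_, codon_pos = NA_integer_,
    effect = rep("non_coding", n)
  )
  for (i in seq_len(n)) {
    v <- variants[i, ]
    hit <- genes[genes$chrom == v$chrom &
                   genes$start <= v$pos & genes$end >= v$pos, ]
    if (nrow(hit) == 0) next
    gid <- hit$gene_id[1]
    model <- genes[genes$gene_id == gid & genes$chrom == v$chrom, ]
    model <- model[order(model$start), ]
    strand <- model$strand[1]
    seq_idx <- match(as.character(v$chrom), names(genome))
    if (is.na(seq_idx)) {
      stop("no sequence for chromosome ", v$chrom, call. = FALSE)
    }
    chrom_seq <- genome[[seq_idx]]
    exon_seqs <- substring(chrom_seq, model$start, model$end)
    cds <- paste(exon_seqs, collapse = "")
    # genomic offset of the variant within the plus-strand CDS
    before <- model$end < v$pos
    cds_pos <- sum(model$end[before] - model$start[before] + 1) +
      (v$pos - model$start[which(model$start <= v$pos &
                                   model$end >= v$pos)][1] + 1)
    if (strand == "-") {
      cds <- paste(rev(strsplit(.complement(cds), "")[[1]]), collapse = "")
      cds_pos <- nchar(cds) - cds_pos + 1
      ref_base <- .complement(v$ref)
      alt_base <- .complement(v$alt)
    } else {
      ref_base <- toupper(v$ref)
      alt_base <- toupper(v$alt)
    }
    if (nchar(cds) %% 3 != 0) {
      warning("CDS length of ", gid, " is not a multiple of 3",
              call. = FALSE)
    }
    codon_idx <- (cds_pos - 1) %/% 3
    within <- cds_pos - codon_idx * 3
    ref_codon <- toupper(substr(cds, codon_idx * 3 + 1, codon_idx * 3 + 3))
    if (substr(ref_codon, within, within) != ref_base) {
      stop("variant ", v$chrom, ":", v$pos, " ref allele '", v$ref,
           "' does not match the supplied reference sequence",
           call. = FALSE)
    }
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_base
    out$gene_id[i] <- gid
    out$ref_codon[i] <- ref_codon
    out$alt_codon[i] <- alt_codon
    out$codon_pos[i] <- within
    out$effect[i] <- classify_codon_change(
      ref_codon, alt_codon, is_start_codon = (codon_idx == 0)
    )
  }
  dplyr::bind_cols(variants, out)
}

#' Per-gene non-synonymous SNP load
#'
#' Tallies annotated variant effects per gene and ranks genes by their
#' number of non-synonymous changes — the ranking used to prioritise
#' candidate genes inside a mapped region.
#'
#' @param annotated Output of [annotate_variants()].
#' @return Tibble with `gene_id`, `n_variants`, `n_non_synonymous`,
#'   `n_synonymous`, sorted by decreasing non-synonymous load.
#' @export
gene_effect_load <- function(annotated) {
  coding <- annotated[!is.na(annotated$gene_id), ]
  coding |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_non_synonymous = sum(.data$effect != "synonymous"),
      n_synonymous = sum(.data$effect == "synonymous"),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_non_synonymous))
}
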