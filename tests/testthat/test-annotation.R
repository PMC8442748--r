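test_that("codon classifier handles the documented example changes", {
  expect_equal(classify_codon_change("aTc", "aGc"), "non_synonymous") # Ile/Ser
  expect_equal(classify_codon_change("ctA", "ctG"), "synonymous")     # Leu/Leu
  expect_equal(classify_codon_change("Ggt", "Agt"), "non_synonymous") # Gly/Ser
  expect_equal(classify_codon_change("TAC", "TAA"), "stop_gained")
  expect_equal(classify_codon_change("TAA", "CAA"), "stop_lost")
  expect_equal(classify_codon_change("ATG", "GTG", is_start_codon = TRUE),
               "start_lost")
  expect_equal(classify_codon_change("ATG", "GTG"), "non_synonymous")
  # case-insensitive: classification invariant under case changes
  expect_equal(classify_codon_change("GGT", "AGT"),
               classify_codon_change("ggt", "agt"))
  expect_error(classify_codon_change("ATC", "ATC"), "exactly one")
  expect_error(classify_codon_change("ATC", "GGG"), "exactly one")
  expect_error(classify_codon_change("AXC", "AGC"), "codon")
  expect_error(classify_codon_change("ATCG", "ATC"), "3 bases")
})

test_that("classifier agrees with Biostrings translation on all 576 single-base changes", {
  changes <- all_codon_changes()
  expect_equal(nrow(changes), 576L)
  got <- classify_codon_change(changes[, "ref"], changes[, "alt"])
  aa <- function(x) {
    as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                       no.init.codon = TRUE))
  }
  aa_ref <- aa(changes[, "ref"])
  aa_alt <- aa(changes[, "alt"])
  want <- ifelse(aa_ref == aa_alt, "synonymous",
          ifelse(aa_alt == "*", "stop_gained",
          ifelse(aa_ref == "*", "stop_lost", "non_synonymous")))
  expect_identical(got, unname(want))
})

test_that("mixed-case codon-change notation parses and mutated base is located", {
  p <- parse_codon_change(c("aTc/aGc", "Ggt/Agt", "tcT/tcC"))
  expect_equal(p$ref_codon, c("ATC", "GGT", "TCT"))
  expect_equal(p$alt_codon, c("AGC", "AGT", "TCC"))
  expect_equal(p$mut_pos, c(2L, 1L, 3L))
  # uniform case: position inferred from the base difference
  expect_equal(parse_codon_change("atc/agc")$mut_pos, 2L)
  expect_equal(parse_codon_change("ATC/AGC")$mut_pos, 2L)
  expect_error(parse_codon_change("atc"), "ref/alt")
  expect_error(parse_codon_change("atcg/atca"), "3 bases")
})

test_that("effect tallies are exact, additive and collapse correctly", {
  eff <- c("synonymous", "non_synonymous", "stop_gained", "synonymous")
  expect_equal(count_effects(eff),
               c(synonymous = 2L, non_synonymous = 2L, other = 0L))
  expect_equal(count_effects(eff, collapse = FALSE),
               c(synonymous = 2L, non_synonymous = 1L, other = 1L))
  expect_equal(count_effects(character(0)),
               c(synonymous = 0L, non_synonymous = 0L, other = 0L))
  # additivity under concatenation
  e1 <- c("synonymous", "non_synonymous")
  e2 <- c("non_synonymous", "stop_lost")
  expect_equal(count_effects(c(e1, e2)),
               count_effects(e1) + count_effects(e2))
  expect_error(count_effects("nonsense_label"), "unknown")
})

test_that("bundled Cla006625 codon table classifies in full agreement", {
  tsv <- system.file("extdata", "cla006625_codon_changes.tsv",
                     package = "bsascan")
  tab <- read_codon_table(tsv)
  expect_equal(nrow(tab), 16L)
  got <- classify_codon_change(tab$ref_codon, tab$alt_codon)
  want <- ifelse(tab$effect == "Synonymous coding",
                 "synonymous", "non_synonymous")
  expect_identical(got, want)
  counts <- count_effects(got)
  expect_equal(counts[["non_synonymous"]], 9L)
  expect_equal(counts[["synonymous"]], 7L)
})

test_that("CDS-aware annotation classifies planted variants and strand symmetry holds", {
  # toy gene, 2 codons: ATG GGT -> protein M G
  genome <- c(chrA = "TTTATGGGTTAATTT")
  genes <- tibble::tibble(gene_id = "g1", chrom = "chrA", strand = "+",
                          start = 4L, end = 12L)
  variants <- tibble::tibble(
    chrom = "chrA",
    pos = c(8L, 9L, 2L),
    ref = c("G", "T", "T"),
    alt = c("A", "C", "A")
  )
  ann <- annotate_variants(variants, genes, genome)
  # GGT -> GAT is Gly->Asp (non-syn); GGT -> GGC is synonymous
  expect_equal(ann$effect, c("non_synonymous", "synonymous", "non_coding"))
  expect_equal(ann$gene_id, c("g1", "g1", NA))
  load <- gene_effect_load(ann)
  expect_equal(load$n_non_synonymous, 1L)
  expect_equal(load$n_synonymous, 1L)

  # same biological change encoded on the minus strand
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  genome_m <- c(chrA = rc(genome[["chrA"]]))
  genes_m <- tibble::tibble(gene_id = "g1", chrom = "chrA", strand = "-",
                            start = 4L, end = 12L)
  variants_m <- tibble::tibble(
    chrom = "chrA", pos = 16L - variants$pos[1:2],
    ref = c("C", "A"), alt = c("T", "G")
  )
  ann_m <- annotate_variants(variants_m, genes_m, genome_m)
  expect_equal(ann_m$effect, ann$effect[1:2])
  expect_equal(ann_m$ref_codon, ann$ref_codon[1:2])
  expect_equal(ann_m$alt_codon, ann$alt_codon[1:2])

  # ref mismatch against the supplied sequence is an explicit error
  bad <- tibble::tibble(chrom = "chrA", pos = 8L, ref = "C", alt = "A")
  expect_error(annotate_variants(bad, genes, genome), "does not match")
})
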