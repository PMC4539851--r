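# In-code fixtures shared across test files.

# minimal gene table builder
gene_df <- function(start, stop, strand = "+", type = "CDS",
                    replicon = "chr1", product = NA_character_, ...) {
  if (!length(start))
    return(data.frame(replicon_id = character(0), feature_type = character(0),
                      strand = character(0), start = integer(0),
                      stop = integer(0), stringsAsFactors = FALSE))
  data.frame(replicon_id = replicon, feature_type = type, strand = strand,
             start = start, stop = stop, product = product, ...,
             stringsAsFactors = FALSE)
}

make_ann <- function(start, stop, strand = "+", type = "CDS", label = "A",
                     ...) {
  annotation(gene_df(start, stop, strand = strand, type = type, ...),
             label = label)
}

# random annotation for property tests: dense enough to create overlaps
random_annotation <- function(n, seed, label = "R", replicon_length = 20000L) {
  set.seed(seed)
  start <- sample.int(replicon_length - 2000L, n, replace = TRUE)
  len <- sample(c(90L, 150L, 300L, 600L, 900L), n, replace = TRUE)
  types <- sample(c("CDS", "tRNA", "rRNA", "ncRNA"), n, replace = TRUE,
                  prob = c(0.8, 0.1, 0.05, 0.05))
  annotation(gene_df(start, pmin(start + len - 1L, replicon_length),
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     type = types,
                     product = sample(c("hypothetical protein",
                                        "DNA gyrase subunit B"),
                                      n, replace = TRUE)),
             label = label)
}

# a hand-written GenBank fixture exercising complement, join, pseudo,
# partial markers and a skipped bare gene feature
genbank_fixture_lines <- function() {
  c("LOCUS       CP000001 50000 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  Synthetic test genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..50000",
    "     gene            100..1099",
    "                     /locus_tag=\"TST_0001\"",
    "     CDS             100..1099",
    "                     /locus_tag=\"TST_0001\"",
    "                     /gene=\"polA\"",
    "                     /product=\"DNA polymerase I\"",
    "     CDS             complement(<300..>800)",
    "                     /locus_tag=\"TST_0002\"",
    "                     /product=\"hypothetical protein\"",
    "                     /pseudo",
    "     CDS             join(2000..2500,2600..2900)",
    "                     /locus_tag=\"TST_0003\"",
    "                     /product=\"conserved hypothetical protein\"",
    "                     /note=\"possible frameshift in homopolymer\"",
    "     tRNA            5000..5075",
    "                     /product=\"tRNA-Ala\"",
    "     misc_RNA        6000..6100",
    "                     /product=\"ignored\"",
    "ORIGIN",
    "        1 aaaaaaaaaa aaaaaaaaaa aaaaaaaaaa aaaaaaaaaa aaaaaaaaaa aaaaaaaaaa",
    "//")
}
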