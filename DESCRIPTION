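Package: selsignal
Title: Molecular Signatures of Selection and Knockout Fitness at the Gene Level
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level comparison of seven molecular signatures of selection
    in selfing plants: pairwise dN/dS by Nei-Gojobori counting with
    Jukes-Cantor correction, the McDonald-Kreitman neutrality index (NI) and
    direction of selection (DOS), and four site-frequency-spectrum statistics
    (Tajima's D, Fu and Li's D*, Fay and Wu's H, Zeng's E) computed from
    multi-accession haplotype alignments with an outgroup. Includes the
    essential-gene randomisation test, knockout-fitness association tests
    (Kruskal-Wallis by selection class and Spearman correlation), readers for
    the standard formats involved (FASTA, GFF3, VCF, tabular fitness data),
    and a synthetic-data generator (neutral coalescent, codon-level ortholog
    divergence, replicate-structured fitness tables) so the whole pipeline is
    exercisable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
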