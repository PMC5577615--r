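Package: lcamp
Title: Mining Linear Cationic Antimicrobial Peptide Precursors from Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for linear, cationic antimicrobial peptide
    (AMP) precursors of the myticalin family from assembled transcriptome
    contigs. Extracts open reading frames in all six frames with a
    precursor-sized length gate, screens for secretory signal peptides,
    applies sliding-window cationicity filters (arginine/proline content and
    side-chain isoelectric point), annotates the four-region precursor
    architecture (signal peptide, mature core, dibasic convertase site,
    anionic tail), models proteolytic maturation with carboxypeptidase
    trimming and C-terminal amidation, characterizes peptides by
    Henderson-Hasselbalch net charge and isoelectric point, classifies mature
    peptides into subfamilies, builds majority-rule consensus sequences,
    screens virtual peptides for pseudogenizing stop codons, and generates
    seeded synthetic transcriptomes with planted precursors and adversarial
    decoys for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
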