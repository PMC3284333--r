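Package: poolscreen
Title: Causative-Mutation Screens from Pooled-Progeny Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies causative mutations in phenotype-selected pools of haploid
    fungal progeny sequenced as bulked DNA. Provides a ground-truthed simulator of
    crosses, spore pools and mate-pair reads; read cleaning, a minimal unique-best
    seed-and-extend mapper and SAM import; per-sample pileups and coverage tracks;
    a penetrance-filtered small-variant screen that classifies sites by cross-sample
    presence pattern and separates reference-assembly errors; kilobase-scale lesion
    detection by sample-specific coverage gaps and mate-pair insert-size anomalies;
    and molecular-consequence annotation (splice-donor defects, stop-loss protein
    extensions, ORF-overlapping deletions) against GFF3 gene models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
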