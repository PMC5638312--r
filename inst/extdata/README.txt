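Published summary tables for the Eurasian walnut germplasm panel, shipped as
plain text and used as worked-example inputs by the acceptance checks:

  walnut_locus_stats.tsv          locus-level variability (n, A, He, Ho, F)
  walnut_diversity_partition.tsv  gene-diversity partition (HT, HG, DGT, GGT)
  walnut_amova_components.tsv     molecular-variance components and percentages

These are printed summary statistics, not raw data. The full multilocus
genotype and occurrence tables are separate supplementary spreadsheets that
cannot be redistributed here; placing CSV exports of them under
inst/extdata/supplementary/ (walnut_genotypes.csv, walnut_occurrences.csv)
enables the corresponding acceptance checks.
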