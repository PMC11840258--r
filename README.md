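# defchimera

Analysis toolkit for **chimeric alpha-defensin transcripts and peptides in
mouse Paneth cells**.

Paneth cells devote ~85% of their mRNA to a cluster of 28 near-identical
two-exon alpha-defensin (*Defa*) genes. Their RNA-seq libraries contain reads
that fit no single gene but are consistent with *chimeric* transcripts: a
donor gene's sequence up to a breakpoint inside the exon-2 coding sequence,
continued by the homologous suffix of an acceptor gene. Because exon 2
encodes the mature peptide (~33 aa, six disulfide-forming cysteines), such
chimeras encode novel antimicrobial peptides. This package implements the
computational arms of that analysis for people working on highly duplicated
antimicrobial gene families:

* **Annotation reconciliation** — merge gene models from several sources
  (RefSeq/GENCODE/MGI disagree on *Defa* boundaries) into maximal extents
  with provenance (`merge_gene_models()`), plus the size/overlap filters
  used for defensin predictions in other species (`filter_predictions()`).
* **Chimera enumeration** — all theoretical exon-2 chimeras of a parental
  family: for every ordered donor/acceptor pair and every breakpoint
  `b ∈ [1, exon2_len − 1]`, the candidate CDS

  `donor_exon1 + donor_exon2[1..b] + acceptor_exon2[b+1..end]`

  is kept iff it is in frame with a single terminal stop, keeps the six
  mature-region cysteines, and differs from both parents at the nucleotide
  and protein level; duplicates collapse with full provenance
  (`enumerate_all()`).
* **Read quantification** — a self-contained k-mer equivalence-class EM
  quantifier with TPM output, substitution-error-aware read classes,
  decoy-aware index roles, and junction-spanning split-read support
  (`build_index()`, `quantify()`, `screen_split_reads()`,
  `occurrence_summary()`, `donor_acceptor_totals()`).
* **Peptide evidence** — in-silico trypsin/Glu-C/elastase digestion,
  junction-spanning peptide selection and uniqueness checks against the
  parental proteome; a chimera is *provable* iff some peptide spans the
  junction and matches no parental window (`digest()`,
  `junction_peptides()`, `uniqueness_check()`, `evidence_report()`).
* **Antibacterial activity** — deterministic four-parameter logistic fits of
  colony-count dose-response assays,
  `s(x) = lower + (upper − lower) / (1 + e^{slope (ln x − ln midpoint)})`,
  absolute-50% IC50, and specific activity `U/mg = 1000 / IC50(µg/ml)`
  (`fit_4pl()`, `ic50()`, `specific_activity()`, `aggregate_table()`).
* **Synthetic data** — a defensin-family generator (92-aa pre-pro-protein,
  19-aa signal, 33-aa mature peptide with a conserved cysteine scaffold,
  configurable pairwise identity), chimera-spiked transcript pools matching
  the measured abundance regime, and an error-bearing read simulator with a
  truth table (`make_family()`, `make_pool()`, `simulate_reads()`), so the
  whole pipeline is testable without downloads.

## Worked example

```r
library(defchimera)

fam  <- make_family(n_genes = 28, identity = 0.90, seed = 42)
cs   <- enumerate_all(fam)
pool <- make_pool(fam, cs, seed = 42)          # 85.19% family, 0.24% chimeric
sim  <- simulate_reads(pool, n_reads = 1e6, read_len = 70,
                       error_rate = 0.001, seed = 42)
idx  <- build_index(data.frame(id = pool$id, sequence = pool$sequence,
                               role = pool$role))
q    <- quantify(sim$reads, idx)

tab <- q$table
fam_tpm <- sum(tab$tpm[tab$role %in% c("parental", "chimera")])
round(c(family_pct   = fam_tpm / 1e4,
        chimeric_pct = 100 * sum(tab$tpm[tab$role == "chimera"]) / fam_tpm), 3)
#>   family_pct chimeric_pct
#>       85.224        0.257
```

The synthetic family occupies 85.2% of the recovered TPM (the measured Defa
share is 85.19%) and the chimeric spike of 0.24% of family mRNA is recovered
as 0.257% — the estimator's scatter at this depth is discussed in the
methods vignette. Published-table arithmetic is reproduced exactly, e.g.

```r
tab2 <- read.delim(system.file("extdata", "table2_activities.tsv",
                               package = "defchimera"), row.names = 1)
aggregate_table(as.matrix(tab2))$row_means[c("Defa4", "Defa35-30")]
#>     Defa4 Defa35-30
#>       396       510
```

the mean specific activities (U/mg) of the strongest parental and chimeric
peptides against four bacterial species.

The numbered drivers under `analysis/` run each arm end to end
(`01_annotate_locus.R` … `05_dose_response.R`) and write tables under
`results/`. The methods vignette (`vignettes/chimeric-defensins.Rmd`)
documents the models, filters, estimator design and limitations.

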