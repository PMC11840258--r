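---
title: "Methods: enumerating, detecting and assaying chimeric alpha-defensins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumerating, detecting and assaying chimeric alpha-defensins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defchimera)
```

## The problem

Mouse Paneth cells transcribe a cluster of 28 highly similar two-exon
alpha-defensin (*Defa*) genes at extraordinary levels — the family accounts
for roughly 85% of the cellular mRNA. RNA-seq of purified Paneth cells shows
reads that cannot be placed on any single gene but are consistent with
*chimeric* transcripts: a donor gene's sequence up to some point inside the
second exon's coding sequence, continued by the homologous suffix of an
acceptor gene. Because the second exon encodes the mature, biologically
active peptide, such chimeras encode novel antimicrobial peptides.

This package implements the computational arms of that analysis so each step
is reproducible and testable without external data:

1. **annotation** — reconcile gene models from several annotation sources
   (RefSeq / GENCODE / MGI disagree on *Defa* transcript boundaries) into
   maximal gene extents, plus the size/overlap filters used for in-silico
   defensin predictions in other species;
2. **chimera** — exhaustively enumerate theoretical exon-2 chimeras with the
   published filters;
3. **quant** — a self-contained equivalence-class EM read quantifier with
   TPM output, plus junction-spanning split-read support;
4. **peptides** — in-silico proteolysis and junction-peptide uniqueness
   logic (the proteomic evidence that chimeras are translated);
5. **activity** — four-parameter logistic dose-response analysis of
   colony-count assays (IC50, specific activity in U/mg);
6. **simulate** — a synthetic defensin-family generator so that all of the
   above runs on data with known ground truth.

## Gene-model reconciliation

All sources annotate full-length coding sequence; they disagree in the UTRs,
by a few bp up to ~112 bp. `merge_gene_models()` takes, per gene, the
earliest start and latest end over sources and records which source
contributed each boundary. Using maximal extents lets more reads map to the
locus. The retired *Defa6* symbol is folded into *Defa24* via an alias table
(`defa_aliases`) before merging. We deliberately do not clip merged extents
to neighbouring genes; in this locus the merged UTRs stay well within the
intergenic distances, and clipping would silently change gene models.

For in-silico predictions in species without curated defensin annotation,
`filter_predictions()` drops predictions shorter than 500 bp or longer than
3000 bp and collapses interval pairs with at least 75% overlap into their
union span. "75% overlap" is interpreted *reciprocally* — the shared bases
must cover 75% of both intervals — so a short fragment cannot absorb a
full-length gene; a single-sided mode is available. Collapse iterates to a
fixpoint in coordinate order, which makes it order-independent and
idempotent (property-tested).

## Chimera enumeration

A parental gene is modelled as `defensin_gene()`: exon-1 and exon-2 CDS, a
~92-aa pre-pro-protein (19-aa signal peptide, pro region, 33-aa mature
peptide), with exactly six cysteines in the mature region. For an ordered
(donor, acceptor) pair, every nucleotide breakpoint `b` in
`[1, exon2_len - 1]` yields a candidate: donor exon 1 + donor exon-2 prefix
of length `b` + acceptor exon-2 suffix from the same offset. Equal-offset
(ungapped homologous) crossover is the natural model for a family this
similar and of equal length; exon 1 always comes from the donor because the
analysis concerns second-exon events only.

Candidates are filtered in this order, with every rejection recorded in a
ledger: (1) in frame with exactly one stop codon, at the end; (2) cysteine
structure of the mature region intact — by default *count6* (exactly six
cysteines), with a stricter *parental_pattern* mode requiring the offsets to
match a parent; (3) different from both parentals at the nucleotide and the
protein level; (4) per-pair duplicates collapse to the smallest breakpoint.
After merging all pairs, candidates whose protein equals *any* parental
pre-pro-protein are removed and global nucleotide duplicates collapse into
one member whose provenance lists all origins.

The enumeration is verified against an independent brute-force oracle
(naive loops, hand-written codon table) on dozens of random small families,
and obeys dedup idempotence, parental exclusion, donor/acceptor relabelling
symmetry, and monotonicity in the parental set.

## Read quantification

Production quantifiers (Salmon-style) were used for the real libraries; this
package ships its own quantifier so the pipeline is self-contained. The index stores every k-mer
(k = 21) of every transcript with its position; transcripts carry roles
(`parental`, `chimera`, `background`, `decoy`), and decoys take part in
assignment but are excluded from reported TPM — reproducing the four
decoy-aware index configurations used on the real data.

**Assignment.** For `max_mismatches` = m, a read is compared against the
candidates found through m+1 pairwise-disjoint anchor k-mers: any transcript
matching the read with at most m substitutions must be clean on at least one
anchor (pigeonhole), so the candidate set is exact for reads of length at
least `(m+1)k`. Each candidate is verified by direct mismatch counting.

**Weighted equivalence classes.** The class of a read keeps *every*
transcript within m mismatches, weighted by the substitution-error
likelihood `(error_rate/3)^mm` relative to a perfect match. This matters in
a near-identical family: about 7% of 70-bp reads carry a sequencing error,
and an error at a position where donor and acceptor differ makes a parental
read an *exact* match to a chimera. Best-match-only classes then exclude the
true parent entirely and overestimate the chimeric load roughly tenfold;
with the weighted classes the abundance-weighted EM resolves such reads
correctly (we verified that an E-step at the true abundances reproduces the
true chimeric read count).

**EM.** Class counts are distributed over transcripts by
expectation-maximisation on read-origin probabilities, uniform over
non-chimera transcripts and starting chimeras at a negligible total share
(`em_init = "sparse_chimera"`). The sparse start matters because a chimera
shares literally every window with its donor and acceptor when its
breakpoint is close to one end, so the likelihood is flat between a parent
and its near-parental chimeras; a uniform start parks parental mass on
thousands of chimeras, while from the sparse start a chimera only gains mass
when junction-spanning reads that no parental can explain within
`max_mismatches` demand it (such reads restore its abundance in a single
iteration, so the start is not a zero-lock). Iteration stops when the
largest change in origin probabilities falls below 1e-8 (typically
~500–700 iterations at the default scale; the cap is 1000). TPM is
count/effective-length normalised to one million over non-decoy transcripts,
with effective length `length - read_len + 1` floored at 1.

**Precision of the chimeric load.** On 28-gene synthetic families the
estimator is calibrated but not noiseless: chimeras whose discriminating
positions sit near a transcript end have few junction-informative windows
(leverage up to ~15), so the recovered chimeric fraction at a 0.24% spike
and 1e6 reads scatters around the truth with a standard deviation of roughly
2e-4 in fraction units across read seeds. Parametric-bootstrap bias
correction, a VBEM-style sparsity prior and post-hoc pruning were evaluated
and did not reduce this scatter; they are not part of the estimator.

**Split reads.** `split_read_support()` anchors a read on two parents by
their best ungapped offsets and returns the in-read breakpoint minimising
total mismatches (ties to the smallest breakpoint; equal to a brute-force
oracle by construction). `screen_split_reads()` first discards reads that
match a parental end-to-end, so error-free parental-only libraries produce
zero chimera calls by design. Indels are out of scope: 60–80-bp reads on
near-identical references make ungapped anchoring appropriate.

## Peptide evidence

Digestion rules: trypsin cleaves after K/R except before P; Glu-C after E
(ammonium-bicarbonate specificity; D-cleavage by flag); elastase after
A/V/S/G/L/I — elastase has no sharp consensus specificity, so the common
broad porcine rule is used and is configurable. At zero missed cleavages
the fragments concatenate to the input (property-tested on random
proteins). Observability is approximated by a 4–60-aa length window rather
than mass/charge modelling.

The junction residue of a chimera in protein coordinates is
`floor((exon1_len + breakpoint_nt)/3)` — the last residue wholly encoded by
the donor. A peptide supports the chimera if it has at least one residue
strictly on each side of the junction *and* matches no window of any
parental protein within `max_mismatches` substitutions (an ungapped
near-substring scan standing in for a protein BLAST). A chimera is
"provable" when at least one theoretical peptide from any of the three
digests carries both flags. Appending a GSG-His6 tag to an acceptor parent
(the knock-in design used to purify chimeric protein in vivo) tags every
chimera with that acceptor and leaves the junction logic unchanged
(`tag_cterm()`).

## Dose-response analysis

Colony counts are normalised per replicate to the 0-dose control
(`survival_from_counts()`, with a dilution column implementing the "highest
countable plating" rule). `fit_4pl()` fits
`s(x) = lower + (upper - lower)/(1 + exp(slope (ln x - ln midpoint)))` by
Levenberg–Marquardt least squares from a fixed multi-start grid (slope in
±{0.5, 1, 2}, log-midpoint at the dose quartiles), keeping the best SSE and
breaking ties toward the smallest midpoint, so the fit is deterministic.
SSE-tied fits with different midpoints (constant or non-monotone data) are
flagged `unstable`.

The IC50 is the *absolute* 50% survival crossing — "the dose that kills half
the bacteria" — solved analytically from the fit, not the curve midpoint;
the two coincide only for symmetric curves with lower = 0 and upper = 1.
Curves that never cross 0.5 within 10x the largest assay dose yield a
flagged `NA`.

Specific activity is defined as `U/mg = 1000 / IC50(ug/ml)`: with 1 U the
dose killing 50% of bacteria in the 1-ml assay, 1 mg of peptide contains
1000/IC50 such doses. The published activity table does not come
with a stated conversion formula, so this definition — which reproduces plausible IC50s of
roughly 1.3–170 ug/ml from the published activities — is a documented
choice and pluggable. Consequently only the *aggregation arithmetic* of the
published activity table is reproduced exactly: all row means match under
half-up rounding (`aggregate_table()`), while the published column means do
not follow from the printed cells (E. coli: 345 computed vs 348 printed,
with the Defa30 row printed twice); we reproduce row means and document the
column-mean discrepancy rather than matching it.

## The synthetic-data generator

`make_family()` works backwards from a valid random mature peptide with six
cysteines at family-conserved offsets: an ancestor protein and codon
sequence are drawn, then each gene receives random nucleotide substitutions
(rejecting any that create a stop, touch the cysteine scaffold or the stop
codon, or change the mature cysteine count) until the target mean pairwise
identity — default 0.90 — is met within ~2 points. All genes share the exon
boundary, so equal-offset crossovers are well defined, as in the real
family.

`make_pool()` reproduces the measured abundance regime: the family occupies
85.19% of molecules; the most abundant gene is pinned to 16.4% of the family
(the Defa24 share), the rest log-normal (several near zero, like
Defa25/31/37); the chimeric load is 0.24% of family molecules, carried by an
active subset sized so each active chimera averages 7.5 TPM — the 5–10 TPM
range in which detected chimeras were observed. Spreading the load over all
~8000 theoretical chimeras instead would put ~0.25 reads on each at 1e6
reads, a regime in which no method could recover per-chimera abundances and
which matches no observation. Inactive chimeras remain in the reference
index, exactly as most theoretical chimeras are never observed in a sample.

`simulate_reads()` draws uniform fragment positions (read probability
proportional to molecule abundance times the number of valid starts),
plants substitution errors at 0.001/base (no indels — the generator does not
model indel errors, homopolymer artefacts, coverage bias or quality-score
structure of real sequencers), and records a truth table. Everything is
deterministic per seed.

What passing tests on these data do **not** show about real data: real
*Defa* genes have more homogeneous divergence patterns shaped by gene
conversion, real libraries mix read lengths, platforms and error profiles,
and real chimera abundances are unknown; the simulations validate the
*machinery* (enumeration exactness, quantifier calibration, evidence logic,
fit recovery), not biological estimates.

## Scale and numerical choices

Default problem sizes keep every analysis on a laptop-class single core:
28-gene families (~8000 enumerated chimeras), 1e6 70-bp reads for the
end-to-end recovery (about two minutes through index, classification and
EM), 50 random small families for the oracle-equivalence property, 1000
random proteins for digestion completeness. k = 21 balances specificity
against the 60–80-bp read length; EM tolerance 1e-8 on origin
probabilities; interval collapse and per-pair dedup use deterministic
coordinate/breakpoint order; ties in 4PL fitting resolve to the smallest
midpoint.

## A worked example

```{r example, eval = FALSE}
fam <- make_family(n_genes = 28, identity = 0.90, seed = 42)
cs <- enumerate_all(fam)
pool <- make_pool(fam, cs, seed = 42)
sim <- simulate_reads(pool, n_reads = 1e6, read_len = 70,
                      error_rate = 0.001, seed = 42)
idx <- build_index(data.frame(id = pool$id, sequence = pool$sequence,
                              role = pool$role))
q <- quantify(sim$reads, idx)
tab <- q$table
fam_tpm <- sum(tab$tpm[tab$role %in% c("parental", "chimera")])
c(family_pct = fam_tpm / 1e4,
  chimeric_pct = 100 * sum(tab$tpm[tab$role == "chimera"]) / fam_tpm)
```

The numbered scripts under `analysis/` run each arm end to end and write
their tables under `results/`; `scripts/acceptance.R` recomputes the
headline quantities into a single JSON file.

## Known limitations

* Crossovers are single-breakpoint, equal-offset and exon-2-only; chimeras
  of more than two parents, indel-tolerant junctions, trans-splicing and
  read-through transcripts are out of scope.
* The quantifier's chimeric-load estimate carries irreducible scatter from
  low-leverage junctions (see above); per-chimera TPMs at the default spike
  level are order-of-magnitude estimates.
* Uniqueness checks are ungapped substring scans, not full local alignment.
* The U/mg conversion is a defined convention, not a published formula.
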