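---
title: "svpath: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svpath: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Germline structural variants (SVs) — deletions, duplications, insertions,
inversions and translocations of ≥ 50 bp — are poorly covered by clinical
variant databases, especially for cohorts of under-represented ancestry.
Deciding whether a rare SV is potentially pathogenic therefore cannot rest
on a ClinVar lookup alone: it requires high-confidence calling, careful
population-frequency QC, gene-impact annotation, and a consensus across
impact-prediction tools plus cancer-gene evidence. `svpath` implements that
workflow end to end, with a synthetic-cohort generator in place of the
controlled-access sequencing data the design was calibrated on.

# Model and assumptions

## Breakpoint representation

Every SV is a pair of breakpoints with junction orientations following VCF
breakend semantics (`+` = the joined segment extends left of the position,
`-` = it extends right). Simple types are fixed orientation patterns — DEL
`(+,-)`, tandem DUP `(-,+)`, INV `(+,+)`/`(-,-)` — which is also the rule
used to resolve paired breakend records from a breakend-only caller into
simple types. Adjacent same-chromosome mates carrying an inserted sequence
resolve to INS; different chromosomes give TRA. Positions are 1-based
(VCF); BED input is converted on read. SV length is `pos2 − pos1` (no +1):
breakpoints delimit the rearranged segment, and this convention is what
makes published coordinate arithmetic come out exactly (e.g. a deletion at
28017719–28020677 is 2,958 bp). Lengths are undefined for translocations.
Intra-chromosomal records are canonicalized to `pos1 ≤ pos2`;
inter-chromosomal breakpoint order is preserved as reported because fusion
names depend on it. Orphan breakends (mate never seen) are retained as
single-junction records with a warning — filters, not I/O, decide
exclusion. Breakpoints are treated as points; confidence intervals (CIPOS)
do not participate in matching.

## Caller concordance

Two calls are concordant iff same SV type, same chromosome pair, both
breakpoint distances ≤ the window (default **200 bp**), and **at least
one** of the two records is PASS. "PASS by one of the two callers" is read
as *at least* one: the stricter exactly-one reading would discard calls
confirmed by both callers, which cannot be what "high-confidence" means.
Matching is one-to-one; among multiple in-window candidates the pair with
the smallest `bp1_dist + bp2_dist` wins, ties broken by record id — the
underlying interval tool reports all overlaps, so a deterministic
assignment rule is our choice, not a published one. Insertions are matched
on their single locus; translocations are compared in reported mate order
with a reciprocal fallback so swapped-mate representations still match.

## Genotype QC and allele frequencies

QC order is fixed and matters (a regression test plants low-quality calls
and checks that skipping the masking step changes frequencies):

1. site filters — FILTER = PASS and `PASS_ratio ≥ 0.5`;
2. call masking — FT ≠ PASS masks DEL/DUP/INS calls; breakend-derived
   sites (INV/TRA) carry no FT, so GQ < 20 masks instead;
3. per-group missingness ≤ 0.2 required in **both** groups ("either"
   exceeding drops the site);
4. fixed sites (overall AF = 1) removed — they measure reference
   divergence, not cohort variation;
5. frequencies from the surviving calls only: per group AC, AN = 2 ×
   non-missing calls, AF = AC/AN, MAF = min(AF, 1 − AF).

Ploidy is fixed at 2 for all samples including sex chromosomes (the
source design gives no sex-chromosome rule; an all-male cohort makes chrX
dosage a real caveat, noted under limitations). Frequencies are kept
unrounded internally; display columns round half-up to 3 decimals. Tier
boundaries are forced by the definitions "rare: MAF < 1 %" and "common:
MAF > 5 %" (both strict), leaving the closed interval [1 %, 5 %] as
low-frequency.

## Gene impact

Annotation uses one canonical transcript per gene. The decision table
(first match wins; gene-body rules, then promoter, then enhancer, then
intergenic):

* **DEL** — removes ≥ 1 CDS base → pLoF; removes UTR exon bases only →
  UTR; fully inside one intron → intronic. Keying pLoF on CDS rather than
  any exon base is what makes the UTR category reachable, consistent with
  the gnomAD-style category set this taxonomy mirrors.
* **DUP** — gene strictly inside, both breakpoints outside → CG; both
  breakpoints inside the gene: both in exons → pLoF, ≥ 1 whole exon
  strictly inside the duplicated interval → IED, otherwise
  partial-exon DUP; exactly one breakpoint inside → partial-gene DUP.
* **INV** — gene strictly inside → whole-gene INV; any breakpoint in the
  gene body (introns included) → pLoF. The intron-included reading is an
  interpretation, but it is the only one consistent with published
  inversion candidates annotated as pLoF.
* **TRA** — breakpoint in a gene body → pLoF; two distinct genes hit →
  fusion `GENE1-GENE2` in reported order.
* **INS** — the table in the source design is silent on insertions; we
  classify by breakpoint containment (CDS → pLoF, UTR exon → UTR, intron →
  intronic). The alternative (all INS fall to regulatory/intergenic) would
  contradict the pathogenicity module's own coverage-constrained INS
  candidacy example.

SVs with a defined span above **1 Mb** are annotated via breakpoint-hit
genes only: short-read evidence supports the breakpoints, not the interior
of very large events. Promoters are the 1 kb window immediately upstream of
the TSS on the transcribed strand and never overlap their own gene body.
One annotation per (SV, gene); an SV may be, say, CG for the duplicated
gene and pLoF for the two breakpoint-flanking genes, and a promoter SV for
one gene can be pLoF for another.

## Catalog matching and pathogenicity cascade

Catalog matching mirrors caller concordance (type equality + both
breakpoints within 200 bp); type equality is enforced even though the
source text does not state it, for symmetry. The per-SV cascade, first rule
wins:

1. not gene-disruptive (disruptive = pLoF, CG, IED);
2. common — MAF > 5 % in a group;
3. ClinVar short-circuit — pathogenic/likely-pathogenic accepted without
   consulting scores (published candidate tables list ClinVar SVs without
   reference to panel scores), benign/likely-benign excluded, uncertain
   falls through;
4. score consensus — ≥ 2 of 4 tools at threshold (StrVCTVRE 0.37 = its
   published ClinVar 90 %-sensitivity point; CADD-SV 10 = top decile of
   its reference distribution; POSTRE 0.8 and PhenoSV 0.5 = the tools' own
   pathogenicity labels). Absent scores never pass and are never imputed;
   tool coverage is type-dependent (StrVCTVRE only exonic DEL/DUP, CADD-SV
   no INV/TRA, POSTRE no INS, PhenoSV everything), so a TRA needs both
   POSTRE and PhenoSV. Candidacy is monotone in every score
   (property-tested).
5. cancer gene-set support — disrupted genes (fusion partners included,
   union semantics) in ≥ 2 of 3 sets;
6. rarity — MAF < 1 % required in both groups; any catalog-reported
   population AF ≥ 0.01 excludes (the 0.01 cutoff is inferred from the two
   worked exclusions at AF 0.03 and 0.01; the source never states it);
7. curated gene-role gate — roles are an *input* (literature curation is
   out of algorithmic scope): mixed tumour-suppressor + oncogene
   involvement → cautionary; any unclear/conflicting/missing role →
   cautionary (missing genes warn); else pLoF of a tumour suppressor or
   CG/IED of an oncogene → pp_sv; else unlikely. The CG/IED-of-a-tumour-
   suppressor case is not in the source table; we classify it `unlikely`
   by symmetry with pLoF-of-an-oncogene (dosage gain of a suppressor is
   not a pathogenic mechanism).

## Reporting

Carrier summaries count distinct patients per tier and per two unions:
ClinVar + predicted PP-SV (the headline "patients with a potentially
pathogenic SV") and all three tiers. Percentages round half-up to one
decimal (tiers) or to integers (eligibility), matching the conventions of
the published cohort arithmetic, and every printed percentage is
recomputed from its own counts at render time. Aggressive disease is ISUP
grade group ≥ 3; carriers with unknown grade are excluded from the default
denominator and reported separately, with the all-carrier convention also
emitted — the published 13/14 figure is not reproducible from the printed
carrier table without an assumption about one unknown, so both conventions
are surfaced rather than picking silently.

# The synthetic cohort

`simulation_plan()` defaults are the stated world: 113 + 57 samples in two
ancestry groups, a 36-SV roster covering all eleven impact categories and
all eleven pathogenicity tiers, noiseless caller concordance
(shared fraction 1, jitter 0) and clean genotypes (error and missingness
0). Grade-group distributions are fixed so that 81/113 (72 %) Africans and
49/57 (86 %) Europeans sit at GG ≥ 4 and 93/113 (82 %) at GG ≥ 3 — the
eligibility arithmetic of the reference cohort. Planted frequency classes
are carrier *counts* (1 or 2 rare carriers, ~2.2 % low-frequency, ~27 %
common at reference size, capped at group size for small cohorts); the
truth table always records the AF implied by the actual counts. Score
panels are drawn from explicit pass/fail templates (0/1/2/4-of-4 over the
covered tools) rather than score distributions, so classifier tests are
exact. A single seed determines everything; sub-seeds are derived per
section so partial regeneration is stable, and generation is byte-identical
across runs.

What it emulates: two caller dialects with controlled sharing and bounded
breakpoint jitter (clipped at 2 sd); a genotyped multi-sample set with
PASS_ratio/FT/GQ structure; a catalog with significance labels, population
AFs and within-window coordinate offsets; gene sets, curation and clinical
tables consistent with the roster. What it does not emulate: read-level
evidence, realistic human SV size spectra, background SV load, linkage
between SVs, caller-specific error modes, or population substructure beyond
two labels. A green end-to-end test therefore establishes that the
*pipeline logic* recovers planted truth under the stated rules — not that
the workflow's sensitivity/specificity on real sequencing data is
reproduced. `perturb()` degrades a bundle in targeted ways (jitter past the
window, per-group genotype masking, site failures, orphan breakends) so the
QC gates can be shown to remove exactly the planted casualties.

# Numerical choices and degenerate inputs

* All threshold comparisons at boundaries are inclusive exactly where the
  definitions require: window ≤ 200, PASS_ratio ≥ 0.5, GQ ≥ 20 kept,
  missingness ≤ 0.2 kept, scores ≥ threshold pass, MAF tiers close
  [0.01, 0.05] into low_frequency. Each boundary has a two-sided test.
* Percentage rounding is half-up (base `round()` is half-to-even and would
  print 12.35 % as 12.3 %).
* Empty inputs are identities: header-only VCFs → empty sets, empty call
  sets → header-only report tables, empty cohorts → zero-row summaries.
* AN = 0 in a group yields NA frequencies (flagged), never 0/0.
* Report generation sorts on stable keys (tier order, then id) and is
  byte-deterministic given identical inputs.
* The CLI config file is JSON (`jsonlite`), round-trip tested; flags
  override config, config overrides defaults.

# Limitations

* Point-breakpoint matching only; no reciprocal-overlap or
  confidence-interval-aware matching, no multi-allelic sites, no nested or
  complex SV reconstruction.
* Fixed diploid model everywhere, including sex chromosomes.
* The curation gate consumes judgments; it cannot resolve a gene whose
  cancer role is genuinely disputed (that is what the cautionary tier is
  for), and tissue-expression evidence is expected to be encoded in the
  curation table, not computed.
* Cohort-scale discovery counts from the reference study depend on
  controlled-access sequencing data and are documentation only; tests
  assert in-table arithmetic and planted-truth recovery, never those
  counts.
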