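---
title: "Scoring phosphosite interaction switches: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phosphosite interaction switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoswitch)
```

## The model

Phosphorylation adds a bulky dianionic group to a serine, threonine or
tyrosine. When the modified side chain sits in a protein–protein
interface, the statistical preferences of its new contacts tell us whether
the modification should help or hurt the interaction. `phosphoswitch`
formalises this in three layers.

**Pair-potentials.** Contacts between residues of different chains
(minimum heavy-atom distance ≤ 5 Å) are tallied over 23 classes — the 20
amino acids plus pS, pT and pY. With pseudocounted counts
$n'(a,b) = n(a,b) + \alpha$ over unordered pairs and
$N' = \sum_{a \le b} n'(a,b)$, the observed frequency is
$f(a,b) = n'(a,b)/N'$, the marginal class frequency is
$g(a) = \sum_b n'(a,b)\,(1 + [a=b]) / (2N')$, and the score is the natural
log-odds against independence,
$s(a,b) = \ln f(a,b) / e(a,b)$ with $e(a,b) = 2\,g(a)\,g(b)$ off the
diagonal and $g(a)^2$ on it. A quasi-chemical potential of this form is
the standard random model for interface statistics; the default
pseudocount $\alpha = 1$ per unordered pair keeps the rare
phospho-involving pairs finite. Scores are symmetric and dimensionless.

**Interaction Effect.** A site mapped onto a template residue with
inter-chain contacts $c$ scores
$\mathrm{IE} = \sum_c \big[ s(\mathrm{p\text{-}aa}, \mathrm{partner}_c) -
s(\mathrm{aa}, \mathrm{partner}_c) \big]$. Across a homodimeric interface
the site is assumed phosphorylated in *both* copies: the mirrored copy
contributes its own contact sum (doubling symmetric contributions), and a
contact between the two copies of the site itself is scored once as the
phospho–phospho minus unmodified–unmodified difference. Contacts are
residue-level edges: several atom pairs between the same two residues
count once.

**The switch score.** $S_\mathrm{switch} = \mathrm{IE} \times f_\mathrm{ID}
\times f_\mathrm{Cons}$, where $f_\mathrm{ID}$ is the minimum fraction of
identical residues between each interacting protein and its structural
template chain (template quality), and $f_\mathrm{Cons}$ is the fraction
of sequences in the protein's orthologue-group alignment carrying the same
amino acid or Asp/Glu at the site column (functional plausibility; Asp and
Glu count because they are natural phosphomimetics). Sites with
$S_\mathrm{switch} \ge 1.7$ are called enabling, $\le -1.7$ disabling
(both inclusive), otherwise neutral.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| contact cutoff | 5.0 | Å | conventional heavy-atom interface contact criterion |
| burial cutoff | < 5.0 | Å² side-chain ASA | strict inequality; 5.0 itself is exposed |
| disorder window / cutoff | 11 / ≥ 0.5 | residues / score | window mean of per-residue disorder, inclusive at 0.5, truncated at termini |
| gap-fraction exclusion | ≥ 0.09 | gaps / member residues | drops poorly aligned members from redundancy grouping |
| switch threshold τ | 1.7 | score units | corresponds to a 5% false positive rate on a benchmark of known switches |
| pseudocount α | 1 | counts / unordered pair | finite scores for rare phospho classes |
| shuffles per positive | 10 | — | negative-set size |
| CV folds / repeats | 5 / 100 | — | balanced logistic-regression evaluation |
| homologous-interface rule | 0.5/0.5/0.5 | fractions | identity, coverage and shared-interface minima |

All of these live in `switch_config()` and every pipeline function takes
them explicitly.

## Numerical choices and degenerate inputs

* **ASA.** Shrake–Rupley with probe 1.4 Å and a deterministic 960-point
  spiral; side chain = CB and beyond; glycine's side-chain ASA is defined
  as 0 (always buried under the < 5 Å² rule — no phosphorylatable residue
  is a glycine, so this only affects background bookkeeping). A residue
  whose side-chain atoms are missing gets an *unset* ASA, never a silent
  zero. Only the highest-occupancy altloc conformer is kept.
* **Contacts** are inclusive at the cutoff and stored once per unordered
  residue pair, ordered deterministically by position.
* **Mapping** transfers positions through alignments even when the aligned
  amino acids differ; a site over a template gap maps to nothing and the
  row is reported as `unmapped`. A mapped residue with no inter-chain
  contact scores IE = 0 and is reported `no-interface`.
* **Aggregation** over alternative templates keeps the maximum
  $|S_\mathrm{switch}|$; ties break by larger $|IE|$, then enabling over
  disabling, then lexicographic template identifier, so a rerun is
  byte-identical. The "most significant template" rule needs *some*
  deterministic tie-break and none is canonical; this cascade is ours.
* **f_Cons denominators** include gapped sequences (and the query itself);
  when no group alignment covers a protein the species average over all
  scored sites is substituted and flagged.
* **Estimation with α = 0** emits −∞ for unobserved pairs with a warning;
  downstream scoring requires α > 0.

## What the synthetic generators emulate

The package is exercised end to end on synthetic fixtures, by design:

* `make_toy_complex()` builds two-chain complexes of idealised
  single-CB pseudo-residues placed so that exactly the requested residue
  pairs are in contact, optionally with planted SEP/TPO/PTR residues.
  This validates contact extraction, phosphoresidue handling, burial and
  the homodimer rule with known ground truth, but contains no real
  side-chain geometry, rotamers or crystallographic noise.
* `make_ortholog_alignment()` draws the site column i.i.d. per sequence
  (wild type with probability $c$, Asp/Glu with $d$, gap with $h$), so the
  expected $f_\mathrm{Cons}$ is $c + d$; columns are otherwise identical —
  there is no phylogenetic correlation or indel process.
* `make_synthetic_benchmark()` plants
  $\mathrm{IE} \sim \mathcal{N}(\pm\,\mathrm{effect},\,1)$ for positives
  (sign = planted direction) and $\mathcal{N}(0,1)$ for negatives, with
  $f_\mathrm{ID} \sim \mathrm{Beta}(8,2)$ and
  $f_\mathrm{Cons} \sim \mathrm{Beta}(5,2)$. The Beta choices reflect that
  usable templates are mostly close homologues and functional
  phosphosites are moderately conserved; they were fixed when the
  generator was written. Effect size 3 at 200 + 200 entries is the
  default evaluation condition.

Passing tests on these fixtures shows the arithmetic, bookkeeping, rules
and statistics are right. It does **not** show that real phosphosites are
predicted with any particular accuracy: real performance depends on
curated site tables, template coverage and orthologue databases that are
deliberately outside this package (inputs are consumed as pre-extracted
TSV/FASTA).

## A note on pair-potential round trips

Sampling contacts from a planted matrix and re-estimating does not return
the raw planted numbers for an arbitrary matrix. The estimator normalises
against the independence model of the *sampled* marginals, so its image is
the family of potentials satisfying
$\sum_{a\le b} e_g(a,b)\, e^{s(a,b)} = 1$ at their own marginals; a matrix
outside that family has no preimage (a uniform shift of $\ln$ of the
normalisation, plus marginal distortion, separates the two). We therefore
sample from $p(a,b) \propto e_0(a,b)\,e^{s(a,b)}$ with fixed marginals and
compare estimates against `calibrate_potential()`, the closed-form implied
log-odds of that target — which is what the estimator provably converges
to. Score *differences* against a fixed partner, the quantity IE consumes,
are preserved by the shift component. At $10^5$ sampled pairs on a
4-class alphabet the maximum deviation is ≈ 0.02; a 23-class alphabet at
the same depth would be dominated by counting noise (≈ 0.05 per score),
which is why the compact alphabet is the round-trip condition.

## Evaluation machinery

Negative benchmark entries are shuffles of each positive to random S/T/Y
positions of the same protein (10 per positive, drawn without replacement,
deterministic under a seed) restricted to the positive's surface-exposure
class, so exposure distributions are preserved exactly whenever eligible
positions exist; the interactor and annotated effect travel with the
shuffle. ROC curves sweep all observed scores (signed mode scores
disabling effects negatively; absolute mode ranks by $|S|$ for
direction-blind detection), AUC is trapezoidal, and the operating point is
the most permissive threshold with FPR ≤ 0.05, with a two-sided Fisher
exact p-value on the resulting 2×2 table. The logistic regression
undersamples negatives to balance, runs 5-fold cross-validation 100 times
with per-repeat derived seeds, pools held-out probabilities per repeat,
and reports means and standard deviations of AUC and the operating-point
statistics plus a final full-data fit — using effect-signed features,
since planted effects of both signs cannot be represented by an unsigned
linear score.

Problem sizes used throughout the tests and the acceptance script —
$10^5$ sampled contacts, $10^6$ product counts for the independence null,
200 + 200 benchmark entries, 100 CV repeats — were chosen as the smallest
sizes at which the statistical assertions have comfortable margins.

## Known limitations

* Contact transfer assumes the template interface geometry holds for the
  query; there is no model building, no conformational rearrangement, no
  steric analysis and no multi-site coupling.
* The potential is residue-level and distance-free; solvation and
  atom-level detail are out of scope.
* mmCIF support is single-model; biological assemblies are handled by
  enumerating chain pairs per assembly file rather than regenerating
  symmetry copies.
* Disorder scores and orthologue groups are consumed, not computed.
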