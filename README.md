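# phosphoswitch

Phosphorylation of a serine, threonine or tyrosine that sits in a
protein–protein interface can act as a switch: the bulky, doubly negative
phosphate group may create new favourable contacts (an **enabling** switch,
strengthening the interaction) or clash with an acidic interface (a
**disabling** switch, weakening it). `phosphoswitch` predicts such switches
from structural templates, for structural bioinformaticians and
phosphoproteomics groups who want to prioritise functional phosphosites.

## The score

Contacting residue pairs observed at interfaces are tallied over 23 residue
classes (the 20 amino acids plus pS, pT, pY) and converted into a
quasi-chemical log-odds **pair-potential**

```
s(a,b) = ln f_obs(a,b) / e(a,b)
```

where `f_obs` is the pseudocounted frequency of the unordered contact pair
and `e(a,b) = 2 g(a) g(b)` (or `g(a)^2` on the diagonal) is its expectation
under independence of the marginal contact frequencies `g`. For a candidate
site mapped onto a template interface, the **Interaction Effect** sums the
change in pair-potential over the site's inter-chain contacts,

```
IE = sum_c [ s(p-aa, partner_c) - s(aa, partner_c) ]
```

with both copies of the site treated as phosphorylated across a homodimeric
interface (doubling symmetric contributions, and scoring the mirrored
self-contact as p–p versus u–u). The switch score weighs IE by two
confidence terms,

```
S_switch = IE × f_ID × f_Cons
```

`f_ID` = minimum fraction of identical residues between each interacting
protein and its template chain; `f_Cons` = fraction of orthologue-group
sequences carrying the site's amino acid (or Asp/Glu) at the site column.
`S_switch ≥ 1.7` calls an enabling switch and `S_switch ≤ −1.7` a disabling
one (a threshold giving a false positive rate of 0.05 on a benchmark of
known switches); anything in between is neutral.

The package also ships the benchmarking machinery: exposure-matched
shuffled negative sets, ROC/PR curves with threshold selection at a bounded
FPR, Fisher's exact significance, balanced cross-validated logistic
regression over (IE, f_ID, f_Cons), and synthetic-fixture generators
(toy complexes, orthologue alignments, planted benchmarks) for every input
format.

## Worked example

A threonine whose template interface places it against two glutamates, on
an identity template, with only 1 of 10 orthologues conserving the site:

```r
library(phosphoswitch)

dir.create(file.path(td <- tempfile(), "structures"), recursive = TRUE)
dir.create(file.path(td, "alignments"))
make_toy_complex(8, list(c(5, 2), c(5, 3)),
                 sequence_a = "AAAATAAA", sequence_b = "AEEAAAAA",
                 path = file.path(td, "structures", "tmpl1.pdb"))
write_pair_potential(
  make_planted_potential(scores = list(list("pT", "E", -3.37))),
  file.path(td, "matrix.tsv"))
write_alignment(c(query = "AAAATAAA", template = "AAAATAAA"),
                file.path(td, "alignments", "QPROT__tmpl1_A.afa"))
write_alignment(c(query = "AEEAAAAA", template = "AEEAAAAA"),
                file.path(td, "alignments", "QPART__tmpl1_B.afa"))
write_alignment(c(QPROT = "AAAATAAA",
                  setNames(rep("AAAAGAAA", 9), paste0("orth", 1:9))),
                file.path(td, "alignments", "group_g1.afa"))

sites <- data.frame(protein = "QPROT", species = "hs", wild_aa = "T",
                    pos = 5, status = "phospho", interactor = "QPART",
                    template = "tmpl1:A:B")
res <- score_sites_pipeline(sites, file.path(td, "structures"),
                            file.path(td, "alignments"),
                            file.path(td, "matrix.tsv"))
res$full[, c("site", "status", "IE", "f_ID", "f_Cons", "S_switch", "label")]
#>   site status    IE f_ID f_Cons S_switch   label
#> 1  T 5 scored -6.74    1    0.1   -0.674 neutral
```

The two acidic contacts give a strongly negative Interaction Effect
(−6.74): phosphorylation would be repelled by this interface. But the site
is poorly conserved (f_Cons = 0.1), so S_switch is only −0.674 (−0.7 at one
decimal) — below the ±1.7 threshold, and the site is left neutral rather
than called a disabling switch.

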