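# ssTEA: subfamily-specific two-entropy analysis of GPCR alignments

Class A G-protein coupled receptors (GPCRs) bind most of their small-molecule
ligands inside the seven-transmembrane (TM) helix bundle. Which residue
positions form the binding site differs between receptor subfamilies, so
family-wide conservation analyses recover the shared pocket but not the
positions a *particular* receptor uses. `ssTEA` implements subfamily-specific
two-entropy analysis for exactly that question: given a gap-free multiple
sequence alignment of the seven TM helices (171 columns in
Ballesteros–Weinstein numbering) and a hierarchical tree over its sequences,
it ranks every TM position by how binding-like its conservation pattern is
for one query receptor. The package is aimed at computational biologists
designing site-directed mutagenesis panels, interpreting receptor pharmacology
or constraining homology models.

## The score

For an alignment column *i* and a subfamily (a tree branch of 50–300
sequences containing the query receptor), two Shannon entropies are computed
over the 20 amino acids:

- *E*<sup>in</sup><sub>i</sub> — entropy over the subfamily members,
- *E*<sup>out</sup><sub>i</sub> — entropy over all sequences outside the
  subfamily,

with *E* = −Σ<sub>a</sub> *p*<sub>a</sub> ln *p*<sub>a</sub> and
*p*<sub>a</sub> the frequency of residue type *a* in the column. A
ligand-binding position is conserved inside the subfamily but variable
outside it, so after normalising both entropies by ln 20 the combined score
is the Euclidean distance to that corner:

&nbsp;&nbsp;&nbsp;&nbsp;*s*<sub>i</sub> = √( *ê*<sup>in</sup><sub>i</sub>² + (1 − *ê*<sup>out</sup><sub>i</sub>)² )

The final score aggregates *s*<sub>i</sub> over every eligible branch *j*
(by default the minimum over branches; a branch-size-weighted mean is the
documented alternative) and positions are ranked ascending — rank 1 is the
most binding-like. Rankings are evaluated with the semi-logarithmic ROC
area, pROC AUC = (1/*n*) Σ<sub>i</sub> log10(1/β<sub>i</sub>), where
β<sub>i</sub> is the fraction of false positives ranked above the *i*-th
true residue (clamped below at 1/*n*<sub>false</sub>): random ranking gives
1/ln 10 ≈ 0.434, and a perfect ordering ahead of 100 false positives gives
exactly 2.0.

Around the score the package provides the full supporting pipeline:
per-helix gap-free log-odds profiles with 95%-failure threshold calibration
and helix-order repair (`alignSequences()`), species-level deduplication and
filtering, p-distance/neighbor-joining subfamily trees (`buildNJTree()`),
curated reference sets of ligand-binding positions for ten receptors
(`referenceSets()`), benchmark baselines, and a synthetic-alignment
generator (`simulateMSA()`) for testing every stage without downloads.

## Worked example

Score a receptor in a synthetic benchmark alignment (10 subfamilies of 60
sequences; 5 binding columns conserved per subfamily at conservation 0.95;
10 globally conserved structural columns):

```r
library(ssTEA)

sim    <- simulateMSA(syntheticSpec(seed = 7))
tree   <- buildNJTree(pDistanceMatrix(sim$alignment))
scores <- scoreReceptor(sim$alignment, tree, "sf01_r001")
scores
#> ResidueScoreTable for receptor sf01_r001
#>   branches (sizes): 59, 108, 158, 231, 244
#>   aggregate: min | corner: theoretical
#>   top 5 positions: 7.39, 3.33, 6.55, 3.32, 5.42

head(residueScores(scores)[order(residueScores(scores)$rank), ], 7)
#>     position     score rank
#> 154     7.39 0.2374082    1
#> 59      3.33 0.2581804    2
#> 144     6.55 0.2871469    3
#> 58      3.32 0.3410486    4
#> 104     5.42 0.4124310    5
#> 165     7.50 0.8604946    6
#> 164     7.49 0.8607999    7
```

The five planted binding columns (3.32, 3.33, 5.42, 6.55, 7.39) take ranks
1–5 with scores near the conserved-inside/variable-outside corner, followed
by the globally conserved structural anchors (7.49, 7.50, ...) whose low
outside entropy pushes them away from the corner. Evaluating the ranking
against the planted truth:

```r
truth <- sim$truth$columns
procAUC(scoreRanking(scores), truth$position[truth$role == "binding"])
#> pROC AUC: 2.22 ( 5 true among 166 false )
```

2.22 = log10(166) is the maximum attainable here, i.e. perfect early
recovery.

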