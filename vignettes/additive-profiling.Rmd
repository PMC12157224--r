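---
title: "Profiling polymer additives: descriptors, similarity, clustering and risk flags"
author: "addsim maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling polymer additives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addsim)
```

## The problem

Additives — antioxidants, UV stabilizers, quenchers, photoinitiators —
determine how long a polymer survives heat, oxygen and sunlight, and they
are also the part of a plastic most likely to leach into the environment.
`addsim` profiles a set of additives from nothing but their 2D structures:
it computes a structural census and physico-chemical descriptors, quantifies
pairwise structural similarity two independent ways, groups the compounds by
clustering with explicit validity and stability assessment, and flags likely
environmental risks from lipophilicity (LogP) and polar surface area (TPSA).
The package ships the 24-compound study set it was built around (identified
by PubChem CID, structures encoded from their chemical names) plus seeded
synthetic generators, so the whole pipeline is testable offline.

## The molecular graph and its census

A `Molecule` is an attributed graph: atoms carry element, formal charge,
implicit hydrogen count and an aromatic flag; bonds carry one of four order
classes (single, double, triple, aromatic). Salts and co-crystals are one
`Molecule` with several connected components — zinc stearate is a Zn(2+)
ion plus two stearate anions, and the census aggregates components into one
sum formula. Structures come in as SMILES (organic subset, bracket atoms
with charge and explicit H, ring closures, branches, dot-separated
components; stereo markers parsed and discarded — everything downstream is
2D and stereo-blind) or as SDF V2000, where aromatic bonds use bond type 4
so a write/parse round trip never needs kekulization. For Kekulé input,
`normalizeAromaticity()` applies a per-ring Hückel 4n+2 count over an SSSR
basis (shortest cycle through each edge, completed by BFS fundamental
cycles, greedily reduced over GF(2) to the cycle-space dimension
bonds − atoms + components).

The census counts twelve functional-group classes. Each oxygen or nitrogen
belongs to at most one class, with precedence ester > acid >
ketone/aldehyde > ether > alcohol, so an ester's two oxygens are never also
counted as ether plus carbonyl. Metal carboxylates count as RCOOH — the
convention that matches the printed characterization of zinc stearate.
Molecular weights use the IUPAC 2005 conventional atomic weights (e.g. Zn
65.409), the vintage consistent with the study set's printed weights, and
are rounded to two decimals only at serialization.

## Descriptors

**TPSA.** Topological polar surface area is the sum of Ertl fragment
contributions over polar-atom environments, keyed by element, charge,
attached hydrogens, bond-order multiset, aromaticity and three-ring
membership; the table ships as plain text under `extdata`. The package
includes the extended divalent-sulfur and trivalent-phosphorus
contributions by default (`includeSP = TRUE`): the study set's printed
values for its thioesters (77.90 Å², of which 25.30 Å² is the S term) and
phosphites (13.59 Å² per P) are reproducible only with them. The original
N/O-only sum is available with `includeSP = FALSE`. Unknown polar
environments contribute 0 with a warning rather than failing.

**LogP and MR.** Lipophilicity and molar refractivity use a condensed
Wildman–Crippen atomic-contribution scheme: a graph-pattern typing (no
SMARTS engine) covering the carbon, heteroatom and hydrogen environments
that occur in polymer additives, with the published contribution values for
those types shipped as data. On the study set this agrees with a reference
Wildman–Crippen implementation to print precision for 24/24 structures, but
LogP/MR remain convention-dependent quantities: they drive the risk
classification and are not meant to replicate any particular engine's
output digit for digit. The study's printed HBA/LogP/MR columns are carried
as `ref.*` reference metadata.

**HBD/HBA.** Donors are N/O atoms bearing at least one hydrogen (each group
counted once). Acceptors follow the Lipinski-style N+O count, excluding
pyrrole-type aromatic nitrogens (three in-plane bonds or aromatic N–H,
whose lone pair is part of the π system) and amide N–H nitrogens. The
study's printed HBA column follows an undocumented convention far from any
N+O count and is deliberately not reproduced.

## Similarity

**Atom pairs (fingerprint route).** Heavy atoms are typed by (element,
heavy-atom degree, π-electron count); every pair of heavy atoms in the same
component contributes one descriptor together with its shortest-path bond
distance. The fingerprint is a *counted* multiset, and similarity is

$$TC = \frac{c}{m_1 + m_2 - c},$$

with $m_1, m_2$ the fingerprint sizes and $c$ the min-count intersection.
The counted convention is deliberate: it is what reproduces published
atom-pair Tanimoto tables for this compound family (a set-semantics
variant inflates, e.g., 0.76 to 0.89 for the pair of methoxy/dihydroxy
benzophenones).

**Maximum common substructure (graph route).** `mcs()` searches for the
largest *connected, induced* common subgraph of two heavy-atom graphs,
matching atoms by element and bonds by order class (aromatic matches only
aromatic at zero budget). The search is branch-and-bound over pair
extensions: seeds in index order, fail-first frontier-vertex selection, an
upper bound from unmapped vertices, and early exit when the smaller
molecule is fully embedded. Budgets `au`/`bu` allow a bounded number of
atom- or bond-label mismatches ("flexible" matching); presence/absence of a
bond must always agree, which keeps the match induced. A wall-clock
`timeout` returns the best mapping found with `exhausted = FALSE` — never
an exception — so batch matrices always complete. Results are
deterministic and order-symmetric; an exhaustive enumerator
(`oracleMcs()`) certifies exactness on small molecules in the test suite.

From an `MCSResult` with common size $c$ and heavy-atom counts $a, b$:

$$OC = \frac{c}{\min(a, b)}, \qquad TC_{MCS} = \frac{c}{a + b - c},$$

so $OC = 1$ means the smaller molecule embeds completely, and
$TC_{MCS} \le OC$ always.

```{r mcs-example, eval = FALSE}
mols <- studyMolecules()
r <- mcs(mols[["4632"]], mols[["8572"]])   # two benzophenone UV absorbers
r                                          # c = 16, OC = 1.00, TC = 0.94
```

## Clustering and validation

Similarity becomes distance as $d = 1 - s$. The pipeline default clusters
the **overlap-coefficient** matrix: on the study set this reproduces the
published four-group partition exactly (benzophenones; thioesters with the
zinc and HALS stabilizers; chlorinated/benzotriazole UV absorbers; the
hindered-phenol antioxidants), whereas the $1 - TC_{MCS}$ transform
separates the HALS/succinate salt prematurely. $TC$-based distances remain
available (`pipelineConfig(distance = "tc")`).

Agglomeration uses the standard Lance–Williams implementations behind
`hcluster()` (single, average, complete, ward.D2 — the latter on squared
distances with square-rooted heights). The linkage is chosen by cophenetic
correlation, the Pearson correlation between input and dendrogram
distances. `cutK()` renumbers labels in first-occurrence order so
labellings are machine-independent.

Three internal indices (connectivity with an L = 10 neighborhood, Dunn,
mean silhouette) and four column-deletion stability indices (APN, AD, ADM,
FOM, each averaged over single-column deletions) score every candidate k;
`selectK()` applies the majority principle over the per-measure best-k
votes, retaining ties. The stability indices need a feature matrix; when
only a distance matrix exists, its classical-MDS embedding (dimension
min(n − 1, 10)) stands in, which is an approximation worth remembering when
the distances are strongly non-Euclidean.

Bootstrap stability resamples observations with replacement B = 100 times
(seeded), reclusters the induced sub-matrix, and matches every original
cluster to its best-Jaccard bootstrap counterpart over the resampled
universe. The mean of those maxima (AvgJ) grades clusters as unstable
(< 0.65), stable, or highly stable (> 0.85). The study speaks of cluster
"instability" without defining it, and its printed instabilities are not
1 − AvgJ; here the dissolution rate — the fraction of resamples whose best
Jaccard falls below 0.5 — is reported under that name, a documented choice.

Binning clustering is the simple alternative: single-linkage components at
fixed cutoffs, each cutoff interpreted as a fraction of the maximum
pairwise distance (the source analysis used a cutoff vector without
defining its units; this reading makes cutoffs dimensionless and
comparable across feature sets). Feature input is z-scored before
Euclidean distances.

## Risk flags

Two screening axes with fixed boundaries (closed/half-open choices are the
package's, since the verbal rules leave exact boundary values open):

| LogP | class | TPSA (Å²) | class |
|------|-------|-----------|-------|
| > 5 | high_bioaccumulation | > 140 | reduced_systemic |
| (3, 5] | borderline | (75, 140] | higher_safety |
| [1, 3] | mild | [60, 75] | borderline |
| < 1 | low_lipophilicity | < 60 | concern |

The joint flag is `hazard` iff LogP > 5 and TPSA < 75 (lipophilic and
membrane-permeable), `investigate` in the two adjacent screening bands
(LogP > 5 with TPSA in [75, 83] — the verbal rule says "77–83 Å", leaving
(75, 77) unaddressed, widened here to the class boundary — or LogP in
(3, 5] with TPSA < 60), and `low_risk` otherwise; very polar compounds
(TPSA > 140) end up unflagged regardless of LogP because they fail the
permeability condition. Applied to the study's printed descriptor table,
these rules reproduce its flagged, follow-up and low-risk example lists;
the two compounds those lists omit fall out of the same rules as
`investigate` (the long-chain thioester, TPSA 77.90) and `low_risk` (the
HALS/succinate salt).

## The synthetic generators, and what passing tests do not show

`randomMolecule()` grows seeded, valence-correct connected graphs;
`plantedMcsPair()` shares an identical core between two molecules and
decorates them with element-disjoint halogens, making the core the unique
maximal common subgraph; `gaussianFeatureMatrix()` places k cluster centers
on a regular simplex at a chosen mutual distance with isotropic noise. All
generators are pure functions of their integer seed through R's
Mersenne-Twister stream. Recovery simulations use 3 clusters of 20
observations at 6σ center separation — the size at which a single
misassigned point still scores above the ARI 0.9 threshold, so the
criterion counts genuine recovery failures rather than label granularity —
and 100 seeds per condition.

These generators emulate graph structure and cluster geometry, not
chemistry: random molecules are not synthesizable compounds, their element
frequencies are arbitrary, and Gaussian clusters are far cleaner than
descriptor-space data. Passing the property suites therefore certifies the
*algorithms* (exact MCS, correct index formulas, stable seeds), not that
real additive families will cluster as crisply.

## Known limitations

* Two study compounds are shipped as curated stand-ins: the printed names
  conflict with the printed formulas, and the structures used here (a
  two-component butylated-hydroxyanisole isomer record; a
  phenol-triazine UV absorber) are the ones consistent with every printed
  property. They are marked `requires_lookup` in the fixture table.
* The zinc stearate fixture is the real salt; printed TPSA/HBD for that
  compound correspond to a neutral di-acid reading and differ accordingly.
* The SMILES subset requires explicit `-` for biaryl single bonds, and the
  SDF reader folds explicit hydrogens rather than preserving them.
* MCS on large, repetitive molecules can hit its per-pair timeout when a
  full embedding does not exist; the returned size is then a lower bound,
  flagged by `exhausted = FALSE`.
* The cophenetic ranking of linkages depends on the similarity matrix; on
  the reconstructed study matrix ward.D2 beats single and complete but not
  average linkage, and the package selects the maximum rather than
  hard-coding a linkage.
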