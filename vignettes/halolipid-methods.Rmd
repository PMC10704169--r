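---
title: "Methods: in-silico archaeal lipid libraries, annotation, networking and chemotaxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico archaeal lipid libraries, annotation, networking and chemotaxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halolipid)
```

# Scope

`halolipid` implements an untargeted lipidomics workflow for halophilic
archaea: a rule-based in-silico MS² library of archaeal ether lipids,
tolerance-based annotation of aligned LC-MS features, core-lipid chain
accounting, feature-based molecular networking, and chemotaxonomic
clustering compared against a 16S rRNA neighbor-joining phylogeny. A
seeded generator emulating a seven-strain culture design (three orders of
the class *Halobacteria*, triplicate cultures, extraction blanks) makes
every stage testable without instrument data.

# The in-silico spectral library

## Species enumeration

Archaeal core lipids are modelled as 2,3-di-O-alkyl glycerol diethers with
two isoprenoid chains of 20 or 25 carbons: archaeol (AR, C20/C20),
extended archaeol (Ext-AR, C20/C25) and di-extended archaeol (diExt-AR,
C25/C25). Compositions follow condensation bookkeeping: every ether
linkage and every core-head junction removes one H₂O; sulfation adds SO₃
without water loss. This reproduces archaeol as C43H88O3 from glycerol
plus two phytanols minus two waters. Unsaturation is handled purely at the
composition level (−H₂ per double bond, 0–8 per core); double-bond
positions are not modelled because CID spectra of these lipids do not
localise them.

Intact polar lipids attach one head group per core (phosphatidylglycerol
PG, methylated PG-phosphate Me-PGP, PGS, PA, PE, PI, Gly-PG, the glycosyl
series MGD/DGD/TGD, their mono- and bis-sulfated forms, and the
glycosyl-aminohexanehexaol lipids S-Gly-AHH/2S-Gly-AHH); archaeal
cardiolipins (BPG and the glyco-phosphatidic acid series MGD-PA, DGD-PA,
TGD-PA, S-DGD-PA) bridge two identical cores. Menaquinones are modelled
as MK with 8 isoprene units and 1–8 side-chain double bonds (MK 8:8 fully
unsaturated); bacterioruberin as a C50 carotenoid tetrol with anhydro
variants. The exact masses obey ladder identities used as tests:
−2.01565 Da per double bond, +70.07825 Da (C₅H₁₀) per chain extension,
+79.95682 Da (SO₃) per sulfation, +162.05282 Da (C₆H₁₀O₅) per hexose.

The default configuration enumerates AR and Ext-AR cores over 0–8 double
bonds for every diether class, eight menaquinones and four
bacterioruberins (390 species, 780 spectra over two adducts). diExt-AR is
enumerable but disabled by default, reflecting its absence from cultured
Halobacteria; requesting a (25,25) chain pair without enabling it is an
error rather than a silent drop.

## Fragmentation rules

Fragment prediction is driven by an editable TSV of rules (head-group
neutral losses, hexose loss, SO₃ loss, phytanyl chain loss, ammonia loss
from ammonium adducts, class-diagnostic head-group ions, and the
sodium-adduct intact unsaturated chain loss). The shipped defaults are
reconstructions from published fragmentation behaviour of archaeal
lipids, not measured reference spectra, and are deliberately overridable.
Two rules deserve comment:

* The PI head-group ion is shipped as a fixed diagnostic m/z (261.038)
  rather than a composition, because the identity of that fragment is
  asserted from its mass only; an accepted PI match lacking the ion is
  flagged *tentative* rather than rejected.
* Sodium-adduct spectra are generated only for unsaturated diether
  species — saturated archaeal lipids largely resist CID under Na⁺ — and
  `[M+Na]⁺` is excluded from the default annotation adduct set; the rule
  exists so that networking can recognise the sequential losses of the
  two intact unsaturated chains (C_nH_{2n−2u} alkenes, the double bonds
  split across the chains with chain 1 taking the larger share).

Head-group diagnostic ions (sulfohexose at the mass of C6H10O8S + H,
aminohexanehexaol-glycoside at C6H13NO5 + H, phosphoethanolamine at
C2H6NO3P + H, hexose oxocarbenium) are included because several head
groups are exactly isobaric at the precursor level — the
glycosyl-aminohexanehexaol head equals its glycosyl counterpart plus NH₃,
which makes an [M+H]⁺ of one class coincide with the [M+NH₄]⁺ of the
other. Precursor mass alone cannot separate these; the head-group ions
can, and without them annotation would have to fall back on arbitrary
tie-breaking.

## Mass conventions

Two charge-carrier conventions are supported: `proton` (true carrier ion
masses, electron included) and `hydrogen_atom` (neutral atom masses,
electron neglected), the convention under which the leucine enkephalin
lock mass prints as 556.2771. The library default is `proton`; the two
differ by ~0.55 mDa, well inside the 10 mDa annotation tolerance.

# Feature processing and annotation

Input is an aligned feature table (feature id, m/z, RT, one intensity
column per sample) with MS² spectra in MGF and sample roles
(sample/blank/qc) in a separate TSV — the shape of a peak-alignment
export. Peak detection itself (centroiding, chromatogram tracing, the
0.1 Da mass slice width) is out of scope and retained only as
configuration metadata.

* **RT correction** fits a piecewise-linear map through internal-standard
  anchors (constant shift with a single standard); anchors deviating more
  than 0.8 min from their expected RT are excluded with a warning.
* **Blank filtering** keeps a feature when max(sample) ≥ 10 ×
  max(blank). The boundary is kept: the rule removes features *lower*
  than ten-fold of the blank, so a ratio of exactly 10 survives. Max (not
  mean) aggregation on both sides is the conservative reading.
* **Annotation** considers library entries within 0.01 Da of the feature
  m/z and scores each as 100 × the unweighted mean of four components:
  a Gaussian MS1 similarity exp(−½(Δm/σ)²) with σ = tol/2, dot product
  and reverse dot product on square-root intensities (greedy nearest-m/z
  matching at 0.05 Da, each peak used once), and the matched fraction of
  library peaks. The exact scoring formula of alignment software is not
  published at this granularity; this unweighted mean reproduces the
  intended accept/reject behaviour at the 70% total-score threshold
  (identical spectra score 100, fragment-free matches fall well below
  70). Ties break on smaller MS1 error, then species name. A curation
  list (feature ids) lets the analyst reject annotations by hand, since
  the manual rules that curate raw annotations down to a final set are
  inherently dataset-specific.
* **Semi-quantification** divides intensities by the spiked C19-PC
  internal standard per sample; response factors are fixed at 1 because
  compound-specific standards are unavailable for most archaeal lipids.
* **Unique lipids** collapse accepted annotations over adduct forms
  ([M+H]⁺, [M+NH₄]⁺) and RT isomers; per-sample intensities are summed.

# Core-lipid chain accounting

Every diether-bearing lipid contributes its abundance to the core it is
built on; cardiolipins carry two cores and contribute with weight 2 (the
accounting is per core, and each cardiolipin molecule contains two).
Menaquinone and bacterioruberin are excluded. Percentages (unsaturated
fraction, C25 chain fraction, low/poly unsaturation split at 4 double
bonds) are weighted by semi-quantified abundance, not feature count — the
alternative weighting is not distinguishable from the outputs alone, and
abundance weighting is what the aggregated profile supports. Under the
no-diExt-AR assumption each Ext-AR molecule carries exactly one C25 chain
out of two, so the molecule-level Ext-AR percentage is exactly twice the
chain-level C25 percentage; a chain fraction above 50% would contradict
the assumption and is an error.

# Molecular networking

Spectra are filtered by removing fragments within 17 Da of the precursor
and keeping peaks ranking in the top 6 by intensity inside a sliding
±25 Da window centred on each peak (the common implementation of a
"50 Da window"; fixed bins are a configurable alternative). The modified
cosine allows fragment matches either direct (|Δm/z| ≤ 0.05) or shifted
by the signed precursor mass difference; both compete in a single optimal
one-to-one assignment maximising the sum of square-root intensity
products, found exactly by branch-and-bound (filtered spectra are small,
so exact assignment is affordable and is verified against an exhaustive
oracle in the tests). Edges require cosine strictly above 0.7 *and* at
least 6 matched peaks. Filtration order follows the stated procedure:
blank-involved nodes and nodes below m/z 500 first (exactly 500 is
kept), then components below 4 nodes (exactly 4 is kept). No per-node
edge cap is applied because none is stated. Components are categorised by
the majority annotated class, or as "taxon-dominant unknown" when one
taxon contributes more than half of the node occurrences of an
all-unknown component; a manual override file can replace labels, since
the reference categorisation was a manual step.

# Chemotaxonomy and phylogeny

For clustering, abundances are log10-transformed and z-scored within each
sample; for ordination, normalised by column sum then log10-transformed.
Zeros are replaced by half the smallest positive value of the matrix
before the log — a standard pseudo-count that preserves presence/absence
contrast. Replicates are averaged (arithmetic mean) before strain-level
clustering. The clustering distance is Euclidean on the scaled values
(the default of the common heatmap tools; configurable), and "Ward"
means the classical Ward criterion on Euclidean distances (`ward.D`).
Constant columns under scaling fall back to sd = 1 with a warning rather
than erroring, so degenerate fixtures remain analysable.

PCA is a column-centred eigendecomposition. PLS-DA uses NIPALS with two
latent variables (the ordination-tool default) on per-feature autoscaled
data; VIP_j = sqrt(p · Σ_a w²_ja SSY_a / Σ_a SSY_a), which guarantees
mean(VIP²) = 1. VIP ranking is computed on replicate-level samples so
every class has several observations; both feature-level and
grouped-lipid inputs are supported because the reference analysis is
ambiguous about which it used.

Phylogeny: p-distances with pairwise deletion on a pre-aligned FASTA
(alignment itself is out of scope), Saitou–Nei neighbor joining with
negative branch lengths clamped to zero, and column-resampling bootstrap
whose supports are invariant to taxon input order (taxa are sorted by
label before resampling). Concordance between a dendrogram and the
phylogeny is reported as the adjusted Rand index of the k-cut partition
against reference order labels (ARI of a single cluster is 0 by
convention) plus the Robinson–Foulds distance on unrooted topologies.

# The synthetic-data generator

The generator emulates the seven-strain design: per-class presence tiers
(major / trace / absent) following the strains' reported lipid profiles
(e.g. TGD-PA only in *Haloarcula argentinensis*, bis-sulfated glycolipids
only in *Haloterrigena turkmenica* and *Natrialba asiatica*,
bacterioruberin absent from *Na. asiatica*, MK/archaeol/Me-PGP/PG
universal), and per-strain unsaturation and C25-chain parameters set to
the printed strain values where stated and to mid-range values inside
the printed ranges otherwise. Because tiers are reported as star levels
without quantitative definitions, "major" draws a log-normal abundance
(σ = 0.3) and "trace" is 1/50 of it — a free choice, documented here.
Class abundance is spread over representative core variants (saturated,
2 and 5 double bonds, extended) with weights that reproduce the strain's
unsaturation and chain fractions exactly before noise, which is what
makes the chain-accounting recovery test sharp (±1 percentage point at
default noise).

Each emitted lipid yields an [M+H]⁺ feature and, for classes drawn as
ammonium-adduct formers (probability 0.6 per class — adduct propensity is
head-group chemistry, and deciding it per class keeps within-class
core-variant ratios intact when adducts are summed), an [M+NH₄]⁺
feature. Measurement noise is an m/z jitter of σ = 0.005 Da per
observation — the consensus feature m/z averages over the samples in
which the feature is detected, as alignment software does — and 10%
log-normal intensity noise. MS² spectra are the predicted library spectra
plus a deterministic six-peak class "fingerprint" (standing in for real
backbone fragments the rule library does not model; it also gives
same-class spectra enough shared peaks to link in the network) plus
random noise peaks. Unknown analogs are CH₂-shifted homologs of a
strain's major classes whose precursor is pushed away from every library
precursor, so they must be recovered by networking, not annotation.
Sodium-adduct features of unsaturated PG-family lipids exercise the
chain-loss rule as network-only unknowns. Blanks contain only
contaminants; half of the contaminants also bleed into samples below the
10× threshold to exercise the filter. The toy 16S alignment mutates an
ancestral random sequence along the order topology (5% to order
ancestors, 1.2% to strains), giving within-order distances strictly
below between-order distances.

What the generator does **not** emulate: chromatographic peak shapes,
isotopologue envelopes, in-source fragmentation, RT structure beyond a
uniform draw, ionisation suppression, or compound-specific response
factors. Passing tests therefore demonstrate the correctness of the
computational pipeline under the stated statistical structure, not
instrument-level performance on real extracts.

# Problem sizes and numerical choices

The default test and pipeline runs use the full 390-species library
(780 spectra), about 160 aligned features over 21 culture samples and 2
blanks, bootstrap sizes of 100 on toy alignments, and exhaustive-oracle
checks on spectra of up to 8 peaks; a full synthetic pipeline run
completes in well under a minute. Peak merging inside predicted spectra
uses a 10⁻⁴ Da window keeping the larger intensity; MSP round-trips are
exact at the printed precision (4 decimals m/z, 1 decimal intensity).

# Known limitations

* Fragmentation rules are literature-informed reconstructions; absolute
  intensities are nominal and should be recalibrated against measured
  spectra before use on real data.
* The Gly-AHH head-group composition is a reconstruction consistent with
  the reported sulfated-head mass; its exact structure is unresolved.
* The annotation score is one defensible formalisation of a
  multi-component similarity; scores are comparable within this package,
  not across software.
* NJ and bootstrap wrap standard phylogenetic routines; very short
  alignments with conflicting sites will show the usual NJ instabilities.
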