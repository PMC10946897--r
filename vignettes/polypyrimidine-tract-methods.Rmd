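---
title: "Models and methods for polypyrimidine-tract evolution in short introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for polypyrimidine-tract evolution in short introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pptract)
```

## The biological question

Short spliceosomal introns carry their splicing information internally.
Three *cis* elements matter here: the 5' donor signal, the branch point,
and the 3' acceptor signal whose core is the near-invariant terminal
dimer AG.  The acceptor AG is found by scanning 5'-to-3' from the branch
point, so an AG arising *inside* the polypyrimidine tract (3PT) — the
pyrimidine-rich stretch just upstream of the acceptor — can trigger
premature splicing.  Purifying selection should therefore deplete AG and
AG-containing motifs from the 3PT, over and above any direct preference
for pyrimidines exerted by tract-binding splicing factors.  `pptract`
implements the full chain of analyses needed to detect, quantify and
model that selection, using the 5' loop region (5LR) between donor
signal and branch point as a neutral reference.

## Region definitions

Within introns of 45–75 bp (transcript orientation):

* **5LR**: intron positions 8–30, a 23-base window.  In *Drosophila*
  short introns this stretch shows an AT:GC ratio of about 2:1,
  consistent with mutation bias alone, and is the standard neutral
  reference of the field.
* **3PT**: the 10 bases ending 4 bases before the intron's 3' end
  (positions length−13 … length−4).  The last four bases are excluded
  because they belong to the acceptor signal itself.
* **junction3**: 8 bases straddling the 3' junction (4 intronic + 4
  exonic), used for positional profiles across the splice site.

The upper length bound of 75 bp marks where the neutral composition of
positions 8–30 gives way to GC enrichment in real data.  No lower bound
is dictated by the biology; we use 45 bp, the smallest length at which
the 5LR (ending at 30) and the 3PT (starting at length−13 ≥ 32) are
disjoint, so no site is counted in both regions.  Both bounds are
arguments of `classify_short()`.

Windows are cut from oriented intron alignments (`load_introns()`
reverse-complements minus-strand features exactly once) and filtered by
`filter_regions()`: any overlap of the genomic footprint with annotated
coding sequence, any N in any individual, or any truncation drops the
window, with every drop logged by reason.  The exonic half of
`junction3` is coding by construction, so that label is exempt from the
CDS filter — applying it would discard every junction window.
Consensus sequences and position-weight matrices are built per window;
consensus ties are broken deterministically in the fixed order
A < C < G < T and flagged, while the PWM retains the full information.

## Strand asymmetry and equivalence testing

Under strand-symmetric evolution a motif and its reverse complement are
equally frequent on one strand (Chargaff's second parity rule).  For
each k-mer M (k ≤ 4) we compute the asymmetry score

$$S(M) = \frac{N_F - N_R}{N_F + N_R},$$

where $N_F$ counts M and $N_R$ its reverse complement in the region's
consensus sequences.  $S$ is antisymmetric under reverse
complementation and identically zero for self-complementary motifs.
Mononucleotide scores $S_{TA}$ and $S_{CG}$ use (T, A) and (C, G).

Two complementary tests probe symmetry: a 1-df chi-square test of
$N_F = N_R$, and a ratio-equivalence test that concludes *practical*
symmetry when the Katz log-scale confidence interval of $N_F/N_R$ lies
inside a tolerance band $(1/\delta, \delta)$.  We default to the
stringent $\delta = 1.1$ and, since the interval's confidence level is
a free choice, to the two-sided 95% quantile $z = 1.959964$.  Raw
p-values are reported; a Benjamini–Hochberg column is optional, since
ordered raw p-values are what the field usually inspects for this
analysis.

The composition-expected score of a motif uses the region-wide base
composition under an independence model.  A per-position variant would
be possible but mixes the positional trend into the expectation; we
keep the region-wide version and expose the positional structure
separately through `per_position_profile()`, which regresses the
per-column scores on position.

## Per-motif selection coefficients

Selection on a motif is quantified as the log-odds of its proportion in
the 3PT against the 5LR:

$$\gamma(M) = \log\frac{f_3(M)/(1-f_3(M))}{f_5(M)/(1-f_5(M))},$$

interpreted as the scaled strength $4 N_e s$.  Because both regions sit
in the same transcripts, non-selective forces (mutation bias,
transcription-associated mutation bias, gBGC) cancel to first order.
$f(M)$ is the motif's share of all k-mer windows in the region.
Zero-count motifs (possible for tetramers) are handled by a
Haldane–Anscombe pseudocount: 0.5 added to every motif count with the
total adjusted, so the log-odds is always finite.  Confidence intervals
come from resampling *introns* (not sites) with replacement, 1000
times by default, independently in the two region sets because
filtering leaves different intron lists; percentile 2.5%/97.5% bounds
are reported and are bit-reproducible under a fixed seed.

## GC-biased gene conversion from site-frequency spectra

Biallelic sites are classified as GC-changing (weak/strong pairs) or
GC-conservative (A/T and G/C pairs); only the former feel gBGC, so the
conservative class is the built-in neutral control.  For a sample of n
haplotypes the probability that a segregating site shows y copies of
the strong allele is modelled as

$$p_y \propto \beta\,\varphi(y; n, B) + (1-\beta)\,\varphi(n-y; n, -B),$$

where $\varphi$ is the binomially sampled diffusion sojourn density
under a directional force and $\beta$ is the fraction of polymorphisms
of weak-to-strong origin.  $\varphi$ is evaluated by adaptive
quadrature with the analytic $1/y$ limit taken at $B = 0$; the
quadrature is validated against Monte-Carlo integration in the test
suite.  The exact published estimator this emulates lives in a cited
reference we do not reproduce verbatim; we adopt the standard
sojourn-density form and validate by parameter recovery instead.

Two properties of this model deserve emphasis:

* **Orientation convention.** For conservative sites the focal allele
  is T (A/T pairs) or C (G/C pairs).  The choice is arbitrary but
  fixed, and at $B = 0$ the expectation is orientation-robust by the
  mirror symmetry $p_y(B, \beta) = p_{n-y}(-B, 1-\beta)$.
* **Identifiability.** At $\beta = 1/2$ the two origin classes cancel
  *exactly* and the spectrum equals the neutral one for every B, so B
  is unidentifiable there.  This is a property of unpolarized spectra,
  not an implementation artifact.  All simulation-based checks
  therefore use $\beta = 2/3$, a realistic weak-to-strong excess under
  AT-biased mutation.  Even there the information is modest: at n = 20
  and $5 \times 10^4$ segregating sites the profile curvature gives a
  standard error near 0.2 for $\hat B$.  Recovery checks in the test
  suite therefore assess the mean of $\hat B$ over independent replicate
  spectra of that size rather than a single draw, and detection of
  $B \neq 0$ combines the per-replicate likelihood-ratio tests.
  Estimators that additionally use monomorphic-site counts can be
  sharper, but fall outside a spectrum-only interface.

`estimate_B()` maximises the multinomial likelihood over $(B, \beta)$
with multi-start L-BFGS-B; `lrt_vs_zero()` compares against the nested
$B = 0$ profile (1 df).  `lrt_pooled_vs_separate()` tests homogeneity
of B across two datasets (e.g. autosomes vs X): the null shares B but
keeps $\beta$ free per dataset, so the statistic has 1 df; spectra of
unequal n are first projected down by expected hypergeometric
downsampling.

## The context-dependent mutation–selection model

Substitutions follow an origin-fixation process: neutral mutation rate
$\mu_{ij}$ times the relative fixation rate
$r(\gamma) = \gamma / (1 - e^{-\gamma})$ of the fitness difference
(with $r(0) = 1$; the implementation is overflow-safe and satisfies
$r(\gamma)/r(-\gamma) = e^\gamma$ to machine precision).  The neutral
matrix is strand-symmetric — six free exchange rates — and is estimated
from 5LR polymorphism: biallelic sites are pooled by
reverse-complement-merged pair class, divided by the originating base
frequencies, and each weak/strong class is split into its two
directions by per-class flux balance, which makes the observed
(complement-averaged) composition stationary.  The time scale is not
identifiable from stationary data, so the matrix is normalised to unit
substitution flow.

Selection has two layers: monomer coefficients
$(\gamma_A, \gamma_T, \gamma_G, \gamma_C)$ constrained to sum to zero
(only differences matter; the constructor projects), and one dimer
coefficient $\gamma_{AG}$ that applies whenever a base completes an AG
with a neighbour — an A before a focal G, or a focal A before a G.  We
implement this through a per-base fitness vector given the neighbours;
rate differences of that fitness reproduce the conditional column/row
modifications and handle the doubly conditioned case (A on the left
*and* G on the right) consistently.

### Likelihood construction

The data per tract position i are the 4×4 joint counts of bases at
(i, i+1).  The full 10-site process has longer-range context than any
closed-form likelihood, so a closure is needed; this was the one
genuinely open design choice.  We model each adjacent pair as a
two-site continuous-time chain — site 1 evolving with right-neighbour
context from site 2, site 2 with left-neighbour context from site 1 —
and take the multinomial likelihood of the counts under its stationary
distribution (`pair_stationary()`, a 16-state solve).  This closure is
exact under neutrality and under monomer-only selection (where the
distribution factorises into the single-site laws), and its adequacy
under dimer selection is demonstrated against the full circular
simulator in the test suite rather than assumed.  Boundary positions
receive no special treatment: position pairs (1,2) … (9,10) are fitted
with the same two-site model.

Three hypotheses are fitted by maximum likelihood: HI monomer selection
only (3 free parameters), HII AG-dimer only (1), HIII both (4).
Optimisation is multi-start L-BFGS-B (zero start plus displaced
starts) on the box [−10, 10] per free parameter, the sum-zero
constraint handled analytically by letting the fourth monomer equal
minus the sum of the other three.  A fit is flagged converged only if
the best restarts agree within 1e−4 log-likelihood units.  HIII vs HI
is a 1-df and HIII vs HII a 3-df likelihood-ratio test; a negative
statistic beyond −1e−6 raises an error because it can only mean the
optimiser failed.  Bootstrap confidence intervals resample whole
sequences and refit.

## The circular Gillespie simulator

`simulate_ctx()` evolves a circular L-base sequence (default L = 10,
matching the tract) exactly: at each event the L×4 table of
context-dependent rates is assembled (precomputed per
(left, focal, right) context, so each event is table lookups), the
waiting time is exponential in the table total, the position is drawn
proportional to its row sum and the new base proportional to its rate.
"Iterations" counts accepted substitutions.  After a burn-in (default
10^3 events) per-position compositions and adjacent-pair joint
frequencies (including the wrap-around pair) are accumulated.

Occupancy can be weighted by sojourn time or by event.  Time weighting
is the statistically correct occupancy of a continuous-time chain and
is the default used by every quantitative check; event weighting is
retained because iteration-counting descriptions of such simulations
are ambiguous on this point, and the two differ predictably (event
weighting over-represents fast-leaving, low-fitness states — itself a
test in the suite).  Batch means over consecutive event blocks provide
Monte-Carlo standard errors.  `chi2_deviation()` compares simulated
joint frequencies with empirical pair counts cell by cell via
(observed − expected)²/expected, the model-ranking statistic: when
empirical counts are generated under joint selection, the
joint-selection simulation attains the smallest total deviation.

## The synthetic-data generators

`synth_genome()` builds an annotated chromosome of multi-exon genes on
both strands with canonical GT…AG introns: neutral segments drawn from
the stationary composition of the mutation matrix (AT:GC = 2:1 by
default), tract segments drawn from the simulator's stationary regime
under a chosen selection hypothesis, and per-individual genomes derived
by injecting biallelic polymorphisms with a neutral (1/y) frequency
spectrum.  A manifest records every intron's coordinates, phase and
true region sequences, so extraction can be verified exactly.  The
generator's defaults are the study conditions used throughout the
tests: intron lengths uniform on 45–75 bp, tract selection
$\gamma_T = 0.5, \gamma_A = -0.5, \gamma_{AG} = -2$, and spectra at
$\beta = 2/3$.

`synth_region_set()` draws sequences by thinning one simulator chain
(default: two substitutions per site between snapshots).  That is
adequate for composition and point estimates, but consecutive
snapshots retain some correlation, so resampling-based confidence
intervals computed from such a set treat correlated draws as
independent introns and can undercover; calibration checks that target
interval coverage draw sequences iid from the exact stationary law
instead (possible whenever selection is monomer-only, where sites are
independent at stationarity).

What the generators deliberately do *not* emulate: demography,
recombination and linkage, heterozygous genotype calling, indels, and
transcription-associated mutation asymmetry (a strictly
strand-symmetric mutation matrix cannot produce 5LR asymmetry; a
non-symmetric matrix can be supplied where that matters).  Passing
tests on these data therefore validate the estimators' internal
consistency and calibration, not robustness to those real-data
complications.

## Numerical choices and problem sizes

* Quadrature: `integrate()` at rel.tol 1e−10, binomial coefficients
  folded into the integrand on the log scale; degenerate 0·log 0
  corners at y = 1 and y = n−1 handled explicitly.
* Stationary solves: least-squares on the generator transpose with the
  normalisation row appended (`qr.solve`), for both 4- and 16-state
  systems.
* Pseudocounts: 0.5 per motif (selection log-odds only; the
  mutation-matrix estimator errors on empty classes instead, since an
  empty class there signals inadequate data).
* Reproducibility: every stochastic entry point requires a seed and is
  bit-reproducible under it.

The test-suite problem sizes were chosen to keep each check
informative at desk scale: pair-count recovery at N = 10^5 draws,
likelihood-ratio calibration over 200 replicates of 5×10^3 draws,
spectrum recovery at 5×10^4 sites with 150-replicate calibration at
B = 0, model ranking over 20 seeds with 2×10^4-event simulations, and
bootstrap coverage over 200 replicates of 100 introns.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_genes = 30, n_individuals = 8, seed = 101)
g <- synth_genome(cfg, out_dir = tempfile("genome"))
introns <- load_introns(g$paths$annotation, g$paths$reference,
                        g$paths$individuals)
regions <- extract_region_sets(introns)

# strand asymmetry in the tract
tract_cons <- region_consensus(regions$threePT)
head(asymmetry_table(tract_cons, k = 2))

# per-motif selection against the 5LR
gamma_bootstrap(tract_cons, region_consensus(regions$fiveLR),
                k = 3, B = 1000, seed = 17)

# mutation matrix from the 5LR, then per-position model fits
Q <- estimate_mutation_matrix(lapply(regions$fiveLR, `[[`, "alignment"))
pc <- pair_counts(tract_cons)
fits <- lapply(c(HI = "HI", HII = "HII", HIII = "HIII"),
               function(h) fit_position(pc[[5]], Q, h))
compare_models(fits)
```

## Known limitations

The two-site closure ignores context beyond nearest neighbours, so
selection on trimers or longer motifs is absorbed into the monomer and
dimer coefficients.  The log-odds coefficients of `motif_selection()`
and the mechanistic coefficients of `fit_position()` are on the same
4Nₑs scale but are not numerically interchangeable — one is a
composition contrast, the other a rate-model parameter.  The gBGC
model assumes free recombination among sites and no polarisation;
near β = 1/2 its B is weakly identified (see above).  All inference
assumes stationarity; non-equilibrium histories are out of scope.
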