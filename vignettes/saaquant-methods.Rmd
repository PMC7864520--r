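---
title: "Quantifying seeded SAA aggregation: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seeded SAA aggregation: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`saaquant` analyses seeded aggregation of serum amyloid A (SAA), the
acute-phase protein behind AA amyloidosis. Amyloid-enhancing factor (AEF) —
fibril-containing tissue extract — acts as a seed that dramatically shortens
the onset of SAA fibril formation, and seeding efficiency differs between
donor species. The package quantifies aggregates in fluorescence micrographs
through the per-pixel brightness SD statistic, fits time-course and
dose-response models to those readouts, describes aggregate morphology and
z-stack thickness, and relates species-level seeding activity to SAA
sequence homology (alignment, tree, discriminative residues). A synthetic
generator reproduces the statistical structure of such an experiment so
every stage has ground truth.

This vignette is the package's methods account: the models, their
assumptions, the tunable parameters and why they have the defaults they do,
what the simulations do and do not establish, and the numerical choices
that matter for reproducibility.

## 1. The seeded nucleation-elongation model

Fibril mass $F$ grows from soluble monomer $M = T - F$ (total $T$) by
primary nucleation and seeded elongation:

$$\frac{dF}{dt} = k_n M + k_e M F, \qquad F(0) = s\,T,$$

with nucleation rate $k_n$ (1/h), elongation rate $k_e$
(1/(concentration·h)) and seed fraction $s \in [0,1]$ — the model's image
of the AEF dose. This is the minimal two-species model that expresses the
seeding phenomenon: larger $s$ strictly shortens the half-time, and with
$s = 0,\ k_n = 0$ nothing ever aggregates. It deliberately omits secondary
nucleation and fragmentation; nothing downstream depends on those terms,
and the package makes no mechanistic claims beyond "seed in, lag out".

`simulate_kinetics()` integrates the ODE with `deSolve::lsoda`
(rtol 1e-10, atol 1e-12). The equation is a Riccati equation with a closed
form, which the test-suite uses as an oracle independent of the integrator,
together with a fixed-step RK4 oracle at a 10-fold finer step (agreement
is required to 1e-5). Mass is conserved by construction ($M := T - F$);
the tests additionally integrate the explicit two-species system and check
$|M + F - T| < 10^{-6}T$.

Per-species defaults (in `species_defaults()`, not hard-wired) encode the
qualitative biology: cat ($k_e = 0.090$) and mouse (0.080) seeds drive
aggregation to plateau well before 168 h, while camel/cattle/goat
(0.0195/0.0190/0.0185) reach only ~50-75% conversion; $k_n = 10^{-12}$/h
makes spontaneous nucleation negligible on the one-week scale, matching an
unseeded series that stays flat. The AEF fraction maps linearly onto the
seed, $s = \text{aef} \times 0.05$: absolute seed concentrations are not
measurable from the assay, so the ceiling 0.05 (5% of total mass as
pre-formed fibril at 100% AEF) is a free, fixed choice. Replicate-level
variability is multiplicative (relative SD 0.05) so that a zero-seed
condition stays exactly at zero.

## 2. The virtual microscope

`render_micrograph()` converts a fibril mass fraction into an 8- or 16-bit
frame (default 128 x 128 px):

* **dotted** morphology — a Poisson number of Gaussian blobs
  (expectation `dot_density * mass_fraction`, default 70 at full
  conversion), random radii 0.8-2.2 px and amplitudes 0.7-1.3, the compact
  deposits seen with cat, camel, cattle and goat seeds;
* **mesh** morphology — persistent random-walk filaments (total path
  `mesh_length * mass_fraction`, default 6000 px), each new filament
  seeded on an existing one so the network is one connected structure,
  stamped two pixels thick; the mouse-seed form.

The structure is blurred with a Gaussian PSF ($\sigma$ = 1.5 px),
superimposed on Gaussian camera background (mean 30, SD 5 on the 8-bit
scale), clipped and quantised. Filaments are stamped bright and thick
enough to sit clearly above the camera noise floor after blurring; a
consequence is that a full-conversion mesh produces a *higher* SD than a
full-conversion dotted frame, so in the default panel the mouse-like
species ranks first and the cat-like species second. The pipeline's
ordering claims concern the high-activity *pair*, which is unaffected.

`render_zstack()` reuses the same structural signal: each xy position is
occupied over a centred run of slices whose length scales with
`z_slices * mass_fraction * (local signal / max signal)`, so the occupancy
envelope thickens monotonically with aggregate load.

Everything is seed-deterministic: identical `(params, rng_seed)` give
bit-identical frames, and the generator restores the session RNG state.

## 3. The SD statistic and its summaries

`sd_statistic()` is the *population* standard deviation (denominator $N$)
of all pixel intensities of the raw frame — no background subtraction, no
cropping, colour collapsed by channel mean. Population vs sample SD is
numerically irrelevant at $\geq 10^4$ pixels but is fixed for bit-level
reproducibility. The statistic is shift-invariant and scale-equivariant,
and an empty frame's SD is the camera background SD, which is why it works
as an aggregate readout: fluorophore concentrated into structures widens
the brightness histogram.

`summarize_timecourse()` reduces replicates to mean ± SEM (sample SD over
replicates / $\sqrt{n}$; SEM is `NA` at $n = 1$), the usual presentation
of such time courses with $n = 3$.

## 4. Curve fitting

**Time courses** are fitted with the Boltzmann sigmoid
$y = b + (p - b)/(1 + e^{-k(t - t_{50})})$, the convention of the
amyloid-kinetics literature, with lag time $t_{50} - 2/k$ floored at 0.
Fitting is deterministic multistart least squares
(`minpack.lm::nlsLM`, 12 start combinations over $t_{50}$ and slope);
a flat series short-circuits to plateau = baseline with the $t_{50}$
flagged extrapolated, and $t_{50}$ outside the observed window is flagged
likewise.

**Dose response** uses the rising four-parameter logistic
$y = b + (t - b)/(1 + (x_{50}/x)^h)$ on endpoint SD versus AEF fraction —
the EC50 idea transposed to a promoting factor. Two numerical choices
matter and were adopted after the estimator proved fragile without them:
the vehicle control $x = 0$ is admitted at its model limit ($y = b$),
anchoring the bottom, and $b \geq 0$ because a brightness SD cannot be
negative. Without the anchor the fit can drift onto a shallow-hill ridge
with absurd extrapolated bottoms. A constant response is flagged
unidentifiable rather than fitted.

When the top plateau is only approached, not reached, within the dose
range, the 4PL parameters ride a top/half/hill ridge: many parameter
combinations describe the same within-range curve, so the `half_max`
*parameter* is weakly identified even on noise-free data. The
well-identified quantity is the **operational half-max**
(`half_max_dose()`): the dose at which the fitted curve crosses halfway
between its predicted responses at the range ends — the EC50 as read off
the plate. It coincides with the parameter whenever the plateau is
reached in-range.

**Validation design.** The dose-recovery simulation uses a standard
microplate EC50 layout — vehicle control plus a two-fold dilution series
from 100% AEF, three wells per dose, cat kinetics at a 48 h endpoint,
where the response both leaves the bottom and spans most of its range.
The assay panel itself (5 linear fractions, 20-100%) is kept for the
screening pipeline, but it cannot identify a half-max on a species that
saturates at every tested dose — an identifiability fact, not a software
limitation. Ground truth is the half-maximal crossing of a dense
noise-free reference curve (40 renders per dose, loess-smoothed on log
dose); the median $|\log_{10}(\hat{x}_{50}/x_{50})|$ across 30 simulated
panels is about 0.06-0.07 regardless of the random stream.

## 5. Morphology and thickness

Frames are thresholded by Otsu's method with a camera-noise floor: the
background level and noise SD are estimated from the darkest quintile of
the histogram by Gaussian quantile matching, and the threshold never drops
below background + 5 SD. (Otsu alone happily splits pure noise; a
median + 5 MAD floor fails in the other direction once a mesh covers most
of the frame.) Above-threshold pixels are labelled by 8-connected
components and thinned with Zhang-Suen skeletonisation. A frame is called
**mesh** when the largest component holds at least 20% of the foreground
*and* the skeleton length per image area is at least 0.012 px$^{-1}$ —
cutoffs calibrated once on the generator (dotted frames stay below 0.006,
meshes above 0.028 at half conversion) and stored in configuration. A
frame with nothing above threshold is labelled `none`.

`thickness_profile()` counts, per xy position, slices of a z-stack above
the same global threshold and scales by the axial step; the summary is the
mean over the above-threshold footprint. It is invariant to slice order.

## 6. Sequence homology

`global_align()` implements Needleman-Wunsch with affine gaps (Gotoh's
three-state recurrences). A gap run of length $L$ costs
`gap_open + (L-1) * gap_extend` (defaults -10/-1, BLOSUM62 scores,
alphabet restricted to the 20 standard residues plus X scored 0);
traceback ties break deterministically diagonal > up > left. The
test-suite checks the scores against exhaustive enumeration over all
alignments of short peptides and against `Biostrings::pairwiseAlignment`
under the translated gap convention.

`progressive_msa()` builds a UPGMA guide tree from pairwise identity
distances and merges profiles bottom-up with the same scoring scheme
(column-column score = mean pairwise residue score, residue-vs-gap scored
`gap_extend`). De-gapping any row always reproduces its input, and
gap-only columns cannot arise.

`percent_identity()` uses pairwise deletion: matches over columns where
neither row is gapped (`NA` when no such column exists). The headline
`overall_homology()` number is the *minimum* pairwise identity — the
"at least X%" summary — with the fraction of fully conserved columns as a
secondary metric. Column conservation classes follow the colouring bands
full = 100%, high = (75, 100)%, mid = (50, 75]%, low ≤ 50%, with values on
a band edge assigned to the lower class (the band definitions are
typographically ambiguous in their source; the edge convention is fixed
here once).

`build_tree()` is UPGMA agglomeration with heights at half the merge
distance and ties broken by the lexicographically lowest leaf pair;
`stats::hclust(average)` serves as an independent cross-check in the
tests, and `clade_check()` delegates monophyly to `ape`.

`discriminative_site_scan()` reports columns where each activity group is
internally uniform under a class partition and the two classes differ,
skipping any column with a gap in a group member. The default partition is
**charge** {acidic, basic, neutral}: the motivating biology is
charge-mediated protein-protein contact, and the known SAA contrast at
column 48 (Gln/Ile in the high-activity pair versus Lys elsewhere) is
mixed under a five-class scheme but cleanly neutral-versus-basic under
charge. The five-class table (D,E acidic; K,R,H basic; S,T,N,Q,C,Y polar;
A,V,L,I,M,F,W hydrophobic; G,P special) remains available via
`scheme = "property"`, and `strictness = "residue"` additionally demands
within-group residue identity.

## 7. The synthetic sequence family

`simulate_sequence_family()` evolves a uniform-random ancestral protein
(default 130 residues, the size class of SAA with signal peptide) along a
user tree under an i.i.d. uniform-exchange (Jukes-Cantor-type) amino-acid
process, without indels. The default six-species topology places mouse and
cat as the closest pair with human just outside, and camel/(cattle, goat)
on the other side; branch lengths put the most distant pairs near 78-80%
identity and mouse-cat near 93% — the "highly conserved family" regime.
Planted columns are frozen during evolution and then set per leaf
(residue letters, or a class name from which a residue is drawn), so the
planted pattern is exact by construction; the defaults plant the
neutral-vs-basic contrast at column 48 and acidic-vs-Ala at column 125.

**What the scan validation does and does not show.** On *clean* families —
zero background branch lengths, randomised planted residues — the scan
recovers exactly the planted columns in 50/50 seeds (precision = recall
= 1). Under realistic divergence the planted columns are still always
recovered (they are immune to substitution), but perfect precision is
impossible *in principle*: any substitution on the internal path
separating {mouse, cat} from {camel, cattle, goat} that crosses a charge
class creates a column statistically indistinguishable from a planted
site. At the default divergences this yields a handful of extra
perfectly-discriminating columns per family. That is phylogenetic
confounding — with a 2-versus-3 species contrast the data cannot tell
"causal residue" from "clade-specific substitution" — and it is exactly
the caveat that applies to reading candidate residues off a real
alignment of two activity groups that are also sister clades.

## 8. The pipeline layer

`run_simulate()`, `run_quantify()`, `run_homology()` and `run_report()`
(chained by `run_all()`) orchestrate disk-level runs under a single
validated configuration (`default_config()`; YAML round-trip via
`read_run_config()`/`write_run_config()`; unknown keys anywhere are
rejected). Images are written as single-page TIFFs named
`{species}_{aef%}_{time}h_{rep}.tif` with a CSV manifest; quantification
writes tidy CSVs (`images`, `timecourse`, `doseresponse`, `fits`,
`morphology`, `ranking`), never aborting on an unreadable frame (it is
logged and skipped); homology writes the gapped FASTA, identity and
conservation tables, Newick tree, clade verdict and site reports; the
report stage renders the figures with their plot data as CSV and degrades
to explicit "no data" sections. Two runs with the same configuration and
seed produce byte-identical CSVs.

This package is function-first: the four `run_*` verbs *are* its command
surface, and a shell wrapper would add nothing beyond argument parsing.

## 9. Problem sizes and limitations

The simulations in the tests and in `scripts/acceptance.R` use the default
panel (5 species x 5 fractions x 8 times x 3 replicates = 600 frames of
128 x 128 px) for ranking (20 runs), 200 frames for morphology accuracy,
30 panels for dose recovery, and 50 families for tree/clade/site
properties — sizes chosen so the whole validation runs comfortably on a
laptop while keeping the Monte-Carlo margins far from the pass thresholds.

Known limitations, deliberate:

* the kinetic model is a stand-in: no secondary nucleation, fragmentation,
  or species-specific structural biology; species differ only through
  rate parameters;
* the renderer emulates brightness statistics, not QD photophysics; real
  micrographs carry illumination gradients, debris and focus drift the
  generator does not produce, so passing tests certify the *analysis*,
  not robustness to every real-world artefact (an optional preprocessing
  hook exists but is off by default, since the SD statistic is defined on
  the raw frame);
* absolute AEF concentrations are unknowable from the assay; the seed
  ceiling is a convention, so fitted half-max fractions are comparable
  within the pipeline but not across assays with different ceilings;
* residue positions in site reports are 1-based *alignment* columns; on
  indel-free families these coincide with sequence positions, on gapped
  alignments they need not;
* discriminative-site precision under realistic divergence is bounded by
  phylogenetic confounding (section 7).
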