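---
title: "Accounting for biomineral ballast on agglomerated tintinnid loricae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for biomineral ballast on agglomerated tintinnid loricae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loricaballast)
```

## The accounting model

Some planktonic tintinnid ciliates capture biogenic mineral particles —
single coccolithophorid calcite plates (liths) and broken diatom frustule
pieces — onto their proteinaceous shells (loricae). The quantity of
interest is the added mineral mass per lorica, the *ballast*:

$$B \;=\; \sum_i n_i\,w_i \;+\; \sum_j V_j\,c \qquad [\mathrm{pg}]$$

with $n_i$ the lith count of coccolith taxon $i$, $w_i$ its per-lith CaCO₃
mass (pg), $V_j$ the biovolume (µm³) of diatom particle class $j$, and $c$
the biovolume-to-biogenic-silica conversion
($0.0005\ \mathrm{pmol\ Si\ µm^{-3}} \times 28\ \mathrm{pg\ pmol^{-1}}
= 0.014\ \mathrm{pg\ µm^{-3}}$).

The model rests on the assumptions under which such counts are made:
liths are captured intact, so a literature per-lith mass applies; both
lateral sides of a lorica are assumed identically covered (micrographs show
one side); diatom fragments contribute only their silica, estimated through
geometric biovolume; and morphotypes within a coccolithophorid genus are
not discriminated, so one mass per genus is used.

Everything enters through a per-lorica observation ledger
(`lorica_ledger()`), with three interchangeable quantity types: `count`
(particles), `mass_pg` (pre-converted mass, as literature tables print),
and `biovolume_um3`. This polymorphism is deliberate: published tables mix
conventions, and exact reproduction of a printed table requires accepting
its printed masses verbatim.

## Reference constants

`ballast_reference()` packages the constants and is fully overridable from
YAML/JSON (`read_reference()`), so sensitivity analyses against the lith
masses are a config edit, not a code change. Defaults (pg CaCO₃ per lith):
Emiliania 4, Gladiolithus 4, Syracosphaera 10, Umbilicosphaera 16,
Florisphaera 20, Rhabdosphaera 60, Calcidiscus 124, Helicosphaera 140,
Coccolithus 152. Diatom particle biovolumes (µm³): Pseudo-nitzschia
fragment 25, Chaetoceros setae 40, Fragilariopsis fragment 63,
Thalassiothrix fragment 100, Eucampia cribrum 250, Coscinodiscus cribrum
375, whole *Fragilariopsis pseudonana* cells 100 (= 1.4 pg Si each). The
bare-lorica dry weight used by `extra_weight_fraction()` is
40 000 ± 20 000 pg.

Several taxa that appear in counted material have no published per-lith
mass. Two design choices follow:

* **Aliases, not silent guesses.** Gephyrocapsa and Alisphaera map onto the
  Emiliania mass class and Coronosphaera onto Syracosphaera, by
  morphological analogy (Gephyrocapsa liths are nearly identical in size to
  Emiliania's). The alias table is explicit, user-editable, and alias
  resolution is part of ledger validation.
* **No default mass for Umbellosphaera and Calciosolenia.** Their
  contributions must be entered as `mass_pg`; inventing a constant would
  masquerade as data. The packaged fixtures store their printed pg values
  verbatim.

## Fixtures and how printed tables were encoded

Four published tables ship as CSV fixtures. Encoding rules: a coccolith
cell printed in pg that is an exact multiple of the default lith mass is
stored as a count (880 pg Emiliania → 220 liths); otherwise as `mass_pg`.
Diatom cells are stored as printed. Printed summary rows without per-lorica
breakdown become *group-mean pseudo-loricae* with `n_loricae > 1`; their
contribution to summaries is weighted by `n_loricae`, and their within-group
variance is unrecoverable, so standard deviations over pseudo-loricae
reflect between-group spread only. "x of n" cells become occurrence
annotations and are never expanded into invented per-lorica rows.

Printed tables are not internally consistent everywhere. Rows whose printed
total differs from the sum of their printed components by more than ±1 pg
are listed in `known_discrepancies()` with both values retained; tests
assert the recomputed value for flagged rows and the printed value for all
others. Two encodings deserve flagging here: the group-summary tables print
per-taxon columns that are best read as mean lith counts of *identified*
taxa, and no such row's count arithmetic reproduces its printed total (the
totals evidently include cover not attributed to the identified columns);
and one table's caption labels columns "% of total liths", an ambiguity we
store as counts with provenance notes and exclude from assertions. One
consequence worth knowing: the "Others" group of the North Atlantic table
classifies as Calcidiscus-dominated under count arithmetic (share 0.502),
which mostly indicates that its printed columns are not all counts — the
printed grouping, not our label, should be trusted for that row.

## Summaries: conventions that the data pin down

* **Population standard deviation** (divisor $n$). The printed summary
  "445 ± 461" for the Emiliania column is reproduced by $n$-division
  (460.6); sample sd would give 483. This empirical match fixes the
  convention package-wide (`pop_sd()`).
* **Absent means zero.** A taxon not found on a lorica contributes 0 pg to
  its group mean, not `NA`; printed means are over all $n$ loricae.
* **Occurrence** requires a strictly positive quantity of any type.
* **Rounding for display** is half-away-from-zero to integer pg and percent
  (`round_half_up()`); unrounded values are retained everywhere internally.
  The source tables themselves round inconsistently (477.7 printed as 477
  but 460.6 as 461), so tests target only rounding-robust cells.
* **Percent shares** on a zero-total lorica are undefined;
  `percent_composition()` signals a warning and returns an empty table
  rather than failing, and such loricae contribute 0 to group percent
  means.

## Classification

Lorica types follow priority rules: any whole diatom cell ⇒ `diatom-type`;
else a heavy coccolith taxon (default list Calcidiscus, Coccolithus)
holding ≥ 50% of total ballast ⇒ `<taxon>-dominated`; else `other`. The
heavy list and threshold are conventions (`dominance_policy()`): published
groupings name the types without numeric cutoffs, so both are configurable
and the defaults are the smallest rule set that reproduces the published
group labels on the per-lorica material. Ties on share are broken by
heavier per-lith mass, then lexicographically.

## Derived metrics

`extra_weight_fraction()` divides ballast by the bare-lorica dry weight and
propagates the dry-weight uncertainty into the interval
$[B/(W+\sigma),\ B/(W-\sigma)]$. `regional_ratio()` compares two group mean
totals. A caveat the package surfaces rather than hides: the published
pooled tropical mean (2428 pg, $n = 8$) is *not* the $n$-weighted mean of
the published regional rows (5 × 3248 and 3 × 2428 pool to 2940.5); it
coincides with the printed Tonga row. The ~8× cold/warm ratio reproduces
with the printed pooled value (19922/2428 = 8.2); weighted re-pooling would
give 6.8.

`preference_matrix()` orders tintinnid taxa by oral diameter and particle
taxa by characteristic size (coccolith lith sizes from the reference;
taxa without a size key go last with a warning), and fills cells with
occurrence fractions and mean mass shares. Occurrence annotations override
computed indicators where the underlying table gave only "x of n".

## The ledger generator

`simulate_ledger()` emulates the statistical structure the accounting
assumes, so that every pipeline stage is testable without external data:

* **Ambient pools** (`ambient_assemblage()`) encode the qualitative
  regional rankings the field material showed: temperate pool ordered
  Emiliania > Calcidiscus > Gephyrocapsa > Syracosphaera > Coccolithus plus
  small whole diatoms; polar pool Emiliania-dominated (Calcidiscus 10%,
  Coccolithus rare) with abundant diatom fragments; tropical pool of small
  light liths plus Rhabdosphaera. Exact proportions are our choice — the
  source observations are ranked, not quantified — made once and fixed.
* **Size-selective capture** (`capture_model()`): a particle whose size
  falls within 20–30% of the lorica oral diameter has its capture weight
  multiplied by $1 + \mathrm{strength}$. The window is the reported
  preferred prey-size band; the boost is multiplicative, not a hard filter,
  because real loricae carry small and large liths simultaneously. The
  default strength 1 (doubling) encodes the reported *direction* of
  preference; no magnitude was published. Strength 0 recovers ambient
  proportions exactly — the property the convergence tests use.
* **Scarcity shift**: when `coccolith_availability` falls below
  `scarcity_threshold` (default 0.25), the coccolith pool is scaled by the
  availability and renormalised, shifting capture to diatom fragments.
  This reproduces the observed binary pattern (lith-covered versus
  fragment-only loricae in one population) without claiming a mechanism.
  Whether the size preference stated for prey even applies to agglutinated
  particles is an open question in the source material; the simulator
  exposes it as a parameter rather than asserting it.
* **Counts** are Poisson (mean `particles_per_lorica`, default 100 — the
  order of magnitude of lith counts on covered loricae), switchable to
  negative binomial for overdispersion; no count model was published.
* **Determinism**: the seed is mandatory, the generator restores the
  caller's RNG state, and identical parameters + seed give identical
  ledgers (a tested contract).

What the generator does *not* emulate: feeding-current hydrodynamics,
lorica construction timing (the brief post-division stickiness window),
particle position on the bowl, and spatial/temporal correlation in ambient
assemblages. Passing recovery tests therefore validate the accounting
arithmetic and the generator's own statistical assumptions — not the
realism of capture in the ocean.

`recovery_experiment()` compares the fitted mean total (and CaCO₃) ballast
against the closed form $E[B] = E[N]\,\sum_i p_i m_i$, with the capture
probabilities averaged over the oral-diameter distribution by quadrature
(201-point normal grid, truncated at 20% of the mean — the same floor the
generator applies). Test and acceptance runs use 100–500 loricae; these
sizes give standard errors small enough for 3-SE checks while keeping the
whole suite fast.

## Numerical choices

* Conservation (total = CaCO₃ + silica = row sum of per-taxon masses) is
  asserted to 1e-9 relative tolerance; the silica-conversion linearity to
  1e-12.
* Degenerate inputs: empty observation tables are valid (total 0);
  all-zero ambient abundances are an error; zero mean particle count gives
  an expected and estimated ballast of 0 with z defined as 0.
* CSV round-trips are value-identical: column types are canonicalised on
  construction and simulated oral diameters are generated at 2-decimal
  resolution so that write→read is lossless.
* Report bundles are byte-stable across runs (no timestamps; provenance
  headers carry version, config hash, seed).

## Limitations

The accounting is semi-quantitative by construction: per-lith masses are
genus-level literature values, biovolumes of irregular fragments are
geometric estimates, and half of each lorica is unobserved. Group-mean
pseudo-loricae propagate printed summaries, not raw data, and inherit the
source tables' internal inconsistencies (all catalogued in
`known_discrepancies()`). No hypothesis tests between regions are provided
— with printed summaries as the only input for most groups, there is no
basis for them — and no sinking-rate predictions are attempted.
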