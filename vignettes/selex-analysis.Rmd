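---
title: "Analysing Cell-SELEX sequencing pools with selextract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing Cell-SELEX sequencing pools with selextract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selextract)
```

## The problem

Cell-SELEX selects ssDNA aptamers against whole cells by iterating
incubation, partitioning and PCR amplification of a randomized
oligonucleotide library. When the enriched pools from several selection
rounds are sequenced on a short-read instrument, the analysis questions
are always the same: which reads are genuine library members, what unique
sequences do they contain, how abundant is each, and which sequences have
enriched across rounds strongly enough to be candidate binders?

`selextract` answers these for libraries of the form
`flank5 – N<k> – flank3`: a randomized region of design length *k*
bounded by two constant regions that double as PCR primer sites. The
default design is an N40 library with 18-nt flanks
(`ATCCAGAGTGACGCAGCA-N40-TGGACACGGTGGCTTAGT`, a 76-bp amplicon), but any
design can be described with `library_design()`.

## Read validation and insert extraction

A sequenced read is accepted as a library member when both constant
flanks are found (on either strand) with the randomized insert between
them inside a length retention window, by default
`n_length ± length_tolerance` = 38–42 nt. Everything else is rejected
with an explicit per-read verdict:

* `NO_FLANK5` / `NO_FLANK3` — a constant region is missing or, with
  `max_mismatch = 0`, mutated. These reads are most often sequencing
  errors in a flank or unrelated DNA.
* `LENGTH_FAIL` — both flanks present but the insert falls outside the
  window. This is the signature of the elongated PCR by-products that
  arise when library molecules prime each other inside the randomized
  region and get extended by the polymerase; they carry intact primer
  sites but a longer-than-design core.
* `AMBIGUOUS_BASE` — the insert contains a non-ACGT base. Collapse works
  on exact string identity, and an `N` would split one molecule's reads
  across spurious "unique" sequences, so such reads are dropped.
* `DISCORDANT_PAIR` — both mates pass but disagree on the insert.

Flank matching is Hamming-only (no indels) and exact by default,
mirroring text-based filtering; `max_mismatch` relaxes it per flank. When
several placements of the flanks are possible, the choice is
deterministic: fewest total flank mismatches, then insert length closest
to the design length, then leftmost 5' flank, then leftmost 3' flank. A
read that passes on both strands (a palindromic corner case) reports its
forward placement and is flagged in the `both_strand` column. Failure
statuses are assigned by the first unmet condition in the order 5' flank,
3' flank, length, taking whichever strand got furthest.

Paired-end data are reconciled per mate: each mate is scanned
independently, exactly-one-wins, and two passing mates must agree on the
insert or the pair is discarded (`on_discordant = "keep_r1"` keeps the
forward mate instead). The window is applied per mate, not per joined
super-read. Base qualities are ignored during extraction — the verdict
logic is purely sequence-based — which is why the FASTQ reader keeps them
only as pass-through strings.

```{r extraction-example}
design <- library_design()
read <- paste0(design$flank5, strrep("ACGT", 10), design$flank3)
find_flanks(read, design)
```

Every pool-level run returns a QC ledger whose status counts sum to the
number of input reads; the drop per cause is the first thing to inspect
on real data, because a healthy late round should lose fewer reads than
an early one.

## Collapse, normalization, ranking, enrichment

`collapse_reads()` reduces identical inserts to unique sequences with
duplication counts. Counts are normalized as reads per million
(`rpm = count / total_pass * 1e6`) so rounds of different depth can be
compared. `top_candidates()` reports the sequences whose count strictly
exceeds `min_count` (default 25 — "more than 25 reads" means 26 and up),
ranked by count with lexicographic tie-breaks so output is independent of
input order. `enrichment()` compares two rounds on the RPM scale with a
0.5-RPM pseudocount, so a sequence absent from the early round still gets
a finite, positive fold-change:

\[
\mathrm{fold} = \frac{\mathrm{rpm}_{late} + p}{\mathrm{rpm}_{early} + p},
\qquad p = 0.5\ \mathrm{RPM}.
\]

The pseudocount is a standard small-count stabilizer; it is recorded as
an attribute of the returned table. `run_pipeline()` wires these steps
into a per-round report bundle (counts tables, QC JSON, enrichment table,
candidate report, summary JSON, log) and is deterministic for fixed
inputs.

## The synthetic SELEX simulator

Real SELEX sequencing data with ground truth rarely exists, so
`selex_sim_config()` + `simulate_round()` generate it. The model:

* **Pool composition.** A fixed universe of `n_binders` binder sequences
  and `n_background` background sequences, all distinct random inserts of
  the design length. At round *r*, binder *i* has relative weight
  `enrichment_factor^(r-1)` against weight 1 per background sequence;
  reads are drawn multinomially from the normalized weights. Geometric
  growth is the simplest model consistent with round-over-round
  enrichment of viable binders; no kinetic claim is attached to it.
* **By-products.** With probability `byproduct_fraction` a read is a
  chimera: a prefix (≥ `n_length − length_tolerance` nt) of one insert
  joined to a suffix of another, elongated 3–38 nt beyond the retention
  window. The prefix/suffix join represents only the observable outcome
  of the hybridization-priming mechanism — extraction can see the length
  violation, not the priming event itself. The elongation cap is 38
  because a chimera is built from two design-length (40-nt) parents:
  the total cannot exceed 80 nt. The default fraction 0.05 is a
  documented, order-of-magnitude choice; gel images of such artifacts
  are qualitative and support no sharper number.
* **Sequencing error.** Substitutions only, applied once per fragment at
  `error_rate` per base; the reverse mate is the exact reverse
  complement of the errored fragment (errors modelled as
  amplicon-level, PCR-dominated). This keeps closed forms exact: with
  `max_mismatch = 0` a clean fragment passes extraction iff none of its
  `nchar(flank5) + nchar(flank3)` constant bases is hit — substitutions
  inside the randomized insert change the recovered sequence but not the
  flank match or the length — so the expected pass fraction is
  `(1 − e)^36` for the default design, while the fraction of fully
  error-free fragments is `(1 − e)^76`. Both are exposed by
  `expected_pass_fraction()` and both are asserted against simulation in
  the test suite. Independent per-mate errors would break this
  one-line calculus without adding realism the extraction logic could
  detect.
* **Reproducibility.** The sequence universe derives from `seed`; round
  *r* uses a stream seeded `seed + r`, so any round can be regenerated
  alone, byte-identically, without simulating its predecessors. That
  conditional independence is also why validation runs that only need
  the final round render only the final round.

What the simulator does *not* emulate: PCR cycle-level amplification
bias, polymerase error spectra, indels, quality-score decay along the
read, strand-separation losses, or any cell-binding biophysics. Passing
tests therefore demonstrate that the analysis logic is correct under a
clean generative model, not that it is robust to every artifact of real
MiSeq data — on real pools the QC ledger, not the simulator, is the
instrument for judging data quality.

Default simulation sizes used in the package's own validation: error
statistics at 10^4 reads (binomial 3-SE tolerances), binder recovery
with 3 binders at factor 1.8 over 12 rounds sampling 10^5 reads from the
final round, and brute-force oracle comparison on 10^3 random reads up to
120 nt. These sizes give comfortable statistical resolution while keeping
a full check run in well under a minute.

## MST dose-response module

Microscale thermophoresis titrations of a labelled aptamer against a
cell dilution series (canonically 16 points, 1:1 from 2×10^7 cells/mL;
`mst_dilution_series()`) are summarized in two steps.

`delta_fnorm()` converts normalized fluorescence to baseline-subtracted
ΔFnorm (‰) by subtracting the baseline Fnorm from all points of the same
curve. The baseline defaults to the lowest-concentration titration point;
designs with a dedicated zero-target well can point `baseline_index` at
it instead. Both conventions appear in practice and the choice is
deliberately explicit rather than guessed. ΔFnorm is invariant to
constant offsets and exactly 0 at the baseline point.

`fit_saturation()` fits the one-site saturation model by
Levenberg–Marquardt least squares. Because the data are
baseline-subtracted, the model is too:

\[
\Delta F(c) = A\left(\frac{c}{m+c} - \frac{c_b}{m+c_b}\right),
\]

with `c_b` the baseline concentration — otherwise the model would predict
a nonzero response where the transform forces zero, and even noiseless
data could not be fit exactly. `A` is the response amplitude in ‰
(negative values allowed; the sign of a thermophoresis response is
assay-dependent) and `m` is the concentration at half-maximal response.
For whole-cell titrations the molar target concentration is unknowable,
so `m` is reported strictly as a *response midpoint*, never as an
equilibrium dissociation constant. The quality metric is
`signal_to_noise = |A| / sd(residuals)`, the usual discriminator when
amplitudes alone mislead.

Numerical choices: the fit is initialized from the data (amplitude at the
largest absolute response; midpoint by profiling the amplitude — which is
linear given `m` — over a 25-point log-spaced grid) and refined with
`minpack.lm::nlsLM`, lower-bounded so `m` stays positive. A flat response
or non-convergence yields a flagged result (`converged = FALSE`,
amplitude and midpoint `NA`) with the ΔFnorm table still returned, so a
non-binding curve is a first-class answer rather than an error.

```{r mst-example}
set.seed(1)
conc <- mst_dilution_series()
fnorm <- sapply(1:3, function(r) 900 + 12 * conc / (1e6 + conc) +
                  rnorm(16, 0, 0.2))
fit_saturation(titration(conc, fnorm))
```

## Known limitations

* Flank matching tolerates substitutions only; an indel in a flank
  shifts the frame and the read is lost. Indel-tolerant matching would
  require alignment and is out of scope.
* Collapse is exact-identity: two reads of the same molecule differing by
  one insert substitution count as two sequences. Clustering of
  near-identical sequences into families is deliberately not provided.
* The candidate threshold is a raw read count; with very deep sequencing
  a fixed count cut admits more background, and `min_count` should be
  raised or an RPM-based cut applied via the enrichment table.
* The simulator's closed-form error calculus holds for the default
  exact-match extraction; with `max_mismatch > 0` the pass probability
  becomes a Binomial tail sum per flank and is checked empirically, not
  in closed form.
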