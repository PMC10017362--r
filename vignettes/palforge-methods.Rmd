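---
title: "Methods: consensus legumain design and ligase characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus legumain design and ligase characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palforge)
```

## The problem

Plant legumains (asparaginyl endopeptidases, AEPs) hydrolyze peptide bonds
C-terminal to Asn/Asp (the P1 residue). A small subfamily — peptide
asparaginyl ligases (PALs) such as butelase-1 and VyPAL2 — runs the same
chemistry in reverse, forming peptide bonds at Asx and enabling head-to-tail
macrocyclization of peptides. `palforge` implements the computational arm of
a two-step engineering strategy for producing a PAL without any natural PAL
template:

1. **Consensus design.** From a large aligned legumain family, take the most
   frequent residue of each alignment column, after removing columns whose
   *occupancy* (non-gap fraction) falls below a threshold. The consensus is
   then packaged into an expression construct by replacing the signal
   peptide plus the nonconserved prodomain region with an N-terminal His6
   tag and the unstructured C-terminal tail (after a designated conserved
   Pro) with a C-terminal His6 tag.
2. **LAD mutation.** Two conserved glycines flanking the S1 Asx-binding
   pocket act as ligase-activity determinants (LADs). Gly at both sites is
   AEP-like; the hydrophobic residues found there in natural PALs (Val at
   LAD1, Ala at LAD2) steer the enzyme toward ligation. The canonical panel
   from a Gly/Gly parent is LAD1→Val, LAD2→Ala, and the double mutant.

The package also provides the measurement side: exact product masses for
Asx-specific cleavage, cyclization, ligation and splice cascades;
initial-rate estimation; Michaelis–Menten fitting; cyclization/hydrolysis
(C/H) ratios; and pH/temperature optimum profiling.

## Consensus model and its conventions

For a family of $N$ aligned sequences, column $j$ has

- occupancy $o_j = (\text{non-gap count})/N$,
- conservation $c_j$ = modal fraction among non-gap symbols,
- consensus residue = the most frequent *designable* residue.

Numerical conventions, chosen where the procedure is usually left to an
alignment viewer:

- **Threshold comparison is strict**: columns with $o_j <$ threshold
  (default 0.10) are removed; a column at exactly the threshold is kept.
  Removal is applied per column; contiguous low-occupancy regions fall out
  as a consequence.
- **Tie-break**: among residues sharing the maximal count the earliest in
  the fixed order `ARNDCQEGHILKMFPSTWYV` wins. Any fixed order gives a
  deterministic, reproducible consensus; this one is the conventional
  single-letter listing order.
- **Ambiguity codes** X/B/Z/U count toward occupancy (they are observed
  residues) but can never become the consensus residue — they are not
  designable — unless a column contains nothing else.
- Alignment columns, consensus positions and reference residue numbers are
  three separate 1-based coordinate systems; conversion is only ever done
  through an explicit `map_to_reference()` object, and a position whose
  column was trimmed resolves to an error, never a silent shift. This
  matters because LAD positions are quoted in one enzyme's numbering while
  construct boundaries are quoted in another's (the reference map fixture
  in the tests reproduces a 12-residue numbering offset of exactly this
  kind).
- Construct boundaries (the prodomain split point and the conserved Pro
  before the C-terminal tail) are *inputs* (`region_annotation()`), not
  constants: they are defined structurally, not by consensus coordinates,
  so hard-coding them would tie the package to one particular family.

## Mass model

Linear peptide mass = sum of residue masses + one water; head-to-tail
cyclization removes exactly that water; each disulfide removes two
hydrogens. Both monoisotopic (water 18.010565 Da) and average (18.0153 Da)
conventions are always computed, because published product tables mix them
— e.g. an 18-residue substrate is quoted at its average mass while a
16-residue one matches its monoisotopic mass. Integer comparisons use
round-half-away-from-zero. Conservation laws hold to better than $10^{-6}$
Da by construction and are property-tested on 1000 random peptides:

- hydrolysis: $m(\text{substrate}) + m(\text{H}_2\text{O}) =
  m(\text{N-frag}) + m(\text{C-frag})$
- cyclization: $m(\text{cyclic}) + m(\text{leaving}) = m(\text{substrate})$
- ligation: $m(\text{ligated}) = m(\text{prefix}) + m(\text{acceptor}) -
  m(\text{H}_2\text{O})$

Recognition-motif checks (P1′ ≠ Pro, P2′ hydrophobic, P1″ Gly-favoured,
P2″ hydrophobic) produce *warnings*, not refusals: substrates violating the
motif still react, only less efficiently. The default hydrophobic set is
{F, I, L, M, V, A, W, Y}, with the experimentally favoured F/I/L/M at its
core; it is configurable. The minimum ring size defaults to 5 residues —
smaller backbone macrocycles are chemically implausible, and the smallest
ring of practical interest here is a decapeptide.

```{r}
predict_splice_cascade("AINGLRRGYSGSDALEG", 3, 13)
```

## Kinetics

Initial rates are the OLS slope (free intercept) over the samples with
conversion ≤ 15% of substrate, requiring ≥ 3 eligible points; quench-based
assays state no linearity criterion, so a fixed early-conversion window is
the reproducible substitute.

Michaelis–Menten parameters come from direct nonlinear least squares of
$v = V_{max} S / (K_M + S)$ — never a Lineweaver–Burk linearization, which
distorts the error structure. Initialization is $V_{max,0} = 1.1 \times
\max v$, $K_{M,0} = \mathrm{median}(S)$; the `port` algorithm is used
because it tolerates the zero-residual (noiseless) case and enforces
positivity; rates are normalized to a maximum of 1 before fitting so the
$10^{-10}$ residual-norm tolerance is scale-free and the fit is exactly
scale-equivariant. Two failure modes are reported explicitly rather than
silently: solver non-convergence, and a $K_M$ driven to the boundary (or
with non-finite standard error), which means the concentration design does
not identify it — e.g. saturation-only data. $k_{cat} = V_{max}/E_0$ and
$k_{cat}/K_M$ is reported in M⁻¹s⁻¹.

C/H ratios use percentage shares with equal HPLC response factors unless a
calibration is supplied. When nothing is hydrolyzed the ratio is undefined
(NA), not infinite; when nothing is cyclized it is 0. The optimum profiler
reports the argmax over the measured (pH, temperature) grid only — no
interpolation — with ties returned as a set.

## What the synthetic generators emulate — and what they do not

The 1500-sequence legumain family behind the original consensus is not
deposited, so the pipeline is validated on generated data with known truth:

- `generate_family()` draws each core column independently: the truth
  residue with the stated per-column conservation (default 0.9), otherwise
  uniform over the other 19. Insert blocks are extra columns carried (with
  random residues) by a small Bernoulli fraction of members (default
  use-case 5%, below the 10% trim threshold) and gapped elsewhere. The
  truth record stores the *realized* per-column occupancy.
- `generate_lad_variants()` labels sequences AEP-like (Gly/Gly) or PAL-like
  (double, LAD1-only, LAD2-only mutation patterns, cycling in that order so
  a single PAL variant is the double mutant); background substitutions
  (default 1% per residue) never touch the LAD or protected catalytic
  positions, so labels stay valid by construction.
- `generate_rate_data()` uses the published kinetic scenario as defaults:
  10 nM enzyme, a 1–100 µM substrate series, multiplicative Gaussian noise
  at 2% CV truncated at zero.
- `generate_product_profiles()` makes the C/H ratio logistic in pH
  (midpoint 6.5, asymptote 25, converted fraction 0.45) — the empirical
  pattern of cyclization overtaking hydrolysis with rising pH.

All randomness flows from one explicit seed per call and the caller's RNG
state is restored afterwards.

These generators deliberately do **not** model phylogenetic correlation
between sequences, substitution-matrix biases, alignment error, family
redundancy, or MALDI peak shapes. A green consensus-recovery test
establishes that the occupancy/consensus machinery is correct on
independent-column families — not that the historical 1500-sequence
consensus is reproduced, which would require the undeposited dataset.

## Design choices in genuinely open territory

- Whether occupancy in the original analysis was computed before or after
  duplicate removal is unstated; here occupancy is always computed on the
  family as given.
- The published efficiency of the Asp substrate (6431 M⁻¹s⁻¹) differs
  slightly from the quotient of its published $k_{cat}$ and $K_M$
  (0.32/49.54 µM ≈ 6459), presumably from rounding of $k_{cat}$; only the
  self-consistent Asn-substrate row is used as an exact target, and the
  ≥ 80-fold preference claim holds under either reading.
- One substrate is spelled inconsistently across the original text and a
  figure legend (A vs S at position 14); the main-text spelling
  `AINGLRRGYSGSDALEG`, consistent with the printed 1735 Da monoisotopic
  mass, is used throughout.

## Limitations

Sequence-level classification (AEP-like/PAL-like) predicts the *direction*
of engineering, not quantitative ligase efficiency; structure-based pocket
analysis, stability prediction and pH-partitioning mechanisms are out of
scope. The consensus machinery assumes a trustworthy input alignment — it
does not run or audit the MSA.
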