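---
title: "Models and methods behind cycloPan"
author: "cycloPan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cycloPan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloPan)
```

# Scope

cycloPan analyses multi-round phage-display biopanning campaigns of
macrocyclic peptide libraries: it decodes degenerate-codon libraries
(including amber-suppressed non-canonical residues), turns per-round FASTQ
into peptide count tables, quantifies enrichment, diversity and
cross-strategy overlap, ranks consensus hits, featurizes and embeds top
peptides, and fits 1:1 biosensor kinetics for hit validation. Because raw
selection NGS data are rarely public, the package ships a generative
simulator of the whole selection process with planted ground truth; every
analysis stage is exercised against it.

# Library schemas and decoding

A `LibrarySchema` is an ordered pattern of fixed and randomized codon
positions plus constant flanking DNA. Two schemas are built in:

* `schemaCX10AcrK()` — a fixed N-terminal Cys, ten NNK positions, and a
  fixed TAG codon read through by amber suppression as AcrK
  (N-epsilon-acryloyl-lysine). The acryloyl group closes a thioether
  macrocycle with the Cys, so the displayed entity is a cyclic 12-residue
  chain whose last residue is non-canonical.
* `schemaCX12C()` — twelve NNK positions flanked by two cysteines, cyclized
  chemically after expression by a bifunctional linker. No suppression
  operates here; an NNK draw of TAG is a genuine stop and the clone is
  rejected at translation.

Decoding rules worth stating once: suppression overrides are applied
*before* stop rejection (suppression is the library's design principle, not
an error path); residue positions are 1-based while DNA intervals are
0-based half-open; non-canonical residues are multi-character tokens, never
single letters, and serialize in parentheses (`"CWRVFIWGQGP(AcrK)"`), so a
20+n alphabet survives any text round trip. The constant flanks are not
published for any specific experiment; they are configuration, with fixed
simulator defaults.

# The selection simulator

`runCampaign()` simulates, per clone $i$ and round $r$ with resin $\rho$:

$$\theta_i = \frac{T_r}{T_r + K_{D,i}}, \qquad
  c_i = 1-(1-\theta_i)(1-\sigma_{i\rho})(1-c_0), \qquad
  q_i = q_{ns} + (1-q_{ns})\max(\theta_i, \sigma_{i\rho})$$

with eluted weight $e_i = a_i\,(1-\sigma_{i\rho})^{k_{neg}}\,c_i\,q_i^{W_r}$
when the round carries a negative selection, followed by amplification
$a'_i \propto e_i\, g_i\, e^{\eta_i}$, $\eta_i \sim N(0,\tau)$. Sequencing
draws multinomial counts at the round's depth and, in FASTQ mode, adds
i.i.d. per-base substitution errors. All randomness flows from one seeded
generator; the stream order is: library generation, then rounds in schedule
order (amplification noise, then sequencing draws per round), so identical
seeds give byte-identical FASTQ.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| rounds, washes | 4; 8,10,10,10 | the standard escalating-stringency protocol |
| target load | 10, 5, 2, 1 µg | stepwise target reduction across rounds |
| `targetScale` | 20 µM/µg | bead-local effective concentration is far above bulk; keeps a 5 µM binder at $\theta \ge 0.8$ in the final round so the weakest plausible hit remains recoverable at the default depth |
| `qNs` | 0.8/wash | ~1000-fold non-specific depletion per 10-wash round, the usual panning range |
| `c0` | 0.01 | baseline carry-over capture |
| binders | 5, $K_D$ log-uniform 50 nM–5 µM | the affinity window of realistic primary hits |
| stickiness | 5%/resin, $\sigma = 0.9\,\mathrm{Beta}(5,2)$ | a visible minority of resin parasites per chemistry, independent across resins — exactly the confound resin alternation removes |
| abundance | lognormal, sdlog 1 | heavy-tailed transformant clone sizes |
| fitness, $\tau$ | lognormal sdlog 0.2; 0.3 | growth bias and amplification noise |
| depth, $\varepsilon$ | $10^5$; $10^{-3}$ | desk-scale Illumina-like sequencing |

What the simulator does *not* emulate: indels and quality-correlated errors,
suppression efficiency at the ribosome, avidity effects, carry-over between
rounds, PCR jackpotting beyond lognormal amplification noise, and paired-end
reads (a $\le$ 45 nt variable region fits comfortably in one read).
Passing tests therefore demonstrate correctness of the analytics under a
plausible generative model, not performance guarantees on any particular
real campaign.

# Ingest

Demultiplexing parses the `i7+i5` pair from Illumina-convention headers and
assigns each read to the unique sheet entry within a Hamming tolerance of 0
or 1; equidistant ties are dropped as `index-unmatched` rather than guessed.
Variable regions are located by exact (optionally 1-mismatch) 5' flank
match, length-checked against the schema, verified against the 3' flank,
and mean-Phred filtered (default Q20). Every read ends in exactly one bucket
— kept, or one of seven drop reasons — and `kept + sum(dropped) == total` is
enforced as a class invariant, so no filter can silently eat reads.

# Enrichment analytics

Frequencies are counts over sample totals. The round-over-round enrichment
ratio is $(f_r + p)/(f_{r-1} + p)$ with a half-read pseudo-frequency
$p = 0.5/N_{r-1}$: no published formula exists for this quantity, and the
Jeffreys-style half count keeps de-novo appearances finite while leaving
ratios of well-sampled peptides essentially untouched. Overlap regions are
exact set algebra; a region's pooled abundance share is read-weighted by
default (summed counts of the region's peptides across the compared samples
over those samples' total reads) with a unique-sequence mode one flag away,
since published "fraction of the pool" figures rarely state which
convention they use. Consensus ranking uses competition ranks ("1224") per
strategy and the *worst* per-strategy rank as the consensus — a peptide must
enrich under every immobilization chemistry to rank well. Candidates enter
at a final-round frequency above 0.1% in at least one strategy; candidates
absent from any strategy are flagged `strategyRestricted` instead of ranked,
which is precisely how resin parasites announce themselves.

# Descriptors and embedding

GRAVY uses Kyte–Doolittle hydropathy; net charge is a Henderson–Hasselbalch
sum over an EMBOSS-style pKa set (termini excluded by default — the termini
of these macrocycles are blocked or consumed by cyclization); the aliphatic
index follows Ikai. "Sequence composition" is realized as the
monomer-frequency vector rather than positional one-hot, because the two
libraries mix lengths and scaffolds. AcrK defaults to lysine-like
hydropathy (−3.9), no ionizable side chain (the ε-amine is acylated), and
zero aliphatic weight; every non-canonical token must carry such an
override, and all scales are user-replaceable. The scaffold cysteines stay
in the descriptors by default (they are part of the displayed macrocycle).

Features are z-scored (zero-variance columns dropped and recorded), embedded
by UMAP (n_neighbors 15, min_dist 0.1, Euclidean; single-threaded and seeded,
hence reproducible) with a deterministic PCA projection as the alternative,
then clustered by DBSCAN. The DBSCAN default is eps 1.5 embedded units with
minPts 5: measured on this UMAP backend, nearest neighbours within one
island reach ~0.6 units while distinct islands sit more than 10 apart, so
eps 1.5 merges islands correctly and cannot bridge them. The
cluster-recovery fixture lives at the descriptor level (two Gaussian clouds
separated by ≥ 10 within-population SDs in GRAVY and charge): z-scoring
gives every retained column unit variance, so a sequence-level fixture
cannot maintain a stated SD separation in the presence of discrete
composition columns.

# Kinetics

The 1:1 model is closed form: association
$R(t) = R_{eq}(1-e^{-k_{obs}(t-t_a)})$ with $k_{obs} = k_{on}C + k_{off}$
and $R_{eq} = R_{max}C/(C+K_D)$; dissociation decays from $R(t_d)$ at
$k_{off}$. Mass transport is deliberately not modeled. The global fit
shares one $(k_{on}, k_{off}, R_{max})$ across traces — per-trace amplitudes
are off by default, matching the plainest reading of a global 1:1 fit — and
adds per-trace baseline offsets. Optimization runs on log-parameters with
physical bounds, seeded by a per-trace profiled single-exponential fit of
$k_{obs}$ regressed on concentration, plus perturbed restarts; standard
errors come from the Jacobian by the delta method, and non-convergence is a
flag in the result, never silent. Phases are unweighted. Alanine-scan fold
changes $K_D^{var}/K_D^{parent}$ classify as neutral (< 2), mild ([2, 4]),
intermediate ((4, 9]) and essential (> 9); the (4, 9] band gets an explicit
name so the classes are exhaustive and boundary behaviour is testable
(fold 9 is intermediate; folds 2 and 4 are mild).

# Problem sizes and reproducibility

The bundled study conditions are $10^4$ background clones plus 5 planted
binders, three parallel four-round strategies, depth $10^5$ per round, and
20-seed replication for stochastic claims; kinetic studies use 5
concentrations spanning 16-fold around $K_D$ at 1% amplitude noise. The
consensus/overlap studies run the simulator in count mode (multinomial
counts straight into the `PoolTable`); FASTQ serialization and re-ingest are
validated separately at smaller depth, where error-free round trips must
reproduce the emitted counts exactly. `runPipeline()` stamps every table
with the run seed and config hash, and identical configs reproduce
identical tables byte for byte.

# Known limitations

Single-target campaigns only (no competitive/negative-target designs beyond
bead-only negative selection); no indel-tolerant flank matching; no UMI
support; enrichment significance is not modeled (no error model for
round-to-round counts is attempted); the kinetic module covers 1:1 binding
only — heterogeneous-ligand and transport-limited regimes are out of scope,
though the misfit of such data against the 1:1 model is detectable through
its residuals.
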