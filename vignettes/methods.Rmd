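---
title: "Structure-implicit goal-directed molecular design: model, reward, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-implicit goal-directed molecular design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`molahc` implements a complete goal-directed generative design loop for
small molecules: a SMILES chemical language model (CLM) is pre-trained
by maximum likelihood on a curated drug-like corpus, then fine-tuned by
Augmented Hill-Climb (AHC) reinforcement learning against a
five-component desirability reward whose structure-based term comes
from a pluggable oracle. The package ships a deterministic synthetic
corpus generator and an analytically checkable mock oracle so the whole
loop can be exercised, tested, and reproduced on a CPU in minutes.

This vignette records the model, the reward, and the design decisions
that were genuinely open, in enough detail that a maintainer can judge
what each passing test does and does not establish.

# The chemical language model

The CLM is an autoregressive model over SMILES tokens. A SMILES string
is tokenized into chemically atomic units (bracket atoms, two-letter
elements, `%nn` ring closures, single characters), framed as
`GO, x_1, ..., x_N, EOS`, and modelled as

$$\mathcal{L}(\theta) = -\sum_{i} \log P(x_i \mid x_{i-1}, \dots, x_0),$$

the negative log-likelihood of each token given its prefix, trained
with teacher forcing. The network is an embedding layer followed by a
stack of gated recurrent units (GRU) and a softmax output projection.
The reference architecture is an embedding of 256 with 3 GRU layers of
hidden size 512 (the `clm_config()` defaults); training defaults are 5
epochs, batch size 128, Adam at learning rate 0.001. The GRU forward
pass, full backpropagation through time, multinomial sampling and
sequence log-likelihood evaluation are implemented in compiled code
(RcppArmadillo) and verified against finite-difference gradients in the
test suite.

Choices the architecture description leaves open, resolved as follows:

* **Maximum sequence length** is 128 tokens. Sampled sequences that hit
  the cap without emitting `EOS` are flagged truncated and scored as
  invalid.
* **Loss reporting** uses the per-token mean NLL (comparable across
  corpora); the sequence *sum* is what enters the reinforcement-learning
  update, since the augmented-likelihood rule operates on sequence
  log-likelihoods.
* **Tokenizer**: character-level with multi-character atoms as single
  tokens. The vocabulary is the sorted set of corpus tokens plus
  reserved `GO`/`EOS`/`PAD`.
* **Augmentation**: 10-fold restricted SMILES randomisation. Each
  molecule's connection table is rewritten under a random atom
  permutation and re-serialized non-canonically, so every variant
  re-canonicalizes to the same molecule (the test suite asserts 100%
  label preservation). The ten variants per molecule are drawn once,
  deterministically from the training seed, and reshuffled each epoch;
  drawing fresh variants every epoch would multiply the standardisation
  cost without changing the augmentation multiplicity, and fixing the
  pool keeps pre-training bit-reproducible.

# Corpus curation

The curation pipeline mirrors standard drug-like corpus preparation:
each raw SMILES is lexically checked, reduced to its largest organic
fragment, charge-neutralized where valence permits, canonicalized, and
filtered to: predicted logP $\le$ 4.5, rotatable bonds $\le$ 7,
molecular weight 150–650 Da, elements within {C, S, O, N, H, F, Cl,
Br}, and no structural-alert match. The alert engine is generic over
any SMARTS pattern file; the shipped default is a compact
reactive-group set (acyl/sulfonyl halides, anhydrides, peroxides,
azides, isocyanates, strained three-membered heterocycles, Michael
acceptors, ...). Activity-based database filters (potency and assay
confidence) are a database query, not chemistry; the synthetic corpus
generator stands in for them.

The curated set is then evened out by scaffold-cluster undersampling:
leader (sphere-exclusion) clustering on the ECFP4 Tanimoto similarity
of Bemis–Murcko scaffolds at threshold 0.8, keeping only cluster
leaders. Leader clustering was chosen because the clustering algorithm
is otherwise unspecified: it is deterministic given input order, linear
in the number of clusters, and the test suite pins it against a
brute-force double-loop oracle.

All chemistry (canonicalisation, properties, fingerprints, SMARTS,
connection tables) is delegated to OpenBabel through ChemmineOB. Two
wrinkles are worth recording. First, OpenBabel parses some malformed
SMILES leniently (`"C("` parses as methane), so validity is defined as
*lexical* well-formedness (balanced branches, paired ring closures,
known tokens) *and* a successful toolkit parse. Second, logP is
OpenBabel's atomic-contribution (Wildman–Crippen parameterised)
estimate; other toolkits' Crippen implementations differ in the second
decimal for some molecules, which is irrelevant at the granularity of
the desirability transform but worth knowing when comparing numbers
across toolkits.

# The desirability reward

The reward of a molecule is the arithmetic mean of five components,
each in $[0, 1]$:

$$R = \tfrac{1}{5}\,(S_{dock} + S_{synth} + S_{logP} + S_{crot} + S_{hbd}).$$

* **Docking component.** The raw oracle score $ds$ (lower is better) is
  normalized against the minimum and maximum oracle scores observed so
  far in the run, in reverse:
  $S_{dock} = (ds_{max} - ds)/(ds_{max} - ds_{min})$, clipped to
  $[0,1]$. The extrema are cumulative over the whole run, are updated
  with each batch *before* that batch is normalized, and are never
  touched by invalid molecules. When only one distinct value has been
  observed the transform returns the neutral 0.5 rather than dividing
  by zero.
* **Synthesisability** is a plug-in returning a probability in
  $[0, 1]$, used untransformed. The contract is enforced: out-of-range
  values raise an error, a failing plugin scores 0 with a warning. The
  default surrogate maps a molecular-complexity estimate (heavy-atom
  count plus a fused-ring-junction penalty) through a decreasing
  logistic; it is a structural heuristic standing behind the plug-in
  interface, not a retrosynthesis model.
* **logP** uses the piecewise soft/hard-limit transform: score 1 inside
  the soft window $[1, 3]$, 0 at or beyond the hard limits $[0, 4]$,
  linear in between.
* **Consecutive rotatable bonds** and **hydrogen-bond donors** use the
  same transform with the soft limit equal to the hard limit (a step):
  1 at 3 or below, 0 at 4 or more. "Consecutive" means the longest
  chain of rotatable bonds in which successive bonds share an atom; a
  rotatable bond is an acyclic single bond between two non-terminal
  heavy atoms, with amide C–N bonds excluded by default (a strict,
  configurable convention — the pattern is not pinned down by the
  component's definition).

Invalid molecules (unparsable, truncated at the length cap, or
net-charged after neutralisation) receive reward 0 with all components
0. Property tests assert that every component and the aggregate stay in
$[0,1]$ over random molecules and extrema, that the docking transform
is monotone decreasing in $ds$, and that the piecewise transform is
continuous with its plateau exactly on the soft window.

# Augmented Hill-Climb

AHC couples a frozen prior policy (the pre-trained CLM) to a trainable
agent initialized from it. Per step, the agent samples a batch
(default 64), molecules are scored, and only the top-$k$ fraction
(default $k = 0.5$, so 32 molecules) by reward enter the update, which
minimises

$$\mathcal{L}(\theta) = \big[\pi_{aug} - \pi_{agent}\big]^2,
\qquad \pi_{aug} = \pi_{prior} + \sigma R$$

with $\sigma = 60$, over 200 steps by default — 12,800 molecules
sampled per run. One point deserves prominence: with $\pi$ denoting a
sequence *log-likelihood*, a high reward must *raise* the target, so
the reward term is added; conventions that write the same rule with a
minus sign read $\pi$ as a negative log-likelihood. The implementation
and all tests use the log-likelihood convention.

A scaffold diversity filter penalises repeated exploration: each valid
molecule increments a run-level count for its Bemis–Murcko scaffold,
and once a scaffold exceeds its bucket (default 25 occurrences) further
molecules on it are zero-rewarded before top-k selection. The filter's
memory structure and threshold are an explicit design choice — the
mechanism is only qualitatively constrained by its purpose — and the
bucket size is configurable, with `Inf` disabling it.

Other loop details: invalid molecules stay in the batch (they can enter
the top-k only at the bottom) and never touch extrema or the diversity
filter; ties in top-k selection resolve stably by batch order; one Adam
update per step at the pre-training learning rate; the prior's
parameters are asserted bit-identical before and after a run.

# Synthetic fixtures and the mock oracle

The fixture generator emulates a curated drug-like training corpus by
combinatorial scaffold decoration: 12 drug-like ring-system templates
(quinazoline, benzimidazole, biphenyl, anilide, phenylpiperazine, ...)
crossed with 24 substituents, enumerated in a seed-shuffled order,
standardized, and filtered until the requested number of unique,
curation-passing molecules is collected. Generation is a pure function
of the spec and seed (asserted bit-identical across runs). The default
corpus used throughout the tests is 2,000 molecules at seed 42.

What the fixtures do *not* emulate: real bioactivity corpora have
heavier tails in size and flexibility, stereochemistry, charged
species, and far more scaffold diversity (a production corpus is two
orders of magnitude larger). Passing the learning tests on fixtures
demonstrates that the machinery optimises its reward on a realistic
token grammar; it says nothing about hit rates against a real target.

The mock oracle is a deterministic test double for a docking engine:

$$ds = -(2\,n_{arom} + n_{HBA}) + 0.7\,c_{rot}$$

(aromatic rings, Lipinski N+O acceptors, maximum consecutive rotatable
bonds; lower is better). It was chosen to be analytically checkable
and improvable by the policy — it rewards exactly the kind of
ring-rich, acceptor-rich, rigid chemistry the corpus grammar can
express more or less of. It is explicitly not a docking surrogate.

# Chemotype analytics

Generated molecules are assessed the way ligand-discovery campaigns
assess de novo output:

* **Bemis–Murcko scaffolds**: ring systems plus linkers, substituents
  pruned (terminal atoms removed iteratively; exocyclic double-bonded
  atoms such as carbonyl oxygens retained). Acyclic molecules yield the
  empty scaffold and are pooled in a reserved cluster excluded from
  chemotype derivation — how scaffold-less molecules were grouped is
  otherwise unspecified, and a reserved bin keeps the partition total.
* **Clustering**: leader clustering on scaffold ECFP4 Tanimoto at a
  permissive cut-off of 0.2 (the similarity required to join a
  cluster).
* **Chemotypes**: the maximum common connected substructure of each
  cluster with at least 3 members, kept when it has at least 6 heavy
  atoms (a floor that prevents trivial one- or two-atom "chemotypes").
  The MCS is a McGregor-style backtracking search over
  element/aromaticity-labelled atoms and bond orders, iterated pairwise
  across members, with an explicit node-expansion budget; exhausting
  the budget flags the cluster rather than silently returning a wrong
  core.
* **Matching** is substructure containment (monomorphism), not exact
  scaffold equality — a molecule "possesses" a chemotype if the pattern
  embeds in it. Matching runs on labelled graphs via subgraph
  isomorphism with a bond-order post-check, because an MCS pattern may
  omit a ring-closing bond and must still match its own members.
* **The funnel**: valid (parses), unique (first occurrence by canonical
  SMILES), novel (absent from a reference vendor set, by exact
  canonical membership — similarity-based novelty is a separate
  statistic), possessing a known chemotype. Known-active rediscovery is
  exact canonical identity against the actives set. Funnel
  monotonicity is asserted on every input.

# Numerical and procedural choices

* Desk-scale problem sizes used by the test suite: the 2,000-molecule
  fixture corpus, a CLM of embedding 64 with two GRU layers of hidden
  size 128 (the reference 256/3/512 architecture is the package
  default for real corpora), 5 pre-training epochs with 10-fold
  augmentation, and AHC runs of 50 steps at batch 32 over 5 seeds.
  These sizes were chosen so the full loop demonstrates its learning
  behaviour (falling held-out loss, ≥80% sampling validity, rising
  mean reward) at interactive cost.
* Desk-scale learning rate: the reference learning rate of 0.001 is
  tied to the reference corpus (~1.9M augmented sequences per epoch);
  the fixture corpus sees only ~860 updates in 5 epochs, so the
  desk-scale configuration trains at 0.005 — a scale adaptation, not a
  new default; `train_config()` keeps 0.001. The AHC update then uses
  the same learning rate as pre-training, per the optimiser
  convention above.
* Diversity filter at desk scale: the fixture grammar spans only about
  a dozen scaffold templates, so a 25-occurrence bucket saturates
  within a few steps of a batch-32 run and the measured reward curve
  then reflects the filter, not the optimiser. The desk-scale learning
  tests therefore run with the filter disabled; the filter's bucket
  mechanics are tested separately at the unit level.
* All randomness is seeded explicitly: corpus generation and
  augmentation through their spec/argument seeds, training through
  `train_config()`, sampling per call, AHC per step via a
  deterministic derivation from the run seed. Replaying a recorded run
  directory reproduces deterministic artifacts byte-identically.
* Oracle calls are cached by canonical SMILES within a scorer; whether
  duplicate molecules in a batch should share one oracle call is not
  externally constrained, and caching is the cheaper default (it can
  be disabled).
* Degenerate inputs: empty batches error early; empty scaffolds get
  all-zero fingerprints and pairs of empty scaffolds count as
  similarity 1; degenerate score extrema give the neutral 0.5.

# Known limitations

* OpenBabel's kekulisation rejects some exotic aromatic systems the
  sampler may emit; such strings count as invalid, which slightly
  understates validity relative to more permissive toolkits.
* The MCS search is exact only within its budget; very large
  homogeneous clusters can time out (flagged, never silently wrong).
* The synthesisability surrogate ranks complexity, nothing more; real
  campaigns should register a trained retrosynthesis-based plug-in.
* Novelty is exact-match novelty; near-duplicate analogues of vendor
  compounds count as novel, as in the rediscovery convention used
  here.
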