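---
title: "Designing RNA sequences by deep Q-learning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing RNA sequences by deep Q-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrnadesign)
```

## The problem

Inverse folding asks for a nucleotide sequence that folds into a prescribed
secondary structure. The target is given in dot-bracket notation; matched
brackets are base pairs, dots are unpaired positions, and additional bracket
tiers (`[]`, `{}`, `<>`) encode pseudoknots — pairs that cross, as in H-type
pseudoknots where a hairpin loop pairs with a downstream region. Supervised
sequence-to-sequence training is poorly suited to this task: paired
structure/sequence data are scarce and token-level likelihood ignores the
global folding constraint. `qrnadesign` instead treats design as
reinforcement learning against a folding environment.

## Markov decision process

The agent builds the sequence left to right. The state at step $t$ is the
partial sequence together with the full target structure; the action is the
base placed at position $t$, drawn from $\{A, C, G, U\}$ but masked to
canonical partners (A–U, G–C, G–U) whenever the target pairs position $t$
with an already-decoded 5$'$ partner (`valid_actions()`). Once the sequence
is complete the environment folds it and pays a per-position reward

$$
r_t \;=\; \mathbb{1}\!\left[\text{pairing status at } t \text{ matches the
target}\right]\cdot
\mathbb{1}\!\left[\text{SHAPE constraint satisfied at } t\right],
$$

where "pairing status" means the partner index or unpairedness, so pairing
with the wrong partner scores zero. The SHAPE term requires the reactivity
of an unpaired position to exceed `unpaired_min` (default 0.5) and that of a
paired position to stay below `paired_max` (default 0.25); both thresholds
are explicit arguments because mis-set thresholds silently degrade designs.
The SHAPE indicator is evaluated at the *target* pairing status: the product
only lets a position score when prediction and target agree, where the two
conventions coincide, and the target status is available even for positions
the fold got wrong. In structure-only mode (the default environment) the
SHAPE term is dropped.

Rewards are assigned post hoc from the completed sequence. Averaged over
many episodes, regressing on them estimates the expected future reward at
each position — exactly the action value the network is asked to produce.

## The environment

The environment is a pair of pure functions of the sequence: a fold
predictor and an optional SHAPE predictor (`design_env()`). Three return
types are accepted for folds — a structure object, a dot-bracket string, or
an $L \times L$ pairing-probability matrix. Matrices are reduced to a pair
set by maximum-weight one-to-one assignment (a Jonker–Volgenant Hungarian
solver in C++), keeping mutually assigned pairs with probability at least
`threshold` (default 0.5) after zeroing the band $|i-j| \le$ `min_loop`
(default 3), which removes sterically impossible pairs. This is the
attachment point for external neural predictors; nothing else in the
package changes when one is plugged in.

The shipped reference environment is deterministic and self-contained:

* `nussinov_fold()` maximises the number of canonical pairs subject to
  nesting and a minimum hairpin-loop span of 3, with a fixed traceback
  tie-break (prefer "position unpaired", then the smallest partner index) so
  folding is a pure function. The dynamic program is C++ ($O(L^3)$).
* `oracle_shape()` maps pairing status to idealised reactivities (0.1
  paired, 0.9 unpaired) with optional clipped Gaussian noise, seeded
  deterministically from the sequence so the environment contract (same
  sequence, same profile) holds.

What this environment does *not* model: thermodynamics (no stacking
energies, G–U treated like any pair), tertiary effects, kinetics, and the
degeneracy of real chemical probing. Tests passing against it demonstrate
the learning machinery and the algorithmic contracts, not wet-lab
designability; for realistic designs, plug in a trained structure/SHAPE
predictor.

A consequence worth knowing: maximum-pairing folding is highly degenerate,
and the "prefer unpaired" tie-break resolves ties by sliding helix ends
inward. Perturbing one stem pair of a solved hairpin therefore often yields
a fold whose mismatch against the target spans up to three adjacent pairs
rather than one. The rescue experiment below accounts for this.

## Action-value network

The network maps (target structure, sequence prefix) to an $L \times 4$
grid of action values, exactly four columns — the padding token gets no
value.

**Encoder** (`qnet_encode()`): learned embedding of the nine structure
tokens → LSTM positional encoding (a recurrent pass whose output is added
to the embeddings, replacing fixed sinusoids) → same-padded 1-D convolution
(local motifs) → contact-graph convolution, one round per layer of
degree-normalised neighbour aggregation with the contact matrix plus
self-loops followed by a learned linear map and tanh (long-range pairing
information) → post-norm multi-head self-attention blocks.

**Decoder** (`qnet_decode_full()`): the input is the sequence shifted right
with a START token; the paired/unpaired flag of the *output* position is
embedded and added at each slot, so the choice at $t$ is directly
conditioned on whether $t$ must pair (the alignment is a package choice —
the flag has to inform the decision it accompanies). LSTM positional
encoding and a causal convolution follow, then blocks of masked
self-attention, cross-attention over the encoder context, and feed-forward
layers, all post-normalised; a linear head emits the four action values.
Causality holds by construction (LSTM and causal convolution are
directional; the self-attention mask is strictly triangular) and is probed
directly in the tests.

`qnet_decode_step()` implements key-value cached stepwise decoding: per
layer the self-attention keys/values of past positions are cached,
cross-attention keys/values are precomputed once, and the LSTM state and a
$(k-1)$-row convolution buffer carry the recurrent context. Agreement with
full-grid decoding to $10^{-4}$ is the module's central correctness oracle
and is tested over random configurations; it is exact in practice because
both paths perform the same arithmetic.

Because no automatic-differentiation library is available to R here, the
package carries a small reverse-mode tape (`R/autograd.R`) with fused ops
(LSTM with backpropagation through time, attention, layer normalisation,
shifted-stack convolutions, embeddings). Its gradients are verified against
central finite differences across all parameter groups in the test suite —
the strongest guarantee we can give short of a reference implementation.

Default sizes (`qnet_config()`) are desk-scale: width 64, 2+2 layers, 4
heads, kernel 5, one graph-convolution round. The learning experiments use
an even smaller network (width 32, 1+1 layers, 2 heads, kernel 3): the
contribution is the training scheme, not capacity, and the small model
trains in seconds per round on one CPU.

## Twice-shifted action-value training

Each outer round alternates play and training (`play_episodes()`,
`train_epoch()`):

1. **Play**: decode each target greedily with probability $\varepsilon$
   (default 0.1–0.15) of a uniformly random valid action per position; fold;
   compute rewards; store (structure, sequence, reward) records. The
   experience store is consumed once per round — the alternation *is* the
   replay scheme; a multi-round buffer is deliberately not the default.
2. **Reward reweighting**: $r_t \leftarrow r_t \exp(\bar r)$. A linear
   reward gives vanishing gradient for pushing 95%-correct sequences to
   100%; the exponential factor (between 1 and $e$) boosts good episodes.
   It never changes which positions are zero.
3. **Discounting**: $\gamma_t = \gamma_{start} - \frac{t}{L-1}
   (\gamma_{start} - \gamma_{end})$, defaults 0.95 → 0.5. Early decisions
   constrain everything downstream and should look far ahead; late
   decisions are local. A length-1 sequence degenerates to
   $\gamma_{start}$.
4. **TD targets**: $\hat Q_t = r_t + \gamma_t \max_{a'} Q_{\theta^-}(s_{t+1},
   a')$, with the frozen network's per-position maxima shifted left and the
   terminal slot set to zero (episodic convention: no successor state).
   Both the decoder input (right-shifted) and the targets (left-shifted)
   are offset — hence "twice-shifted".
5. **Loss and update**: squared error between the predicted values at the
   taken actions and the TD targets, minibatch Adam (default learning rate
   $10^{-3}$; the learning experiments use $2\times10^{-3}$) under a global
   gradient-norm clip (default 5). The frozen network stays fixed within a
   round and is synchronised every `target_sync_epochs` rounds (default 5).

The learning acceptance experiment trains on 50 random hairpin targets of
length 20 (stems 3–8, so helices are stably stacked and loops satisfy the
span rule) for 30 rounds and evaluates greedy decoding on 20 held-out
hairpins. Mean episode reward rises (typically from ~0.73 to ~0.91) and all
20 held-out targets are solved exactly at the tested seed; the ≥ 80% bar
leaves room for seed variation. The run takes under a minute on one CPU —
problem sizes were chosen so the full suite stays fast, not because larger
curricula fail.

## Inference and screening

* **Greedy / beam** (`beam_search()`): beams are scored by summed selected
  Q-values — cumulative action value, not a log-likelihood; the quantity has
  no probabilistic interpretation but ranks expected structural fidelity.
  Ties break lexicographically so results are deterministic. Width 1 is
  greedy; a width of $4^L$ recovers exhaustive enumeration, which the tests
  exploit on length-4 targets.
* **Random search** (`random_search()`): per position, uniform over valid
  actions with probability `uniform_prob`, otherwise softmax of the values
  at `temperature`; seeded.
* **Rescue** (`rescue()`): positions whose pairing status disagrees with
  the target are grouped into target pairs (plus target-unpaired singles);
  if at most `max_mismatch_pairs` pairs are involved, all 6 canonical
  assignments per pair and 4 bases per single are enumerated and refolded,
  returning the first exact match, else the best Jaccard improvement, else
  nothing. The default cap is 2; the repair *experiment* calls it with cap
  3 because of the tie-break register shifts described above — one broken
  pair usually surfaces as two or three mismatched pairs. The experiment's
  fixtures (`make_solved_hairpins()`) use Watson–Crick stems with inert
  all-A loops and break one stem pair by mutating its 5$'$ base to A, a
  non-complement that cannot itself create new pairing potential; under
  this protocol rescue restores ≥ 95% of cases. Perturbations that insert
  pairable bases (e.g. U next to an A-rich loop) can rearrange the
  maximum-pairing fold globally and are not locally repairable by any
  mismatch-bounded procedure.
* **Screening** (`screen()`): candidates are folded and SHAPE-profiled by
  the environment (or a supplied measured profile), deduplicated, and
  ranked by (Jaccard, OpenKnot) descending.

## Screening metrics

SHAPE profiles are normalised to a 90th percentile of 1, using linear
interpolation between order statistics — the convention is fixed and
documented because percentile definitions differ across tools. The Eterna
Classic Score is 100 × the fraction of residues consistent with their
pairing status: a paired residue is penalised when reactivity exceeds 0.5,
an unpaired one when it falls below 0.125; values exactly at a threshold
count as consistent (the penalties are strict inequalities). The Crossed
Pair Quality Score applies the same rule only to residues in crossing pairs
after removing singlets (isolated pairs with no stacked neighbour — the
standard meaning), optionally downweighting residues whose partner lies in
a user-declared flanking region (weight 0.5 by default; the flanking
intervals default to empty because they are a property of the design
construct, not of the structure). A structure with no crossing pairs scores
CPQ 0 — a design that forms no pseudoknot earns no crossed-pair credit; the
alternative convention (omit the term) would make hairpins score 100 on a
pseudoknot metric. The OpenKnot score is the arithmetic mean of the two.

## Numerical and degenerate-input choices

* Positions are 0-based inclusive everywhere; pairs are stored with
  $i < j$. Four bracket tiers are supported; deeper pseudoknot orders raise
  an error naming the required tier count.
* Jaccard of two empty pair sets is 1 (two open chains agree).
* Normalising an all-zero SHAPE profile is an error, not a silent no-op.
* The stepwise/full decoder equivalence tolerance is $10^{-4}$;
  finite-difference gradient checks use $10^{-4}$ relative tolerance at
  step $10^{-5}$.
* All stochastic entry points take a seed and restore the caller's RNG
  state; identical (seed, config) reruns are bitwise identical, which the
  run manifests rely on.
* Network checkpoints embed their configuration and format version;
  loading with a structurally different configuration is an error (the
  weight-initialisation seed is not part of structural identity).

## Known limitations

* The reference environment is a maximum-pairing folder: no energies, heavy
  tie degeneracy, and G–U treated like canonical Watson–Crick pairs.
  Learning results against it do not transfer claims to real RNA.
* Training is single-process; there is no distributed episode gathering,
  no prioritised replay, and no mixed precision.
* The hand-written network is desk-scale; widths beyond a few hundred or
  sequences beyond a few hundred nucleotides will be slow in R.
* Rescue is bounded enumeration: mismatches beyond the pair cap or the
  variant cap are declined rather than searched heuristically.
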