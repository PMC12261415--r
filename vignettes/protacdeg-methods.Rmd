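---
title: "Methods: equivariant graph learning for PROTAC degradation prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivariant graph learning for PROTAC degradation prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

A PROTAC (proteolysis-targeting chimera) is a heterobifunctional molecule:
a warhead that binds a protein of interest (POI), a linker, and a ligand
that recruits an E3 ubiquitin ligase. Degradation proceeds through the
ternary POI–PROTAC–E3 complex, so whether a candidate degrades its target
depends jointly on the 3D geometry of the molecule and of both binding
pockets. `protacdeg` predicts a binary degradation-activity class from
three attributed 3D graphs — the PROTAC molecule and the two pockets —
plus the molecule's physicochemical profile.

Activity labels come from the standard annotations: a compound is **low**
activity iff DC50 ≥ 100 nM *and* Dmax < 80%, otherwise **high**. When only
one annotation is present the conjunction degenerates to the available
clause; with neither, the entry is unlabeled. `assign_activity_label()`
implements exactly this rule, including its boundary behaviour (DC50 =
100 nM with Dmax = 80% is high, because Dmax < 80 fails).

## Graph construction

PROTAC molecules are read from TRIPOS mol2 (`parse_mol2()`): atoms are
nodes, bonds are edges, coordinates are taken verbatim; hydrogens are
dropped by default so the graphs stay small and match common practice in
pocket-scale modeling (a `keep_hydrogens` flag retains them). Protein
pockets are defined by the classical distance rule: every residue with at
least one heavy atom within 5 Å of the docked ligand belongs to the pocket,
kept or dropped as a whole residue (`extract_pocket()`). Pocket graphs
(`build_protein_graph()`) connect atom pairs of the same residue within
1.9 Å (a heavy-atom covalent-distance rule — covalent heavy-atom bonds lie
between roughly 1.2 and 1.8 Å, so this reproduces template connectivity on
standard geometry while remaining robust to nonstandard residues and atom
naming) and atoms of different residues within 4.5 Å. All three cutoffs
are configuration entries (`pocket_cutoff`, `intra_cutoff`,
`inter_cutoff`) because the inter-residue rule in particular is a modeling
choice, not a physical constant.

Edge attributes are a fixed one-hot over
{single, double, triple, aromatic, intra-residue, inter-residue} plus the
interatomic distance at construction time; node features are an element
one-hot (C, N, O, S, P, halogen, other), the graph degree, aromatic and
ring-membership flags, and a residue-type one-hot that is zero for
small-molecule atoms (`feature_layout()` documents the exact order).
Coordinates are never re-centred at parse time; any geometric
normalization is the encoder's concern, and the encoder needs none because
it only consumes relative geometry.

## The E(3)-equivariant encoder

Each layer computes an edge message from invariant inputs — the edge
attributes, both endpoint feature vectors, and the squared interatomic
distance — then updates coordinates by a sum over neighbours of unit
difference directions scaled by a learned scalar gate of the message, and
updates features from the plain neighbour-sum of messages:

$$m_{ij} = \phi_e\!\left(a_{ij},\, h_i,\, h_j,\, \lVert x_i - x_j\rVert^2\right),
\qquad
x_i \leftarrow x_i + \sum_{j \in N(i)} \frac{x_i - x_j}{\lVert x_i - x_j\rVert + \varepsilon}\,\phi_x(m_{ij}),
\qquad
h_i \leftarrow \phi_h\!\left(h_i \,\Vert\, \textstyle\sum_{j} m_{ij}\right).$$

Because features see coordinates only through distances, and the
coordinate update is a linear combination of difference vectors, the
feature output is invariant and the coordinate output equivariant under
every rigid motion *including reflections* — the full Euclidean group
E(3). `check_equivariance()` makes that contract executable: it encodes a
graph before and after an orthogonal-plus-translation transform and
reports the worst feature and coordinate deviations (at double precision
these sit at the 1e-15 level; the tests assert 1e-8 over hundreds of
random graphs and transforms).

Numerical choices:

* The coordinate update divides by the *unnormalized* distance; we
  stabilize with ε = 1e-8 so coincident atoms cannot produce NaN.
* The neighbour count divides the coordinate sum only when
  `normalize_coord_update = TRUE`; the unnormalized sum is the default and
  the 1/n variant is one switch away.
* φe, φx, φh are two-layer perceptrons with SiLU activations (φe also has
  a SiLU output; φx and φh end linear). φx's output layer is initialized
  to zero so training starts from unmoved coordinates — this stabilizes
  the first optimization steps without breaking equivariance.
* The first layer consumes raw atom features, later layers the d′-wide
  embeddings, so a zero-layer encoder is exactly the identity.
* The three entities (PROTAC, POI, E3) get separate encoder weights:
  small-molecule and pocket graphs have different edge semantics, so
  sharing weights would conflate bond chemistry with contact geometry.

Defaults are L = 3 layers and d′ = 128, a standard hidden width for
molecular graph encoders; the synthetic study below runs a
compact variant (L = 2, d′ = 32) because the planted-signal corpus is far
simpler than PROTAC-DB-scale data.

## Descriptors, selection, and the attribute vector

Eleven candidate descriptors are computed per SMILES: hydrogen-bond donor
and acceptor counts, rotatable-bond count, TPSA, molecular weight, cLogP,
ring count, aromatic ring count, heavy-atom count, net formal charge, and
the fraction of sp3 carbons. The first six come from Open Babel; the rest
are derived from the parsed molecular graph. The exact candidate list is a
package decision and is configurable: `select_features()` accepts any numeric descriptor
table.

Selection is two-step: near-zero-variance descriptors are dropped and the
survivors ranked by a chi-square score against the binary label (after
min-max scaling to unit range and decile binning, because chi-square needs
nonnegative binned inputs); the top nine survivors then enter a
gradient-boosted tree ensemble (100 trees, depth 3, learning rate 0.1,
fixed seed) and the six with highest gain importance are kept, ties broken
by the chi-square rank. Selected descriptors are z-scored **on training
statistics only** — the statistics travel with the fitted model and a
dedicated test asserts that including test rows changes them, which is the
leakage this discipline prevents.

Morgan fingerprints are computed over the parsed molecular graph by
iterative environment hashing (radius 2, 2048 bits by default): the
initial atom invariant covers element, heavy degree, formal charge,
aromaticity and ring membership, and each iteration hashes the current
identifier with the sorted multiset of (bond order, neighbour identifier)
pairs. The construction is order-invariant, so any valid SMILES of the
same molecule yields identical bits.

The selected descriptors and the fingerprint pass through two independent
one-layer perceptrons whose outputs (each d′/2 wide) concatenate into the
attribute vector f. Its length is forced to d′ because the pooling stage
adds f to a d′-wide weighted sum — with unequal widths that addition
would be ill-typed, so the two widths are tied by construction.

## Mutual attention pooling and fusion

Node embeddings pool into a graph embedding through attention keyed on the
attribute vector: queries q_i = W_Q h_i, key k = W_K f, per-node logits
aᵀ tanh(q_i ∥ k), softmax over nodes, and z = Σ w_i h_i + f. One algebraic
consequence of the concatenation form is worth knowing: the key
contributes the same additive constant to every node's logit, and softmax
is shift-invariant, so the attention *weights* are unaffected by f — the
attribute vector shapes the embedding only through the additive term. The equations are
implemented in exactly this form and the gradient through the key channel
is correspondingly an exact zero.

Protein graphs have no chemical-descriptor attribute, so the POI and E3
keys are learned free vectors of length d′ — the attention machinery then
applies uniformly to all three graphs. The three embeddings concatenate
into the ternary representation z ∈ R^{3d′} and a two-layer head produces
two logits; training minimizes class-weighted cross-entropy
(inverse-frequency weights) and prediction thresholds the high-class
probability at 0.5. The attention weights are exported per edge as
(w_i + w_j)/2 (`edge_attention_map()`, `export_attention()`) for
inspection of which molecular regions drive the prediction.

An ablation switch replaces attention with mean pooling
(z = mean(H) + f), a second one removes all coordinate dependence from the
encoder (squared distances and distance attributes zeroed, coordinate
updates skipped), a third disables descriptor selection, and setting K = 0
disables label enrichment; `ablation_run()` reports all requested variants
under one seed.

## Training

Optimization is Adam at learning rate 1e-3 with minibatches of 50. Internally a
minibatch is encoded as one disjoint-union graph per entity kind
(block-diagonal adjacency) so the layer arithmetic runs on large matrices;
a test asserts the batched path reproduces the per-sample path to 1e-10,
and the per-sample path is itself checked against central finite
differences. A 10% validation carve-out from the training split drives
early stopping on validation AUROC with patience 20; stopping activates
only after `min_epochs` (default 50) because with small validation sets
the AUROC of the first few epochs is noisy enough that restoring a
"lucky" early checkpoint measurably hurts test performance. Everything —
initialization, carve-out, batch order — derives from one seed, and two
runs with the same seed are bit-identical.

## Memory-enhanced pseudolabeling

With most corpus entries unannotated, the semisupervised loop enriches
training labels in four steps: (1) pretrain on the labeled training set
(60 epochs, no early stop, so the recording window is well defined);
(2) over the last T = 10 pretraining epochs, record each unlabeled
training entry's predicted class and latent embedding z ∈ R^{3d′}, and
each labeled entry's embedding; (3) score and select; (4) retrain from
scratch on the labeled set plus the selected pseudolabeled entries, under
the same seed discipline as supervised training. Held-out test entries
are never scored, selected, or trained on; an instrumentation test
asserts this on the recorded id trail.

The disagreement score is the entropy of the epoch-prediction frequencies
(natural log): 0 for unanimous predictions, ln 2 for a 50/50 split.
By the method's convention, *higher* disagreement marks a stronger
candidate. The memory bank holds R = 4 prototypes initialized by
k-means++ on the final-epoch labeled embeddings and updated per recorded
epoch: each prototype takes a soft assignment over labeled samples
(softmax across samples of cosine similarity), moves by the weighted
embedding sum, and is renormalized to unit length — without
renormalization the raw accumulation grows unboundedly. The memory
score of an unlabeled entry is its maximum cosine to the prototypes, and
the combined score is exactly s = (s_dis + s_mem)/2. The top K by s
(ties by entry id, so selection is order-stable) receive their
majority-vote epoch label, ties broken by the latest epoch. K defaults to
the labeled-set size.

Two properties of this design deserve honesty. First, preferring
high-entropy candidates is the opposite of the usual confidence-based
pseudolabeling heuristic; it is the method's deliberate design, and
`invert_disagreement = TRUE` switches to the conventional preference.
Second, precisely because selection favours the *uncertain*, the
majority-vote labels of the selected top-K are on average less accurate
than those of the unselected pool on our synthetic corpus — selection
optimizes informativeness as defined by the method, not label purity. On
the planted-signal study this means label enrichment is roughly
performance-neutral rather than clearly beneficial; the acceptance suite
reports both comparisons as measured.

## The synthetic study and what it shows

All tests run without external data on generated fixtures. Random
molecules are connected random trees with occasional ring-closing edges;
coordinates follow a Gaussian chain with a per-molecule bond-length scale
drawn from U(1.2, 1.9) Å. That scale matters: the planted label depends on
the *global* mean pairwise atom distance, and a message-passing encoder
only observes geometry through local edge distances, so the generator
makes global extent covary with the local distances the model can see —
keeping the learning checks answerable by the architecture under test.
Random pockets place residues on golden-spiral directions around a small
ligand, a configurable fraction within the 5 Å cutoff.

The planted rule is a thresholded latent
`signal_strength · (z_geom + z_TPSA)/√2 + noise`, with z_geom the
standardized mean pairwise PROTAC atom distance and z_TPSA the
standardized TPSA descriptor; signal_strength = 3 and noise_sd = 1 put
the Bayes AUROC near 0.95. DC50/Dmax annotations are emitted consistently
with the labeling rule so `assign_activity_label()` recovers the planted
label exactly, and a configurable fraction of entries withholds both
annotations to form the unlabeled pool.

The study sizes are 600 generated entries (500 train / 100 test), the
compact encoder above, and at most 200 training epochs; at these sizes
supervised training reaches test AUROC ≈ 0.94 in about 70 epochs. These
fixtures emulate the *shape* of the real task — ternary 3D structure plus
descriptors, scarce labels, duplicated (target, SMILES) pairs for the
leakage rule — but not real chemistry: conformers are not energy-minimized,
pockets are geometric toys, and the planted signal is far cleaner than
degradation data. Passing tests therefore certify the correctness and
learning capability of the machinery, not transferable accuracy on
PROTAC-DB-scale corpora, which additionally require docking and predicted
structures upstream.

## Splitting and evaluation

`make_split()` performs the 80/20 random split on labeled records, then
moves every test record sharing both the target protein and the canonical
PROTAC SMILES (Open Babel canonical form) with any training record into an
excluded set. Metrics are accuracy at the 0.5 threshold, AUROC by the
rank/Mann–Whitney method with half credit for ties, and F1 on the high
class (defined as 0 when no positive is predicted and none recovered);
all three are cross-checked against independent reference implementations
to 1e-9 in the tests.

## Known limitations

* Structures are consumed, not produced: docking poses and predicted
  structures are upstream inputs.
* Intra-residue connectivity is inferred by distance, not by residue
  templates; exotic covalent geometry (metal coordination, modified
  residues) may gain or lose an edge.
* The eleven-descriptor candidate list is a package choice and is
  configurable for that reason.
* Aromatic ring counting uses ring perception over rings of size ≤ 7
  from the toolkit's ring set, which is adequate for drug-like molecules
  but not for exotic fused systems.
* The pure-R implementation favours clarity and testability; at
  PROTAC-DB scale a tensor-library backend would be the pragmatic choice.
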