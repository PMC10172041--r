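---
title: "Methods: gamma-centroid simultaneous alignment and folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-centroid simultaneous alignment and folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

centrifold treats the joint alignment-and-folding (SAF) of two RNA
homologs $x$ (length $N$) and $y$ (length $M$) as a discrete object
$A = (M, M^P)$: a strictly increasing set $M$ of matched positions
$(i, k)$, and a set $M^P$ of matched base-pair quadruples $(i, j, k, l)$
whose projections give the two pseudoknot-free secondary structures.  Two
modeling restrictions are inherited from the sparse-SAF literature and are
assumed throughout:

* no pseudoknots — both structures are nested;
* no base-pairing indels — every base pair in either structure is matched
  with a partner pair in the other sequence, so structure always lives on
  quadruples.

A candidate is scored linearly, $s(A; \theta) = \theta^\top \phi(A)$,
where $\phi(A)$ counts occurrences of each feature of a fixed catalog
(F = 204): match emissions over unordered residue pairs, insert emissions
shared by insertions and deletions, the nine alignment state bigrams over
{M, I, D}, ordered base-pair compositions, helix stackings restricted to
canonical/wobble pairs, capped hairpin/bulge/internal loop length bins,
internal-loop asymmetry, and multibranch/external loop terms.  This is the
minimal CONTRAfold-style loop catalog joined with a CONTRAlign-style
alignment catalog; both sequences' loop features are tallied into the
same catalog entries.  Scores define a Boltzmann distribution (a pairwise
conditional log-linear model), $p(A) \propto e^{s(A;\theta)}$, over the
candidate ensemble.

Alignment candidates are canonicalized: inside every gapped run all
deletions precede all insertions, so mixed orderings are not distinct
ensemble members and the `trans_ID` feature is structurally zero.  A
consequence worth knowing: because insertion and deletion *transitions*
are separate parameters (only the emissions are shared), the model is
not automatically symmetric under swapping the two sequences; it is
symmetric exactly when the transition block satisfies MD = MI, DD = II
and DM = IM.

# Posterior inference

`posteriors()` computes the log partition function, the match posteriors
$p^M_{ik}$, the per-sequence base-pairing marginals $p^P_{ij}$, and the
indel posteriors $p^I_i = 1 - \sum_k p^M_{ik}$,
$p^D_k = 1 - \sum_i p^M_{ik}$ by a sparse inside–outside algorithm.
Internally every dynamic program in the package (the joint SAF ensemble,
the single-sequence structure ensemble used for candidate nomination, and
the pair-HMM limit) is expressed as an acyclic hypergraph whose edges
carry their feature emissions; one generic log-domain engine provides the
inside and outside sweeps, expected feature counts, event marginals and
stochastic traceback.  The gradient identity
$\partial \log Z / \partial \theta_f = E[\phi_f]$ then holds by
construction and is verified against central finite differences in the
test suite.

The grammar mirrors the two-level state structure of the decoding
recursion: closures of matched quadruples (with hairpin, stacked,
bulge/internal or multibranch interiors resolved at closure; the
multibranch case tracks "no branch / one branch / at least two branches"
so one-branch loops are never scored as multiloops), loop-level alignment
stretches, and an external level.  With all structure candidates removed
the joint grammar *is* the pair-HMM — that degradation is exact, not an
approximation.

## Sparsity

Candidate matches are nominated by the pair-HMM posterior (threshold
`epsilon_match`, default 0.01), candidate base pairs by a
single-sequence McCaskill-style partition function over the structure
features (threshold `epsilon_pair`, default 0.01, minimum hairpin length
3), and candidate quadruples are all consistent combinations.  Optional
caps (`max_match_keep`, `max_pair_keep` per position and
`max_pair_total` per sequence) bound the ensemble when the nominating
model is still uninformative — early training epochs under a random
initialization being the canonical case.  The caps keep the top-posterior
candidates, so the sets remain nested as thresholds tighten.  During
training the reference example's events are always force-included, which
keeps every per-example cost term non-negative.

The single-sequence nominator skips one-branch loops whose total
unpaired length exceeds `max_loop` (default 30, the CONTRAfold
convention); the joint ensemble itself carries no such restriction —
loop lengths beyond 30 simply share the cap bin of their length feature.

# Gamma-centroid decoding

Given posteriors, `align_pair()` maximizes the expected-accuracy
objective

$$\sum_{(i,k) \in M} (\gamma^M p^M_{ik} - 1)
  + \sum_{(i,j,k,l) \in M^P} \{\gamma^P (p^P_{ij} + p^P_{kl}) - 2\}$$

over all candidates by the two-level sparse recursion ($b_{ik}(j,l)$
spans opened at the match $(i,k)$ with $b_{ik}(i,k) = 0$; the answer is
read at a virtual outermost anchor $(0,0)$).  Quadruple endpoint matches
accrue both their match terms and the pair terms through the closing
bonus.  Only base pairs with $p^P \ge 1/\gamma^P$ are materialized, and
the match threshold $p^M \ge 1/\gamma^M$ gates the *unpaired-match*
recursion case: a quadruple whose pairs are eligible may use endpoint
matches below the match threshold, since those matches enter through the
quadruple bonus.  This reading is what makes the threshold pruning
lossless: an ineligible unpaired match has strictly negative gain and
enables nothing, while a beneficial quadruple always carries eligible
pairs whenever its two pair marginals coincide (which they do for genuine
model posteriors on short instances, where one quadruple accounts for
both marginals).  If instead the match threshold were applied to
quadruple endpoints as well, optimality under pruning would fail on easy
counterexamples (e.g. $\gamma^M = 2$, $\gamma^P = 9$, a quadruple of
probability 0.2 with endpoint match posteriors 0.3 carries a positive
bundle that the pruned space would lose).  Ties are broken
deterministically: gap cases are preferred over matches over quadruples,
so among equal-score optima a candidate with fewer matches is returned.

# Progressive multiple alignment

For $n$ homologs, all pairwise posterior tables are computed once.  The
guide tree is built by UPGMA on distances $d = \sigma_{\max} - \sigma$,
where $\sigma = \sum_{ik} p^M_{ik}\,[p^M_{ik} \ge 1/\gamma^M]$ is the
stochastic similarity at the current $\gamma^M$ (ties join the
lowest-index pair; any strictly decreasing similarity-to-distance map
gives the same merge order).  Profiles are merged leaf-to-root with the
same recursion, substituting column matching probabilities
$p^M_{IK} = \frac{1}{|X||Y|} \sum_{x,y} p^M_{I_x K_y}$ and column
base-pairing probabilities
$p^P_{IJ} = \frac{1}{|X|} \sum_x p^P_{I_x J_x}$ — gapped members
contribute 0 while denominators stay $|X|$ and $|X||Y|$.  The
per-sequence $p^P_{ij}(x)$ is the pairwise SAF marginal averaged over
all partners in the input set (the "consistency" transformation), fixed
once per prediction.  No iterative refinement is performed.  Merges are
oriented so that the child holding the smallest input index plays the
first-sequence role, which together with the deterministic tie rules
makes the product invariant under permuting the input order.

## Hyper-parameter auto-correction

$\gamma^M, \gamma^P$ take values $2^e + 1$ on an exponent grid
(defaults $e_M \in [0,7]$, $e_P \in [0,3]$: 32 candidates).  For every
grid point a full progressive alignment is decoded and its *expected*
sum-of-pairs score is evaluated:

$$E = \frac{1}{C} \sum_{x<y} \Big[ \sum_{(i,k) \in M_{xy}} p^M_{ik}
 + \sum_{i \in I_{xy}} p^I_i + \sum_{k \in D_{xy}} p^D_k \Big],$$

with $C$ the total count of scored events (matches plus indels over all
pairs).  That choice of normalization makes the SPS of a prediction
against itself exactly 1, and the same event bookkeeping is shared by
the realized-SPS metric so the two are directly comparable.  The
candidate with the highest expected SPS wins; ties resolve toward the
smaller exponent pair.  The consensus structure of the winner is then
replaced by the consensus-folding post-process: a Nussinov-style
maximization of $\sum (\gamma p^P_{IJ} - 1)$ over pseudoknot-free column
pairings at fixed $\gamma = 2$, using the column probabilities only (no
covariance or free-energy rescoring of the alignment).  The folding
gamma is not re-selected by the grid.

## Model ensemble

Two parameter vectors of the same catalog can be averaged at the
posterior level: `saf_align(model = "ensemble")` transplants the
alignment-group parameters (match emissions, insert emissions,
transitions) from the trained vector into the packaged partner vector,
runs both inferences, and takes the entrywise mean of the match and
base-pair tables before decoding.  Averaging commutes with the column
aggregations by linearity, so applying it at the pairwise level is
equivalent to averaging column tables.  The packaged partner vector is an
independently trained parameter set over the same catalog (see
"Packaged parameter tables" below).

# Training

Given two-sequence reference examples $A_d$, the convex cost
$c^S = \sum_d [\log Z^S_d(\theta) - s(A_d;\theta)]$ has gradient
$\sum_d (E^S_d[\phi] - \phi(A_d))$.  `fit_saf()` minimizes the
L2-regularized cost by majorization–minimization: each epoch refreshes
the per-group constants
$\lambda_g = (|G|/2 + \alpha) / (\beta + \tfrac12 \sum_{f \in G}
\theta_f^2)$ (defaults $\alpha = 0$, $\beta = 1$) and then runs a BFGS
minimization of $c^S + \tfrac12 \lambda^\top \theta^2$ at fixed
$\lambda$.  The quantity reported as the regularized objective in the
trace is the profiled form
$c^S + \sum_g (|G|/2 + \alpha) \log(\beta + \tfrac12 \sum_g \theta^2)$,
which the alternation provably decreases (the $\lambda$ refresh is the
tangent majorization of the log term).  The inner solver is
`stats::optim(method = "BFGS")` — the standard quasi-Newton
implementation available in base R; its line search enforces sufficient
decrease, which is all the MM argument needs.  Because line-search
probes only require the cost, they run the cheaper inside-only sweep;
gradient points pay for the full inside–outside pass, and each example's
DP hypergraph is built once per candidate refresh and re-swept across
$\theta$ values.

Candidate sets are rebuilt from the current $\theta$ every
`rebuild_every` = 5 epochs (reference events always force-included).  A
rebuild changes the sparse ensemble and therefore the objective itself,
so monotonicity of the trace is asserted between consecutive epochs that
share candidate sets; the trace's `rebuilt` flag marks the boundaries.
The outer loop stops when the relative change of the regularized
objective falls below `tol` (default 1e-4) or after `max_epochs`
(default 200).

Two initializations are provided: `init_random(seed)` draws i.i.d.
$N(0, 1/F)$ values, and `init_transfer()` starts from the packaged
transfer table.  On the synthetic benchmark used in the test suite the
transfer start reaches the stopping tolerance in no more epochs than the
random start.

One identifiability fact matters when interpreting fitted emissions: the
transformation that adds $t_a + t_b$ to every match emission and $t_a$
to every insert emission shifts all candidates of a sequence pair by the
same constant (each residue is emitted exactly once per candidate), so
the likelihood is invariant along this 4-parameter gauge and the
regularizer is what pins the fitted gauge down.  Comparisons of fitted
emission parameters across models — including the parameter-recovery
experiment in the test suite — are therefore made on the
gauge-orthogonal component.

## Packaged parameter tables

`inst/extdata/transfer_params_synthetic.json` (the transfer /
prediction default) and `inst/extdata/partner_params_synthetic.json`
(the ensemble partner) were both produced by full training runs of this
package on synthetic families drawn from two deliberately different
generator configurations (different lengths, pairing densities,
substitution and indel regimes, disjoint seeds), starting from random
initializations.  They are synthetic-data reference fits — the
filenames say so — not published parameter sets; they play the
structural role of an externally trained starting point and of a second,
differently calibrated scoring model.  The reference sets are
deliberately helix-rich (4–5 planted pairs per family) so that the
stacking and wobble features are well determined; in both fits every
canonical/wobble base-pair feature comes out strictly positive and all
non-canonical compositions score below the weakest canonical one.

# The synthetic family generator

`sample_family()` grows a pseudoknot-free ancestor structure with a
helix-extension bias toward a target pairing density, places canonical
pairs (GC-rich, 10% wobble) at paired sites, and evolves each homolog
by per-site substitutions — paired columns are resampled as a canonical
pair ("compensatory") with probability `compensatory_prob`, otherwise
one side mutates freely — plus indels confined to unpaired ancestor
regions, with deletions never shrinking a hairpin loop below 3 nt (the
model's minimum).  The reference alignment keeps one column per ancestor
position and gives every insertion event its own columns.  Defaults
(5 sequences of about 40–80 nt once indels act on a 60-nt ancestor,
pairing density 0.25, substitution rate 0.15, compensatory probability
0.9, indel rate 0.05) are desk-scale by design.

What the generator does *not* emulate: phylogenetic correlation between
homologs (all descend independently from the ancestor), indels at paired
sites, pseudoknots, modified bases, or the length and family-size
distributions of curated databases.  Tests passing on these families
show the algorithmic contracts hold — exact inference, decoding
optimality, recovery of planted signal — not that accuracy figures
transfer to real RNA families.

# Numerical choices and problem sizes

* All DP is in the log domain with explicit $-\infty$; inside/outside
  agreement is asserted to 1e-8, enumeration equivalence to 1e-8, and
  gradient-vs-finite-difference agreement to a relative 1e-4.
* Hypergraph states that cannot contribute (multibranch tables whose
  interior cannot hold two branches of minimal span) are pruned at
  build time; this is exact, not an approximation.
* Tie-breaking is deterministic everywhere (decoding case order, UPGMA
  lowest-index rule, grid order), so predictions and fits are
  bit-reproducible on a single thread under a fixed seed.
* The test and acceptance workloads use deliberately small instances —
  enumeration oracles at lengths at most 5 (plus hand-built nested and
  multibranch candidate sets up to length 16), training examples from
  families of 3 sequences at 14–26 nt, prediction families of 3
  sequences at 24–28 nt, 50-example training sets, 30-family
  expected-SPS sweeps — chosen so the whole suite exercises every code
  path at interactive speed.  The algorithms themselves are the same at
  any scale.

# Known limitations

* The pair-CLLM is trained on pairwise projections; the progressive
  step is a heuristic assembly of pairwise optima, as in all
  progressive SAF tools.
* Expected SPS is an estimator of alignment quality only; the folding
  gamma of the consensus post-process is fixed rather than selected.
* No covariance/free-energy rescoring of the consensus (the structure
  conservation index is out of scope: it needs a thermodynamic engine).
* Per-sequence candidate nomination caps internal loops at `max_loop`
  unpaired nucleotides; extremely long interior loops can therefore be
  missed at the nomination stage even though the joint model could score
  them.
* Single-threaded by design; determinism is part of the contract.
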