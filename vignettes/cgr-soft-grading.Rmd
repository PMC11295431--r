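---
title: "Soft grading of chemical reactions with Condensed Graphs of Reaction"
author: "cgrgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft grading of chemical reactions with Condensed Graphs of Reaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrgrade)
```

## The problem

Automated correction of chemistry homework usually checks a drawing for
exact identity with the expected structure. For *reaction* exercises that
is too blunt: a student who uses the wrong diene in a Diels–Alder but
pushes the electrons correctly deserves more credit than one who draws the
right molecules with impossible electron flow. `cgrgrade` grades an
atom-mapped reaction drawing on a continuous 0–1 scale against one or more
reference reactions, so that the size of an error — and crucially *where*
it sits relative to the reaction center — determines the penalty.

The intended user is the operator of a teaching platform (or a teacher
scripting their own correction) who receives reactions as MDL RXN V2000
files or reaction SMILES in which the students themselves have numbered
corresponding atoms. Manual atom-to-atom mapping (AAM) is the pedagogical
point: a correct mapping encodes a correct understanding of the electron
reorganization, and *any* consistent renumbering of a correct mapping
grades identically.

## From reaction to grade

### Condensed Graph of Reaction

A reaction with a valid AAM is superimposed into a single graph, the
Condensed Graph of Reaction (CGR): one node per mapped atom pair, and per
bond a pair of orders *(reactant, product)*. Bonds whose pair members
differ are **dynamic** — `0>1` formed, `1>0` broken, `2>1` order change —
and atoms whose formal charge or radical count changes are dynamic atoms.
An identity reaction produces a CGR with no dynamic features at all.

Before superposition each molecule is aromatized (a Hückel-style 4n+2
perception over conjugated simple rings of up to eight atoms, applied
iteratively so fused systems resolve), so a Kekulé drawing and an aromatic
drawing of the same ring compare equal. A CGR bond may legitimately pair
an aromatic order with a single or double order.

Atoms mapped on one side only (leaving groups, unbalanced equations) and
unmapped spectators are kept rather than rejected. A bond from a mapped
atom to such an orphan is genuinely formed or broken; a bond *between* two
one-sided atoms — a spectator solvent molecule, or a template fragment —
is untransformed matter and stays static. This choice is what lets a
reactants-only template or an unbalanced student equation grade instead of
crash, and it mirrors the composition convention of the established CGR
toolkits.

### Linear fragment descriptors

The CGR is encoded as a count vector of **sequence fragments**: every
simple path of 2–4 atoms (configurable 2–12) is rendered as an
atom/bond-label string and counted. Atom labels are the element symbol,
decorated with the formal charge when non-zero (`C+1`), a radical mark
(`C*1`), and `r>p` pairs when the value changes (`O-1>0`). Static bonds
are `-`, `=`, `#`, `:`; dynamic bonds use order digits `r>p` with 0 =
none and 4 = aromatic, so a formed C–C single bond reads `C0>1C`. Each
undirected path is counted once: the string is the lexicographic minimum
of its forward and reverse renderings (bond labels are
reaction-directional and do not flip with the path). Explicit hydrogens
drawn as nodes participate exactly like heavy atoms — drawings with and
without explicit hydrogens encode differently, which is why questions
accept several alternative references.

The exact separator-level grammar of the historical ISIDA fragmentation
tool is not published; this package's grammar is self-consistent and
unambiguous but need not agree byte-for-byte, which shifts pairwise
similarities by a few hundredths on small CGRs (see *Limitations*).

```{r fragments}
da <- parseReaction(paste0(
  "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]",
  ">>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1"))
counts(enumerateFragments(da))
```

### Similarity and the grade

Two fragment vectors $A$ and $B$ are compared with the count form of the
Tanimoto coefficient over the union of their keys:

$$ g_{sim} \;=\; \frac{\sum_i A_i B_i}{\sum_i A_i^2 + \sum_i B_i^2 - \sum_i A_i B_i} $$

A question carries 1..N reference reactions (to accommodate tautomers,
mesomers, alternative hydrogen conventions); the student's $g_{sim}$ is
the maximum over the references, ties resolved to the lowest index.

If the teacher pre-draws a **reaction template** (a partial reaction,
possibly partially mapped), its own similarity $g_{tpl}$ to the winning
reference is subtracted out, so the given part of the answer earns
nothing — even for a student who submits the template untouched, or
nothing at all:

$$ g_{rest} = \begin{cases}\dfrac{g_{sim}-g_{tpl}}{1-g_{tpl}} & \text{template}\\[2pt] g_{sim} & \text{no template}\end{cases} $$

clamped below at zero. A template with $g_{tpl}=1$ is rejected as
degenerate (it already is a full correct answer).

If the question grades **stereochemistry**, standard InChI strings are
generated (via the OpenBabel CLI, which bundles the InChI library) for
every molecule of the answer and the winning reference; molecules are
paired by identical formula/connectivity/hydrogen layers and the stereo
layers compared: tetrahedral centers from `/t` with signs normalized by
the `/m` mirror flag, double-bond Z/E centers from `/b`. The stage score
is the proportion of correctly drawn centers,

$$ g_{rest} = \begin{cases}\#\,\text{correct}/\#\,\text{total} & g_{sim} = 1\\ 0 & g_{sim}\neq 1,\end{cases} $$

because with any constitutional difference the InChI priority labels stop
being comparable — partial stereo credit is only meaningful on an
otherwise perfect answer. A reference without stereo centers (0/0) passes
the stage with 1 rather than failing on an undefined ratio.

Finally the softness transform with teacher-set parameters $\alpha$
(exponent, range 0.1–10, default 1) and cutoff $t$ (range 0–1, default 0):

$$ g = \begin{cases}(g_{rest})^{\alpha} & (g_{rest})^{\alpha} \ge t\\ 0 & \text{otherwise}\end{cases} $$

Small $\alpha$ forgives partial errors, large $\alpha$ punishes any
deviation; $t$ discards low partial credit entirely.

```{r grade}
q <- questionSpec(paste0(
  "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]",
  ">>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1"))
pentadiene <- parseReaction(paste0(
  "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH:6][CH3:7]",
  ">>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH:6]1[CH3:7]"))
gradeAnswer(pentadiene, q)
```

An error *at the reaction center* — a wrong mapping — rewrites the
dynamic bonds themselves, so most fragments of the erroneous CGR share
nothing with the correct one and the grade drops much further than for a
peripheral error of similar size. An invalid mapping in the answer
(duplicated numbers, element-inconsistent pairs) is a student error and
grades 0 with the mapping report as diagnostic; an invalid reference or
template is a question-configuration error and throws.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `kind` | `FragmentationScheme` | `atoms_and_bonds` | spell out atoms and bonds, atoms only, or bonds only |
| `minLen`, `maxLen` | `FragmentationScheme` | 2, 4 | path length window in atoms (2–12) |
| `formalCharge` | `FragmentationScheme` | on | decorate atom labels with formal charges |
| `radicals` | `FragmentationScheme` | on | decorate atom labels with radical marks |
| `alpha` | `QuestionSpec` | 1 | softness exponent, 0.1–10 |
| `threshold` | `QuestionSpec` | 0 | cutoff `t`, 0–1 |
| `stereo` | `QuestionSpec` | off | add the InChI stereo stage |

The default scheme (`IAB(2-4) FC_UR`: sequences of 2–4 atoms and bonds,
formal charges and radical/lone-pair marks on) is the configuration the
grading service runs with; it can be overridden per question or loaded
from the server-style XML file (`loadFragmentationConfig()`, elements
`scheme`, `minLength`, `maxLength`, `formalCharge`, `radicalsLonePairs`).
Lone pairs are accepted in the configuration name for fidelity, but no
supported input format carries explicit lone-pair counts, so the toggle
only ever acts on radicals and charges — the package never invents
electron bookkeeping the input does not state.

## Numerical and design choices

* **Determinism.** Parsing, CGR construction and grading are purely
  deterministic; CGR atoms get a canonical order by Morgan-style
  neighborhood refinement with the input index as final tie-break. The
  fragment *vector* is order-free by construction, which is what makes
  the grade exactly invariant under consistent AAM renumbering — the
  suite asserts bit-identical grades over random renumberings.
* **Empty vectors.** Tanimoto of two empty vectors is defined as 0 (with
  a warning): a blank answer to a blank-CGR question must not score 1.
* **Reference ties.** Equal similarities resolve to the lowest reference
  index, and $g_{tpl}$ is computed against that reference.
* **Gate tolerance.** The $g_{sim}=1$ gates compare against 1 with a
  `1e-12` slack; identical vectors produce exactly 1 in floating point,
  so the slack only guards against pathological rounding.
* **Aromatization** only ever promotes bonds (never de-aromatizes), so it
  is idempotent; perception failure on an exotic ring leaves the Kekulé
  form, which still compares consistently as long as both sides of both
  reactions are drawn at the same convention.

## The fixture generator

`generateFixture()` builds deterministic toy cases for four classroom
families — Diels–Alder cycloaddition, SN2 with Walden inversion (graded
with the stereo flag), Fischer esterification, and the
pentane-2,4-dione + ammonia condensation whose imine/enamine tautomers
motivate two-reference questions. Perturbations model archetypal student
errors: a peripheral substituent (partial credit), a reaction-center
mis-mapping (valid AAM, wrong dynamic bonds, heavy penalty), a stereo
flip, and a fully unmapped drawing. The seed drives a consistent random
renumbering of the answer's maps, so every seed must — and does — grade
identically.

The generator emulates the *grading-relevant* structure of student input:
small mapped molecules, one error class at a time. It does not emulate
sketcher artifacts, mixed error classes, hydrogen-convention mismatches
or the long tail of malformed files real students produce, so green
fixtures demonstrate the engine's discrimination ordering, not field
robustness. Test problem sizes (random CGRs of up to 8 atoms, 200 draws
for the enumeration cross-check, 100 renumberings per fixture) were
chosen as the smallest sizes that still exercise every code path —
ring/branch combinatorics saturate well below 8 atoms for a 4-atom
fragment window.

## Limitations

* The fragment-string grammar is internally consistent but not guaranteed
  byte-identical to the historical ISIDA Fragmentor2022 dialect; absolute
  similarity values on small CGRs can differ from the original service by
  a few hundredths (the relative ordering of error classes is robust).
* Atom-centered fragments and pharmacophoric triplet descriptors are out
  of scope; only sequence fragments are implemented.
* Radicals have no reaction-SMILES notation and round-trip through the
  RXN dialect only (`M  RAD`; a singlet marker maps to zero unpaired
  electrons and is not preserved).
* RXN V3000 is rejected; classroom sketchers export V2000.
* Aromaticity perception is a deliberately simple Hückel model over
  simple rings; it covers benzenoid, heteroaromatic and fused-bicyclic
  teaching chemistry but is not a full aromaticity engine.
* Stereochemistry assessment requires the `obabel` executable and only
  reads stereo from the original serialized input (SMILES `@`/`/`/`\`
  marks or molfile wedges), never from the graph.
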