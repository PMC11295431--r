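# cgrgrade

Soft grading of atom-mapped chemical reactions via Condensed Graphs of
Reaction (CGR).

Automated homework platforms traditionally mark a drawn reaction right or
wrong by exact comparison. `cgrgrade` instead grades a student's
atom-mapped reaction on a continuous 0–1 scale against one or more
teacher reference reactions, so partial understanding earns partial
credit and errors *at the reaction center* — wrong electron pushing,
encoded as a wrong atom-to-atom mapping (AAM) — cost far more than
peripheral mistakes. It is written for operators of teaching platforms
and for teachers scripting their own correction of RXN V2000 / reaction
SMILES submissions.

## Method

1. **CGR construction.** Reactant and product molecules are aromatized
   (Hückel 4n+2 over conjugated rings) and superimposed by their atom
   maps into one graph whose bonds carry an order pair
   *(reactant, product)*: `0>1` formed, `1>0` broken, `2>1` order change.
   Any consistent renumbering of a correct mapping yields the same CGR,
   and the same grade.
2. **Fragment descriptors.** All simple paths of 2–4 atoms of the CGR are
   rendered as canonical atom/bond label strings (`C0>1C`, `C-C=C`,
   `C=C-O`, ...) and counted into a sparse vector.
3. **Similarity.** Count-form Tanimoto over the key union,

       g_sim = ΣA·B / (ΣA² + ΣB² − ΣA·B),

   maximized over the 1..N references (tautomers, mesomers, alternative
   hydrogen conventions).
4. **Grading formulas.** An optional teacher template's own similarity is
   subtracted, `g_rest = (g_sim − g_tpl)/(1 − g_tpl)`; optional
   stereochemistry assessment compares InChI `/t`, `/m`, `/b` layers and
   scores the proportion of correctly drawn R/S and Z/E centers (only at
   `g_sim = 1`); finally the softness transform
   `g = (g_rest)^α if ≥ t else 0` with teacher parameters
   `α ∈ [0.1, 10]`, `t ∈ [0, 1]`.

See the methods vignette (`vignettes/cgr-soft-grading.Rmd`) for the full
model, design choices and limitations.

## Worked example

The classic Diels–Alder question: buta-1,3-diene + ethylene →
cyclohexene. The student answers with penta-1,3-diene instead of
butadiene — right mechanism, wrong nucleophile:

```r
library(cgrgrade)
q <- readQuestion(system.file("extdata", "dielsalder-question.json",
                              package = "cgrgrade"))
ans <- parseReaction(paste0(
  "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH:6][CH3:7]",
  ">>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH:6]1[CH3:7]"))
gradeAnswer(ans, q)
#> GradeResult: g=0.8980 (gSim=0.8980 ref#1, gRest=0.8980)
```

The answer keeps most of the correct CGR (all six dynamic ring bonds) and
adds five fragments around the extra methyl, so it scores 0.898 — strong
partial credit. A student who instead draws the *correct* molecules but
numbers the product ring in the wrong direction creates wrong dynamic
bonds at the reaction center and falls to 0.532:

```r
mismap <- parseReaction(paste0(
  "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]",
  ">>[CH2:1]1[CH2:6][CH2:5][CH:4]=[CH:3][CH2:2]1"))
gradeAnswer(mismap, q)@grade
#> [1] 0.5319149
```

`gradeResultJSON()` emits the full diagnostic record (per-reference
similarities, mapping report, fragment counts, stereo assessment) for the
platform side. A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/cgrgrade grade -q question.json -a answer.rxn
Rscript inst/scripts/cgrgrade similarity "A>>B" "C>>D"
Rscript inst/scripts/cgrgrade cgr "[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]"
```

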