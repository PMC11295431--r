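Package: cgrgrade
Title: Soft Grading of Atom-Mapped Chemical Reactions via Condensed
    Graphs of Reaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grades a student's atom-mapped chemical reaction against one
    or more reference reactions on a continuous 0-1 scale.  Reactant and
    product molecules are aromatized and superimposed by their atom-to-atom
    mapping into a single Condensed Graph of Reaction (CGR) whose dynamic
    bonds encode the transformation; CGRs are encoded as count vectors of
    canonical linear fragments (sequences of 2-4 atoms and bonds) and
    compared with the count form of the Tanimoto coefficient.  Optional
    reaction templates, InChI-layer stereochemistry assessment and
    teacher-tunable softness parameters (exponent alpha, cutoff t) turn
    the similarity into a partial-credit grade.  Reads and writes MDL RXN
    V2000 and reaction SMILES with atom maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, xml2, igraph
Suggests: testthat (>= 3.0.0)
SystemRequirements: OpenBabel 3 command line tool (obabel) with InChI
    support, required only for stereochemistry assessment.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'parse-smiles.R'
    'parse-rxn.R'
    'write.R'
    'mapping.R'
    'aromatize.R'
    'cgr.R'
    'fragments.R'
    'similarity.R'
    'stereo.R'
    'grade.R'
    'question.R'
    'fixtures.R'
    'cli.R'
    'periodic.R'
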