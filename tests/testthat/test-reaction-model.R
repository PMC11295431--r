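test_that("reaction SMILES parsing preserves structure, maps, charges and H counts", {
    rxn <- parseReaction(DA_REF)
    expect_s4_class(rxn, "Reaction")
    expect_length(reactants(rxn), 2L)
    expect_length(products(rxn), 1L)
    expect_equal(vapply(reactants(rxn), function(m) nrow(atoms(m)), integer(1)),
                 c(2L, 4L))
    expect_equal(nrow(atoms(products(rxn)[[1]])), 6L)
    expect_equal(validateMapping(rxn)@mappedPairs, 6L)
    # independent parser agrees on atom and map counts
    counts <- pythonOracle(paste0(
        "from rdkit import Chem\n",
        "m = Chem.MolFromSmiles('[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]')\n",
        "print(m.GetNumAtoms(), sorted(a.GetAtomMapNum() for a in m.GetAtoms()))"))
    expect_equal(counts, "6 [1, 2, 3, 4, 5, 6]")

    # charges, implicit H bookkeeping, bracket atoms
    mol <- reactants(parseReaction("[NH4+].[O-][N+](=O)[O-]>>[NH4+].[O-:1][N+](=O)[O-]"))[[1]]
    expect_equal(atoms(mol)$charge, 1L)
    expect_equal(atoms(mol)$hcount, 4L)

    # mapping optional at parse time
    expect_equal(validateMapping(parseReaction("C=C.C=CC=C>>C1CCC=CC1"))@mappedPairs, 0L)

    # explicit hydrogens become graph nodes, bracket H counts do not
    withH <- reactants(parseReaction("[H][C:1]([H])=[O:2]>>[H][C:1]([H])=[O:2]"))[[1]]
    expect_equal(sum(atoms(withH)$explicit), 2L)
    expect_equal(nrow(atoms(withH)), 4L)
})

test_that("malformed SMILES raise parse errors naming the position", {
    expect_error(parseReaction("C(C>>C"), "position")
    expect_error(parseReaction("C=C>>C1CC"), "ring")
    expect_error(parseReaction("[Xx:1]C>>C"), "element")
    expect_error(parseReaction("C=C"), ">")
    expect_error(parseReaction(""), "non-empty")
})

test_that("RXN V2000 parses to the same reaction as the SMILES form", {
    lines <- writeReaction(parseReaction(DA_REF), "rxn_v2000")
    rxn <- parseReaction(lines, "rxn_v2000")
    expect_equal(validateMapping(rxn)@mappedPairs, 6L)
    expect_identical(cgrSignature(buildCGR(rxn)),
                     cgrSignature(buildCGR(parseReaction(DA_REF))))
    expect_error(parseReaction("$RXN V3000\n\n\n\n  1  1", "rxn_v2000"), "V3000")
    expect_error(parseReaction("no header", "rxn_v2000"), "RXN")
})

test_that("write/parse round trips preserve graph, charges, radicals and maps", {
    smis <- c(DA_REF, DA_METHYL,
              "[O-:1][C:2](=[O:3])C>>[OH:1][C:2](=[O:3])C",
              "c1ccccc1[CH2:1]Br>>c1ccccc1[CH2:1]O",
              "[OH-:7].[CH3:1][CH:2]([Br:6])[CH2:3][CH3:4]>>[CH3:1][CH:2]([OH:7])[CH2:3][CH3:4].[Br-:6]")
    mapMultiset <- function(rxn) sort(unlist(lapply(
        c(reactants(rxn), products(rxn)), function(m) atoms(m)$map)))
    for (s in smis) {
        rxn <- parseReaction(s)
        for (dialect in c("reaction_smiles", "rxn_v2000")) {
            back <- parseReaction(writeReaction(rxn, dialect), dialect)
            expect_identical(cgrSignature(buildCGR(back)),
                             cgrSignature(buildCGR(rxn)), label = paste(s, dialect))
            expect_identical(mapMultiset(back), mapMultiset(rxn))
        }
    }
    # radicals survive the V2000 property block
    rad <- parseReaction(paste0(
        "$RXN\n\n\n\n  1  1\n$MOL\n\n\n\n  1  0  0  0  0  0  0  0  0  0999 V2000\n",
        "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  1  0  0\n",
        "M  RAD  1   1   2\nM  END\n$MOL\n\n\n\n",
        "  1  0  0  0  0  0  0  0  0  0999 V2000\n",
        "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  1  0  0\n",
        "M  END"), "rxn_v2000")
    expect_equal(atoms(reactants(rad)[[1]])$radical, 1L)
    back <- parseReaction(writeReaction(rad, "rxn_v2000"), "rxn_v2000")
    expect_equal(atoms(reactants(back)[[1]])$radical, 1L)
})

test_that("an empty side is rejected unless the object is a template", {
    expect_error(parseReaction("C=C>>", template = FALSE), "template")
    tpl <- parseReaction("[CH2:1]=[CH2:2]>>", template = TRUE)
    expect_length(products(tpl), 0L)
})

test_that("mapping validation reports duplicates, mismatches and orphans", {
    ok <- validateMapping(parseReaction(DA_REF))
    expect_true(ok@valid)
    expect_equal(ok@mappedPairs, 6L)

    dup <- validateMapping(parseReaction("[CH3:3][CH3:3]>>[CH3:3][CH3:4]"))
    expect_false(dup@valid)
    expect_equal(dup@duplicates, 3L)

    mism <- validateMapping(parseReaction("[CH4:2]>>[OH2:2]"))
    expect_false(mism@valid)
    expect_equal(mism@elementMismatches, 2L)

    orph <- validateMapping(parseReaction("[CH3:1][Br:2]>>[CH3:1][OH:9]"))
    expect_true(orph@valid)          # orphans reported, not fatal
    expect_equal(orph@orphansReactant, 2L)
    expect_equal(orph@orphansProduct, 9L)
})

test_that("mapping validation is invariant under consistent renumbering", {
    set.seed(42)
    rxn <- parseReaction(DA_METHYL)
    for (i in 1:20) {
        perm <- randomMapPermutation(rxn)
        rep2 <- validateMapping(permuteMapNumbers(rxn, perm))
        expect_true(rep2@valid)
        expect_equal(rep2@mappedPairs, validateMapping(rxn)@mappedPairs)
    }
})

test_that("parsing is deterministic", {
    a <- parseReaction(DA_METHYL)
    b <- parseReaction(DA_METHYL)
    expect_identical(writeReaction(a), writeReaction(b))
    expect_identical(cgrSignature(buildCGR(a)), cgrSignature(buildCGR(b)))
})
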