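firstMol <- function(smi) reactants(parseReaction(paste0(smi, ">>C")))[[1]]

test_that("aromaticity perception matches the canonical cases", {
    expect_equal(unname(table(bonds(aromatize(firstMol("C1=CC=CC=C1")))$order)[["aromatic"]]), 6L)
    expect_identical(bonds(aromatize(firstMol("C1CCCCC1")))$order, rep("single", 6L))
    sty <- aromatize(firstMol("C=CC1=CC=CC=C1"))
    expect_equal(sum(bonds(sty)$order == "aromatic"), 6L)
    expect_equal(sum(bonds(sty)$order == "double"), 1L)  # vinyl untouched
    expect_equal(sum(bonds(aromatize(firstMol("C1=CC=C2C=CC=CC2=C1")))$order == "aromatic"), 11L)
    expect_equal(sum(bonds(aromatize(firstMol("C1=CC=NC=C1")))$order == "aromatic"), 6L)
    # anti-aromatic and cross-conjugated rings stay Kekule
    expect_equal(sum(bonds(aromatize(firstMol("C1=CC1")))$order == "aromatic"), 0L)
    expect_equal(sum(bonds(aromatize(firstMol("O=C1C=CC(=O)C=C1")))$order == "aromatic"), 0L)
})

test_that("aromaticity perception agrees with an independent toolkit", {
    cases <- c("C=CC1=CC=CC=C1", "C1=CC=C2C=CC=CC2=C1", "C1=CC=NC=C1",
               "C1CCCCC1", "O=C1C=CC(=O)C=C1")
    ours <- vapply(cases, function(s)
        sum(bonds(aromatize(firstMol(s)))$order == "aromatic"), integer(1))
    theirs <- pythonOracle(paste0(
        "from rdkit import Chem\n",
        "smis = ['C=CC1=CC=CC=C1','C1=CC=C2C=CC=CC2=C1','C1=CC=NC=C1',",
        "'C1CCCCC1','O=C1C=CC(=O)C=C1']\n",
        "print([sum(b.GetIsAromatic() for b in Chem.MolFromSmiles(s).GetBonds())",
        " for s in smis])"))
    expect_equal(paste0("[", paste(unname(ours), collapse = ", "), "]"), theirs)
})

test_that("aromatization is idempotent", {
    for (s in c("C1=CC=CC=C1", "C=CC1=CC=CC=C1", "C1=CC=C2C=CC=CC2=C1")) {
        once <- aromatize(firstMol(s))
        expect_identical(bonds(aromatize(once)), bonds(once))
    }
})

test_that("the Diels-Alder CGR has the six expected dynamic bonds", {
    cgr <- buildCGR(parseReaction(DA_REF))
    expect_equal(nrow(atoms(cgr)), 6L)
    expect_true(all(atoms(cgr)$element == "C"))
    dyn <- dynamicBonds(cgr)
    expect_equal(nrow(dyn), 6L)
    expect_equal(sort(dyn$label), sort(c("0>1", "0>1", "2>1", "2>1", "2>1", "1>2")))
    # manual superposition, bond by bond (map pairs)
    byMaps <- function(u, v) {
        at <- atoms(cgr)
        i <- which(at$map == u); j <- which(at$map == v)
        d <- dyn[(dyn$a == i & dyn$b == j) | (dyn$a == j & dyn$b == i), ]
        d$label
    }
    expect_equal(byMaps(1, 2), "2>1")
    expect_equal(byMaps(2, 3), "0>1")
    expect_equal(byMaps(6, 1), "0>1")
    expect_equal(byMaps(4, 5), "1>2")
})

test_that("an identity reaction gives a static CGR equal to the molecular graph", {
    cgr <- buildCGR(parseReaction("[CH3:1][CH:2]=[CH2:3]>>[CH3:1][CH:2]=[CH2:3]"))
    expect_equal(nrow(dynamicBonds(cgr)), 0L)
    expect_equal(nrow(dynamicAtoms(cgr)), 0L)
    expect_equal(nrow(bonds(cgr)), 2L)
    expect_identical(bonds(cgr)$rOrder, bonds(cgr)$pOrder)
})

test_that("every reactant and product bond lands in exactly one CGR bond", {
    for (smi in c(DA_REF, DA_METHYL,
                  "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>[CH3:1][C:2](=[O:3])[O:6][CH3:5].[OH2:4]")) {
        rxn <- aromatize(parseReaction(smi))
        cgr <- buildCGR(rxn, aromatize = FALSE)
        nSide <- function(mols) sum(vapply(mols, function(m) nrow(bonds(m)), integer(1)))
        expect_equal(sum(bonds(cgr)$rOrder != "none"), nSide(reactants(rxn)))
        expect_equal(sum(bonds(cgr)$pOrder != "none"), nSide(products(rxn)))
    }
})

test_that("orphan and unmapped atoms are kept with one-sided bonds", {
    # leaving group Br is product-orphan; spectator water unmapped
    cgr <- buildCGR(parseReaction("[CH3:1][Br:2].O>>[CH3:1][OH:9]"))
    at <- atoms(cgr)
    expect_setequal(unique(at$origin), c("both", "reactant_only", "product_only"))
    oneSided <- bonds(cgr)[bonds(cgr)$rOrder == "none" | bonds(cgr)$pOrder == "none", ]
    expect_true(nrow(oneSided) >= 2L)  # broken C-Br and formed C-O at least
})

test_that("invalid mappings are rejected with the diagnosis", {
    expect_error(buildCGR(parseReaction("[CH3:1][CH3:1]>>[CH3:1][CH3:2]")),
                 "duplicated map numbers: 1")
    expect_error(buildCGR(parseReaction("[CH4:2]>>[OH2:2]")),
                 "element mismatches")
})

test_that("consistent map renumbering leaves the CGR signature unchanged", {
    set.seed(7)
    for (smi in c(DA_REF, DA_METHYL, DA_MISMAP)) {
        rxn <- parseReaction(smi)
        sig <- cgrSignature(buildCGR(rxn))
        for (i in 1:25) {
            perm <- randomMapPermutation(rxn)
            expect_identical(cgrSignature(buildCGR(permuteMapNumbers(rxn, perm))),
                             sig)
        }
    }
})

test_that("the CGR debug block lists the dynamic bonds", {
    block <- writeCGRBlock(buildCGR(parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")))
    expect_true(any(grepl("^> <DYNAMIC_BONDS>$", block)))
    expect_true(any(grepl("^\\d+ \\d+ 2>1$", block)))
})
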