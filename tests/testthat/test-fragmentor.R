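test_that("the XML configuration loads with server defaults and validates", {
    sc <- loadFragmentationConfig(
        "<fragmentation><scheme>IAB</scheme><minLength>2</minLength><maxLength>4</maxLength><formalCharge>true</formalCharge><radicalsLonePairs>true</radicalsLonePairs></fragmentation>")
    expect_identical(sc@kind, "atoms_and_bonds")
    expect_identical(c(sc@minLen, sc@maxLen), c(2L, 4L))
    expect_true(sc@formalCharge && sc@radicals)
    # absent fields take the defaults
    d <- loadFragmentationConfig("<fragmentation/>")
    expect_identical(c(d@kind, d@minLen, d@maxLen, d@formalCharge, d@radicals),
                     c("atoms_and_bonds", 2L, 4L, TRUE, TRUE))
    expect_error(loadFragmentationConfig(
        "<f><minLength>5</minLength><maxLength>3</maxLength></f>"), "minLength")
    expect_error(loadFragmentationConfig("<f><scheme>XYZ</scheme></f>"),
                 "atoms_and_bonds")
    expect_error(loadFragmentationConfig("<f><scheme>IAB</f>"), "XML")
})

test_that("canonical fragment strings are direction-minimal", {
    cgr <- buildCGR(parseReaction("[CH3:1][CH:2]=[CH:3][OH:4]>>[CH3:1][CH:2]=[CH:3][OH:4]"))
    at <- atoms(cgr)
    path <- c(which(at$map == 4), which(at$map == 3), which(at$map == 2))
    # "O-C=C" read one way, "C=C-O" the other; the minimum wins
    expect_identical(canonicalFragmentString(cgr, path), "C=C-O")
    expect_identical(canonicalFragmentString(cgr, rev(path)), "C=C-O")
    # a formed single bond between carbons reads 0>1
    formed <- buildCGR(parseReaction("[CH4:1].[CH4:2]>>[CH3:1][CH3:2]"))
    expect_identical(canonicalFragmentString(formed, c(1, 2)), "C0>1C")
})

test_that("fragment enumeration matches hand counts on tiny cases", {
    idty <- buildCGR(parseReaction("[CH3:1][CH:2]=[CH2:3]>>[CH3:1][CH:2]=[CH2:3]"))
    expect_identical(
        counts(enumerateFragments(idty, fragmentationScheme(minLen = 2, maxLen = 3))),
        c("C-C" = 1L, "C-C=C" = 1L, "C=C" = 1L))
    # ethene -> ethane: one dynamic fragment
    e2e <- buildCGR(parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]"))
    expect_identical(counts(enumerateFragments(e2e, fragmentationScheme(minLen = 2, maxLen = 2))),
                     c("C2>1C" = 1L))
    # too small for the window
    single <- buildCGR(parseReaction("[CH4:1]>>[CH4:1]"))
    expect_length(counts(enumerateFragments(single)), 0L)
})

test_that("atoms-only and bonds-only schemes drop the other label type", {
    cgr <- buildCGR(parseReaction("[CH3:1][CH:2]=[CH2:3]>>[CH3:1][CH:2]=[CH2:3]"))
    ao <- counts(enumerateFragments(cgr, fragmentationScheme("atoms_only", 2, 3)))
    expect_identical(ao, c("CC" = 2L, "CCC" = 1L))
    bo <- counts(enumerateFragments(cgr, fragmentationScheme("bonds_only", 3, 3)))
    expect_identical(bo, c("-,=" = 1L))
})

test_that("charge and radical decorations obey the scheme flags", {
    rxn <- parseReaction("[CH3:1][O-:2]>>[CH3:1][OH:2]")
    cgr <- buildCGR(rxn)
    withFC <- counts(enumerateFragments(cgr, fragmentationScheme()))
    expect_identical(names(withFC), "C-O-1>0")
    noFC <- counts(enumerateFragments(cgr, fragmentationScheme(formalCharge = FALSE)))
    expect_identical(names(noFC), "C-O")
})

test_that("enumeration equals the independent brute-force path oracle", {
    set.seed(2026)
    schemes <- list(fragmentationScheme(),
                    fragmentationScheme(minLen = 2, maxLen = 3),
                    fragmentationScheme("atoms_only", 2, 4))
    for (i in 1:60) {
        cgr <- randomCGR(8L)
        sc <- schemes[[(i %% length(schemes)) + 1L]]
        mine <- counts(enumerateFragments(cgr, sc))
        ref <- oracleFragments(cgr, sc)
        expect_identical(mine[order(names(mine))], ref[order(names(ref))],
                         label = sprintf("random CGR %d", i))
    }
})

test_that("palindromic paths are not double-counted", {
    set.seed(11)
    for (i in 1:20) {
        cgr <- randomCGR(7L)
        sc <- fragmentationScheme()
        total <- sum(counts(enumerateFragments(cgr, sc)))
        expect_equal(total, sum(oracleFragments(cgr, sc)),
                     label = "total equals number of undirected simple paths")
    }
})

test_that("isomorphic CGRs (relabeled atoms) give identical fragment vectors", {
    set.seed(5)
    for (i in 1:20) {
        cgr <- randomCGR(8L)
        n <- nrow(atoms(cgr))
        perm <- sample(n)
        at <- atoms(cgr)[order(perm), , drop = FALSE]
        rownames(at) <- NULL
        bd <- bonds(cgr)
        bd$a <- perm[bd$a]; bd$b <- perm[bd$b]
        swap <- bd$a > bd$b
        tmp <- bd$a[swap]; bd$a[swap] <- bd$b[swap]; bd$b[swap] <- tmp
        shuffled <- new("CGR", atoms = at, bonds = bd)
        expect_identical(counts(enumerateFragments(shuffled)),
                         counts(enumerateFragments(cgr)))
    }
})

test_that("enlarging the window never removes existing fragment keys", {
    set.seed(9)
    for (i in 1:15) {
        cgr <- randomCGR(7L)
        small <- counts(enumerateFragments(cgr, fragmentationScheme(minLen = 2, maxLen = 3)))
        large <- counts(enumerateFragments(cgr, fragmentationScheme(minLen = 2, maxLen = 5)))
        expect_true(all(names(small) %in% names(large)))
        expect_identical(large[names(small)], small)
    }
})

test_that("the TSV debug dump is sorted and tab-separated", {
    fvec <- enumerateFragments(buildCGR(parseReaction(DA_REF)))
    tf <- tempfile()
    df <- writeFragmentsTSV(fvec, tf)
    lines <- readLines(tf)
    expect_equal(length(lines), length(counts(fvec)))
    expect_true(all(grepl("\t", lines)))
    expect_identical(df$fragment, sort(df$fragment))
})
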