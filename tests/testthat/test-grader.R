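test_that("count Tanimoto follows the similarity formula on a grid", {
    a <- fv(k1 = 2L, k2 = 1L)
    b <- fv(k1 = 1L, k2 = 1L, k3 = 1L)
    expect_equal(tanimoto(a, b), 3 / (5 + 3 - 3))          # 0.6
    expect_equal(tanimoto(a, a), 1)
    expect_equal(tanimoto(fv(x = 1L), fv(y = 2L)), 0)
    expect_warning(z <- tanimoto(new("FragmentVector"), new("FragmentVector")),
                   "empty")
    expect_equal(z, 0)
    # symmetry + bounds on random count vectors
    set.seed(3)
    for (i in 1:50) {
        ka <- sample(letters[1:8], sample(1:6, 1))
        kb <- sample(letters[1:8], sample(1:6, 1))
        a <- fv(stats::setNames(sample(1:5, length(ka), TRUE), ka))
        b <- fv(stats::setNames(sample(1:5, length(kb), TRUE), kb))
        t1 <- tanimoto(a, b)
        expect_equal(t1, tanimoto(b, a))
        expect_gte(t1, 0); expect_lte(t1, 1)
        expect_equal(tanimoto(a, a), 1)
    }
})

test_that("the best reference wins with ties broken to the lowest index", {
    ref1 <- fv(a = 1L, b = 1L)
    ref2 <- fv(a = 1L)
    ans <- fv(a = 1L, b = 1L)
    best <- bestReferenceSimilarity(ans, list(ref2, ref1))
    expect_equal(best$gSim, 1)
    expect_equal(best$index, 2L)
    tie <- bestReferenceSimilarity(ans, list(ref1, ref1))
    expect_equal(tie$index, 1L)
})

test_that("the template adjustment renormalizes and clamps", {
    expect_equal(templateAdjust(0.75, 0.5), 0.5)
    expect_equal(templateAdjust(0.5, 0.5), 0)   # the template floor earns nothing
    expect_equal(templateAdjust(0.9, NA), 0.9)
    expect_equal(templateAdjust(0.2, 0.5), 0)   # clamped, not negative
    expect_error(templateAdjust(1, 1), "degenerate")
    # monotone in gSim; identity at gTpl = 0
    g <- seq(0, 1, by = 0.1)
    adj <- vapply(g, templateAdjust, numeric(1), gTpl = 0.4)
    expect_true(all(diff(adj) >= 0))
    expect_equal(vapply(g, templateAdjust, numeric(1), gTpl = 0), g)
})

test_that("the softness transform applies exponent and cutoff", {
    expect_equal(finalGrade(0.7), 0.7)                       # defaults: identity
    expect_equal(finalGrade(0.81, alpha = 0.5), 0.9)
    expect_equal(finalGrade(0.9, alpha = 2, threshold = 0.85), 0)
    expect_equal(finalGrade(0.9, alpha = 2, threshold = 0.8), 0.81)
    grid <- expand.grid(g = seq(0, 1, 0.25), a = c(0.1, 0.5, 1, 2, 10),
                        t = c(0, 0.3, 0.9))
    for (i in seq_len(nrow(grid))) {
        v <- grid$g[i]^grid$a[i]
        expect_equal(finalGrade(grid$g[i], grid$a[i], grid$t[i]),
                     if (v >= grid$t[i]) v else 0)
    }
    # monotone in gRest; softer alpha is more forgiving below 1
    for (a in c(0.1, 1, 4)) {
        gs <- vapply(seq(0, 1, 0.1), finalGrade, numeric(1), alpha = a)
        expect_true(all(diff(gs) >= 0))
    }
    expect_true(all(diff(vapply(c(0.1, 0.5, 1, 2, 10), function(a)
        finalGrade(0.7, alpha = a), numeric(1))) <= 0))
    expect_error(finalGrade(0.5, alpha = 20), "alpha")
})

test_that("an identical answer grades exactly 1 through the whole pipeline", {
    q <- questionSpec(DA_REF)
    res <- gradeAnswer(parseReaction(DA_REF), q)
    expect_identical(res@grade, 1)
    expect_identical(res@gSim, 1)
    expect_equal(res@bestReference, 1L)
})

test_that("questions with alternative references accept either tautomer", {
    fam <- generateFixture("keto_enol_tautomers", "none", seed = 1)
    expect_length(fam$question@references, 2L)
    enamine <- gradeAnswer(fam$answer, fam$question)
    expect_identical(enamine@grade, 1)
    imine <- parseReaction(paste0(
        "[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[O:6])[CH3:7].[NH3:8]",
        ">>[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[NH:8])[CH3:7].[OH2:6]"))
    res <- gradeAnswer(imine, fam$question)
    expect_identical(res@grade, 1)
    expect_equal(res@bestReference, 1L)
})

test_that("a template subtracts its own contribution from the grade", {
    # template: the mapped dienophile with its bond-order change pre-drawn
    q <- questionSpec(DA_REF, template = "[CH2:1]=[CH2:2]>>[CH2:1][CH2:2]")
    full <- gradeAnswer(parseReaction(DA_REF), q)
    expect_identical(full@grade, 1)     # gSim 1 -> (1-gTpl)/(1-gTpl)
    expect_true(!is.na(full@gTpl) && full@gTpl > 0 && full@gTpl < 1)
    # no answer at all: the template's own similarity earns nothing
    blank <- gradeAnswer(NULL, q)
    expect_equal(blank@gRest, 0)
    expect_equal(blank@grade, 0)
    expect_equal(blank@gSim, blank@gTpl)
    # a partially-better answer lands strictly between
    part <- gradeAnswer(parseReaction(DA_MISMAP), q)
    expect_true(part@grade < full@grade)
})

test_that("an invalid answer mapping grades 0 with a diagnostic, not an error", {
    q <- questionSpec(DA_REF)
    bad <- parseReaction("[CH2:1]=[CH2:1].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1")
    res <- gradeAnswer(bad, q)
    expect_equal(res@grade, 0)
    expect_false(res@diagnostics$mappingReport@valid)
    # but a broken reference is a question-configuration error
    qbad <- questionSpec("[CH3:1][CH3:1]>>[CH3:1][CH3:2]")
    expect_error(gradeAnswer(parseReaction(DA_REF), qbad), "question configuration")
})

test_that("grading is invariant under consistent renumbering of the answer", {
    set.seed(123)
    q <- questionSpec(DA_REF)
    for (smi in c(DA_METHYL, DA_MISMAP)) {
        base <- gradeAnswer(parseReaction(smi), q)@grade
        for (i in 1:20) {
            rxn <- permuteMapNumbers(parseReaction(smi),
                                     randomMapPermutation(parseReaction(smi)))
            expect_identical(gradeAnswer(rxn, q)@grade, base)
        }
    }
})

test_that("grade result JSON carries the intermediates", {
    res <- gradeAnswer(parseReaction(DA_METHYL), questionSpec(DA_REF))
    parsed <- jsonlite::fromJSON(gradeResultJSON(res))
    expect_equal(parsed$g, res@grade)
    expect_equal(parsed$g_sim, res@gSim)
    expect_equal(parsed$best_reference, 1L)
    expect_true(parsed$mapping$valid)
})
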