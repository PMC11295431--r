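# InChI-layer stereochemistry comparison (needs the obabel CLI).

SN2_REF <- paste0("[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH3:4]",
                  ">>[CH3:1][C@@H:2]([OH:7])[CH2:3][CH3:4].[Br-:6]")
SN2_RETENTION <- paste0("[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH3:4]",
                        ">>[CH3:1][C@H:2]([OH:7])[CH2:3][CH3:4].[Br-:6]")

test_that("identical stereochemistry scores all centers correct", {
    a <- stereoAssess(parseReaction(SN2_REF), parseReaction(SN2_REF))
    expect_equal(a@correct, a@total)
    expect_equal(a@total, 2L)      # one R/S center on each side
    expect_equal(stereoGrade(a, 1), 1)
})

test_that("an inverted center is counted incorrect", {
    a <- stereoAssess(parseReaction(SN2_RETENTION), parseReaction(SN2_REF))
    expect_equal(a@total, 2L)
    expect_equal(a@correct, 1L)    # reactant side still right, product inverted
    expect_equal(stereoGrade(a, 1), 0.5)
})

test_that("double-bond Z/E centers come from the /b layer", {
    ez <- function(s) parseReaction(paste0("[CH3:1]/[CH:2]=[CH:3]/[CH3:4]>>", s))
    refE <- ez("[CH3:1]/[CH:2]=[CH:3]/[CH3:4]")
    ansZ <- ez("[CH3:1]/[CH:2]=[CH:3]\\[CH3:4]")
    a <- stereoAssess(ansZ, refE)
    expect_equal(a@total, 2L)
    expect_equal(a@correct, 1L)
})

test_that("the stereo stage gates on perfect constitutional similarity", {
    a <- stereoAssess(parseReaction(SN2_REF), parseReaction(SN2_REF))
    expect_equal(stereoGrade(a, 0.8), 0)   # any gSim != 1 scores 0
    none <- stereoAssess(parseReaction(DA_REF), parseReaction(DA_REF))
    expect_equal(none@total, 0L)
    expect_equal(stereoGrade(none, 1), 1)  # no centers to judge: stage passes
})

test_that("enantiomeric molecules disagree on every center after /m normalization", {
    # (2R,3R)- vs (2S,3S)-2,3-dichlorobutane: same /t layer, opposite /m
    two <- function(core) parseReaction(paste0(core, ">>", core))
    ref <- two("[CH3:1][C@H:2]([Cl:5])[C@@H:3]([Cl:6])[CH3:4]")
    ent <- two("[CH3:1][C@@H:2]([Cl:5])[C@H:3]([Cl:6])[CH3:4]")
    a <- stereoAssess(ent, ref)
    expect_equal(a@correct, 0L)
    expect_equal(a@total, 4L)
})

test_that("stereo grading inside the pipeline follows the decision network", {
    q <- questionSpec(SN2_REF, stereo = TRUE)
    expect_identical(gradeAnswer(parseReaction(SN2_REF), q)@grade, 1)
    flip <- gradeAnswer(parseReaction(SN2_RETENTION), q)
    expect_equal(flip@gSim, 1)
    expect_equal(flip@grade, 0.5)
    # constitutional error with stereo requested: 0 regardless of centers
    other <- parseReaction(paste0(
        "[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH2:4][CH3:8]",
        ">>[CH3:1][C@@H:2]([OH:7])[CH2:3][CH2:4][CH3:8].[Br-:6]"))
    res <- gradeAnswer(other, q)
    expect_lt(res@gSim, 1)
    expect_equal(res@grade, 0)
})
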