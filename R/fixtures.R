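#' @include question.R
NULL

## Small multiplicative congruential generator so fixture generation is
## deterministic without touching R's global RNG state.
.lcg <- function(seed) {
    state <- (as.numeric(seed) %% 2147483647)
    if (state <= 0) state <- state + 2147483646
    function() {
        state <<- (state * 16807) %% 2147483647
        state / 2147483647
    }
}

.lcgShuffle <- function(x, rng) {
    n <- length(x)
    for (i in seq_len(n - 1L)) {
        j <- i + floor(rng() * (n - i + 1L))
        tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
    }
    x
}

.stripMaps <- function(rxn) {
    strip <- function(m) {
        m@atoms$map <- 0L
        m
    }
    rxn@reactants <- lapply(rxn@reactants, strip)
    rxn@products <- lapply(rxn@products, strip)
    rxn
}

## Per-family reference reactions and perturbed answers, as mapped reaction
## SMILES.  `center_mismap` swaps map numbers of same-element atoms at the
## reaction center on one side (AAM stays valid, dynamic bonds go wrong);
## `peripheral_substituent` adds a methyl/ethyl away from the center.
.FIXTURE_FAMILIES <- list(
    diels_alder = list(
        references = "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1",
        stereo = FALSE,
        answers = list(
            none = "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1",
            peripheral_substituent = "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH:6][CH3:7]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH:6]1[CH3:7]",
            center_mismap = "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:6][CH2:5][CH:4]=[CH:3][CH2:2]1")),
    sn2 = list(
        references = "[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH3:4]>>[CH3:1][C@@H:2]([OH:7])[CH2:3][CH3:4].[Br-:6]",
        stereo = TRUE,
        answers = list(
            none = "[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH3:4]>>[CH3:1][C@@H:2]([OH:7])[CH2:3][CH3:4].[Br-:6]",
            stereo_flip = "[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH3:4]>>[CH3:1][C@H:2]([OH:7])[CH2:3][CH3:4].[Br-:6]",
            peripheral_substituent = "[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH2:4][CH3:8]>>[CH3:1][C@@H:2]([OH:7])[CH2:3][CH2:4][CH3:8].[Br-:6]",
            center_mismap = "[OH-:7].[CH3:1][C@H:2]([Br:6])[CH2:3][CH3:4]>>[CH3:1][C@@H:3]([OH:7])[CH2:2][CH3:4].[Br-:6]")),
    esterification = list(
        references = "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>[CH3:1][C:2](=[O:3])[O:6][CH3:5].[OH2:4]",
        stereo = FALSE,
        answers = list(
            none = "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>[CH3:1][C:2](=[O:3])[O:6][CH3:5].[OH2:4]",
            peripheral_substituent = "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][CH2:7][OH:6]>>[CH3:1][C:2](=[O:3])[O:6][CH2:7][CH3:5].[OH2:4]",
            center_mismap = "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]")),
    keto_enol_tautomers = list(
        references = c(
            "[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[O:6])[CH3:7].[NH3:8]>>[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[NH:8])[CH3:7].[OH2:6]",
            "[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[O:6])[CH3:7].[NH3:8]>>[CH3:1][C:2](=[O:3])[CH:4]=[C:5]([NH2:8])[CH3:7].[OH2:6]"),
        stereo = FALSE,
        answers = list(
            none = "[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[O:6])[CH3:7].[NH3:8]>>[CH3:1][C:2](=[O:3])[CH:4]=[C:5]([NH2:8])[CH3:7].[OH2:6]",
            peripheral_substituent = "[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[O:6])[CH2:7][CH3:9].[NH3:8]>>[CH3:1][C:2](=[O:3])[CH:4]=[C:5]([NH2:8])[CH2:7][CH3:9].[OH2:6]",
            center_mismap = "[CH3:1][C:2](=[O:3])[CH2:4][C:5](=[O:6])[CH3:7].[NH3:8]>>[CH3:1][C:5](=[O:3])[CH:4]=[C:2]([NH2:8])[CH3:7].[OH2:6]")))

#' Generate a toy grading fixture
#'
#' Deterministically builds a question and a (possibly perturbed) student
#' answer for one of four classroom reaction families: a Diels-Alder
#' cycloaddition, an SN2 substitution with Walden inversion (graded with
#' the stereo flag), a Fischer esterification, and the
#' pentane-2,4-dione + ammonia condensation whose imine/enamine tautomers
#' motivate questions with two alternative correct references.
#'
#' Perturbations: `none` (grades exactly 1), `peripheral_substituent`
#' (extra alkyl away from the reaction center: partial credit, higher
#' than the center error), `center_mismap` (map numbers of same-element
#' atoms cross-swapped at the reaction center: valid AAM, wrong dynamic
#' bonds, heavy penalty), `stereo_flip` (sn2 only: constitution and
#' mapping right, configuration inverted), `unmapped` (all map numbers
#' removed).  The seed drives a consistent random renumbering of the
#' answer's map numbers - equivalent mappings must grade identically, so
#' the expected relations hold for every seed.
#'
#' @param family one of `"diels_alder"`, `"sn2"`, `"esterification"`,
#'   `"keto_enol_tautomers"`.
#' @param perturbation see above.
#' @param seed integer.
#' @return a list (fixture case) with elements `name`, `question`
#'   (\linkS4class{QuestionSpec}), `answer` (\linkS4class{Reaction}),
#'   `perturbation` and `expectedRelation` (qualitative constraint on the
#'   grade).
#' @examples
#' fx <- generateFixture("diels_alder", "none", seed = 1)
#' gradeAnswer(fx$answer, fx$question)
#' @export
generateFixture <- function(family = c("diels_alder", "sn2", "esterification",
                                       "keto_enol_tautomers"),
                            perturbation = c("none", "peripheral_substituent",
                                             "center_mismap", "stereo_flip",
                                             "unmapped"),
                            seed = 1L) {
    family <- match.arg(family)
    perturbation <- match.arg(perturbation)
    fam <- .FIXTURE_FAMILIES[[family]]
    rng <- .lcg(seed)

    question <- questionSpec(as.list(fam$references),
                             stereo = fam$stereo &&
                                 perturbation %in% c("none", "stereo_flip"))
    base <- if (perturbation == "unmapped") fam$answers$none
            else fam$answers[[perturbation]]
    if (is.null(base))
        stop(sprintf("perturbation '%s' is not defined for family '%s'",
                     perturbation, family), call. = FALSE)
    answer <- parseReaction(base)
    if (perturbation == "unmapped") {
        answer <- .stripMaps(answer)
    } else {
        ## consistent random renumbering: same transformation, new labels
        maps <- sort(unique(unlist(lapply(c(answer@reactants, answer@products),
                                          function(m) m@atoms$map))))
        maps <- maps[maps > 0L]
        perm <- stats::setNames(.lcgShuffle(seq_along(maps), rng), maps)
        answer <- permuteMapNumbers(answer, perm)
    }
    expected <- switch(perturbation,
        none = "grade == 1",
        peripheral_substituent = "0 < grade < 1; grade > center_mismap grade",
        center_mismap = "0 <= grade < peripheral_substituent grade",
        stereo_flip = "0 < grade < 1 (stereo proportion)",
        unmapped = "grade < 1")
    list(name = sprintf("%s_%s_seed%d", family, perturbation, as.integer(seed)),
         question = question, answer = answer,
         perturbation = perturbation, expectedRelation = expected)
}
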