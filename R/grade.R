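#' @include stereo.R
NULL

#' Template adjustment of the similarity score
#'
#' When the teacher supplies a reaction template, its content is free to
#' the student and must earn nothing: the score is renormalized to the
#' part of the reaction the student actually contributed,
#' `(gSim - gTpl) / (1 - gTpl)`, clamped below at 0 (a student who
#' destroys template content does not go negative).  Without a template
#' the similarity passes through unchanged.  A template scoring 1
#' against the reference already *is* a full correct answer and leaves
#' nothing to grade: degenerate, rejected with an error.
#'
#' @param gSim best reference similarity in `[0, 1]`.
#' @param gTpl template-vs-best-reference similarity, or `NA`/`NULL` when
#'   no template is set.
#' @return the adjusted score in `[0, 1]`.
#' @examples
#' templateAdjust(0.75, 0.5)  # 0.5
#' templateAdjust(0.9, NA)    # 0.9
#' @export
templateAdjust <- function(gSim, gTpl = NA_real_) {
    stopifnot(gSim >= 0, gSim <= 1)
    if (is.null(gTpl) || is.na(gTpl)) return(gSim)
    stopifnot(gTpl >= 0, gTpl <= 1)
    if (gTpl >= 1 - 1e-12)
        stop("degenerate template: it already matches a full correct answer",
             call. = FALSE)
    max(0, (gSim - gTpl) / (1 - gTpl))
}

#' Softness transform of the grade
#'
#' Raises the score to the softness exponent alpha and applies the
#' cutoff t: `gRest^alpha` if that is at least `t`, else 0.  Small alpha
#' tolerates more errors (concave lift of partial scores), large alpha
#' deteriorates the grade for any deviation; t discards low partial
#' credit entirely.  Teacher-facing ranges: alpha in [0.1, 10]
#' (default 1), t in [0, 1] (default 0).
#'
#' @param gRest score in `[0, 1]`.
#' @param alpha softness exponent.
#' @param threshold cutoff t.
#' @return the final grade g in `[0, 1]`.
#' @examples
#' finalGrade(0.81, alpha = 0.5)            # 0.9
#' finalGrade(0.9, alpha = 2, threshold = 0.85)  # 0.81 < 0.85 -> 0
#' @export
finalGrade <- function(gRest, alpha = 1, threshold = 0) {
    stopifnot(gRest >= 0, gRest <= 1,
              alpha >= 0.1, alpha <= 10,
              threshold >= 0, threshold <= 1)
    g <- gRest^alpha
    if (g >= threshold) g else 0
}

.questionFragmentVectors <- function(question) {
    scheme <- question@scheme
    refFV <- lapply(question@references, function(r)
        tryCatch(enumerateFragments(r, scheme), error = function(e)
            stop("question configuration error in a reference reaction: ",
                 conditionMessage(e), call. = FALSE)))
    tplFV <- if (!is.null(question@template))
        tryCatch(enumerateFragments(buildCGR(question@template), scheme),
                 error = function(e)
                     stop("question configuration error in the template: ",
                          conditionMessage(e), call. = FALSE))
    list(references = refFV, template = tplFV)
}

.gradeCore <- function(answerFV, answerRxn, question, mappingReport) {
    qfv <- .questionFragmentVectors(question)
    best <- bestReferenceSimilarity(answerFV, qfv$references)
    gSim <- best$gSim
    gTpl <- if (!is.null(qfv$template))
        suppressWarnings(tanimoto(qfv$template, qfv$references[[best$index]]))
    else NA_real_
    gRest <- templateAdjust(gSim, gTpl)
    assessment <- NULL
    if (question@stereo) {
        if (gSim >= 1 - 1e-12 && !is.null(answerRxn)) {
            assessment <- stereoAssess(answerRxn,
                                       question@references[[best$index]])
            gRest <- stereoGrade(assessment, gSim)
        } else {
            gRest <- 0
        }
    }
    g <- finalGrade(gRest, question@alpha, question@threshold)
    diag <- list(mappingReport = mappingReport,
                 similarities = best$all,
                 answerFragments = length(answerFV@counts),
                 referenceFragments = vapply(qfv$references, function(f)
                     length(f@counts), integer(1)))
    if (!is.null(assessment)) diag$stereo <- assessment
    new("GradeResult", gSim = gSim, bestReference = best$index,
        gTpl = gTpl, gRest = gRest, grade = g, diagnostics = diag)
}

#' Grade a student's reaction against a question
#'
#' The full grading pipeline: aromatize and superimpose the answer, every
#' reference and the optional template into CGRs, fragment them under the
#' question's scheme, take the maximal count-Tanimoto similarity over the
#' references (`gSim`), subtract out the template contribution
#' ([templateAdjust()]), optionally assess stereochemistry through the
#' InChI layers ([stereoAssess()], [stereoGrade()]) and apply the
#' softness transform ([finalGrade()]).  All intermediates are recorded
#' in the result's diagnostics.
#'
#' An invalid atom-to-atom mapping in the *answer* is a student error:
#' the reaction is graded 0 with the mapping report as diagnostic.  An
#' invalid reference or template is a question-configuration error and
#' throws.  `answer = NULL` represents a student who submitted nothing
#' (meaningful with a template: the template's own similarity is then
#' subtracted from itself, earning 0).
#'
#' @param answer a mapped \linkS4class{Reaction}, or `NULL`.
#' @param question a \linkS4class{QuestionSpec}.
#' @return a \linkS4class{GradeResult}.
#' @examples
#' q <- questionSpec("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
#' gradeAnswer(parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]"), q)
#' @rdname gradeAnswer
#' @export
setMethod("gradeAnswer", signature("Reaction", "QuestionSpec"),
    function(answer, question) {
        validObject(question)
        rep <- validateMapping(answer)
        if (!rep@valid) {
            nref <- length(question@references)
            return(new("GradeResult", gSim = 0, bestReference = 1L,
                       gTpl = NA_real_, gRest = 0, grade = 0,
                       diagnostics = list(
                           mappingReport = rep,
                           similarities = rep_len(NA_real_, nref),
                           error = "invalid atom-to-atom mapping in the answer")))
        }
        answerFV <- enumerateFragments(answer, question@scheme)
        .gradeCore(answerFV, answer, question, rep)
    })

#' @rdname gradeAnswer
#' @export
setMethod("gradeAnswer", signature("NULL", "QuestionSpec"),
    function(answer, question) {
        validObject(question)
        ## a blank submission is the template itself: its similarity is the
        ## template's own, and the template adjustment zeroes it out
        answerFV <- if (!is.null(question@template))
            enumerateFragments(buildCGR(question@template), question@scheme)
        else new("FragmentVector")
        .gradeCore(answerFV, NULL, question, NULL)
    })
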