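#' @include grade.R
NULL

.asReaction <- function(x, template = FALSE) {
    if (is(x, "Reaction")) return(x)
    if (is.character(x) && length(x) == 1L) {
        if (grepl("\\.(rxn|smi|smiles|txt)$", x, ignore.case = TRUE) &&
            file.exists(x))
            return(readReaction(x, template = template))
        return(parseReaction(x, template = template))
    }
    stop("cannot interpret this as a reaction: supply a Reaction object, ",
         "a reaction SMILES, or a file path", call. = FALSE)
}

#' Construct a question specification
#'
#' @param references one reaction or a list of 1..N alternative correct
#'   reactions (Reaction objects, reaction SMILES strings, or file
#'   paths), all mapped.
#' @param template optional partial reaction the student completes
#'   (Reaction/string/path); parsed with the template flag so one side
#'   may be empty.
#' @param alpha softness exponent in [0.1, 10].
#' @param threshold cutoff t in [0, 1].
#' @param stereo logical, grade stereochemistry.
#' @param scheme a \linkS4class{FragmentationScheme}.
#' @return a \linkS4class{QuestionSpec}.
#' @examples
#' questionSpec("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]", alpha = 2)
#' @export
questionSpec <- function(references, template = NULL, alpha = 1,
                         threshold = 0, stereo = FALSE,
                         scheme = fragmentationScheme()) {
    if (!is.list(references)) references <- list(references)
    refs <- lapply(references, .asReaction)
    tpl <- if (!is.null(template)) .asReaction(template, template = TRUE)
    new("QuestionSpec", references = refs, template = tpl,
        alpha = as.numeric(alpha), threshold = as.numeric(threshold),
        stereo = isTRUE(stereo), scheme = scheme)
}

#' Read a question specification from JSON
#'
#' The grading contract document:
#' \preformatted{
#' {"references": ["...reaction SMILES or RXN path..."],
#'  "template": null,
#'  "alpha": 1.0, "threshold": 0.0, "stereo": false,
#'  "fragmentation": {"scheme": "IAB", "minLength": 2, "maxLength": 4,
#'                    "formalCharge": true, "radicalsLonePairs": true}}
#' }
#' `fragmentation` may also be a path to the XML configuration file.
#' Relative RXN paths are resolved against the JSON file's directory.
#'
#' @param path JSON file path, or a JSON string.
#' @return a \linkS4class{QuestionSpec}.
#' @export
readQuestion <- function(path) {
    base <- if (file.exists(path)) dirname(path) else "."
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$references) || !length(doc$references))
        stop("question JSON lacks a non-empty 'references' array", call. = FALSE)
    resolve <- function(x) {
        if (is.character(x) && grepl("\\.rxn$", x, ignore.case = TRUE) &&
            !file.exists(x) && file.exists(file.path(base, x)))
            file.path(base, x)
        else x
    }
    frag <- doc$fragmentation
    scheme <- if (is.null(frag)) fragmentationScheme()
        else if (is.character(frag)) loadFragmentationConfig(frag)
        else fragmentationScheme(
            kind = {
                tok <- frag$scheme
                if (is.null(tok)) "atoms_and_bonds"
                else if (tok %in% names(.SCHEME_TOKENS)) .SCHEME_TOKENS[[tok]]
                else .configError("scheme", sprintf("unknown scheme '%s'", tok))
            },
            minLen = if (is.null(frag$minLength)) 2L else frag$minLength,
            maxLen = if (is.null(frag$maxLength)) 4L else frag$maxLength,
            formalCharge = if (is.null(frag$formalCharge)) TRUE
                           else isTRUE(frag$formalCharge),
            radicals = if (is.null(frag$radicalsLonePairs)) TRUE
                       else isTRUE(frag$radicalsLonePairs))
    questionSpec(
        references = lapply(doc$references, resolve),
        template = if (!is.null(doc$template)) resolve(doc$template),
        alpha = if (is.null(doc$alpha)) 1 else doc$alpha,
        threshold = if (is.null(doc$threshold)) 0 else doc$threshold,
        stereo = isTRUE(doc$stereo),
        scheme = scheme)
}

#' Serialize a grade result as JSON
#'
#' Emits the grade with all intermediates: `g`, `g_sim`, `g_tpl`,
#' `g_rest`, the best reference index, per-reference similarities,
#' fragment-vector sizes, the mapping report and, when computed, the
#' stereo assessment.
#'
#' @param result a \linkS4class{GradeResult}.
#' @param pretty logical, indent the JSON.
#' @return a JSON string.
#' @export
gradeResultJSON <- function(result, pretty = TRUE) {
    stopifnot(is(result, "GradeResult"))
    d <- result@diagnostics
    rep <- d$mappingReport
    obj <- list(
        g = result@grade,
        g_sim = result@gSim,
        g_tpl = if (is.na(result@gTpl)) NULL else result@gTpl,
        g_rest = result@gRest,
        best_reference = result@bestReference,
        similarities = as.numeric(d$similarities),
        answer_fragments = d$answerFragments,
        reference_fragments = d$referenceFragments,
        mapping = if (!is.null(rep)) list(
            valid = rep@valid,
            mapped_pairs = rep@mappedPairs,
            orphans_reactant = rep@orphansReactant,
            orphans_product = rep@orphansProduct,
            duplicates = rep@duplicates,
            element_mismatches = rep@elementMismatches),
        stereo = if (!is.null(d$stereo)) list(
            correct_centers = d$stereo@correct,
            total_centers = d$stereo@total),
        error = d$error)
    obj <- obj[!vapply(obj, is.null, logical(1))]
    jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty, digits = NA)
}
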