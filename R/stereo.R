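#' @include similarity.R
NULL

.haveObabel <- function() nzchar(Sys.which("obabel"))

## Standard InChI of one molecule through the OpenBabel CLI.  The original
## serialized form (SMILES token or molblock) is used when available so
## wedge/slash stereochemistry survives; otherwise the graph is re-serialized
## (stereo-free).
.moleculeInChI <- function(mol) {
    if (!.haveObabel())
        stop("stereochemistry assessment requires the 'obabel' command line tool",
             call. = FALSE)
    args <- if (identical(mol@sourceFormat, "molblock")) {
        tf <- tempfile(fileext = ".mol")
        writeLines(strsplit(mol@source, "\n")[[1]], tf)
        on.exit(unlink(tf))
        c("-imol", tf, "-oinchi")
    } else {
        smi <- if (identical(mol@sourceFormat, "smiles")) mol@source
               else .writeSmilesMolecule(mol)
        c(shQuote(paste0("-:", smi)), "-oinchi")
    }
    out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = FALSE))
    inchi <- grep("^InChI=", out, value = TRUE)
    if (!length(inchi))
        stop("InChI generation failed for molecule ", mol@source, call. = FALSE)
    inchi[1]
}

## Decompose an InChI into a constitution key (formula + connectivity +
## hydrogen + charge layers) and normalized stereo descriptors.
.inchiStereo <- function(inchi) {
    parts <- strsplit(inchi, "/", fixed = TRUE)[[1]]
    layer <- function(prefix) {
        hit <- grep(paste0("^", prefix, "[^A-Za-z]"), parts, value = TRUE)
        hit <- c(hit, parts[parts == prefix])  # bare prefix (unlikely)
        if (!length(hit)) return(character())
        strsplit(substr(hit[1], 2, nchar(hit[1])), ",", fixed = TRUE)[[1]]
    }
    formula <- if (length(parts) >= 2L) parts[2] else ""
    const <- paste(c(formula,
                     grep("^[chqp][0-9]", parts[-seq_len(min(2, length(parts)))],
                          value = TRUE)), collapse = "/")
    tlab <- layer("t")
    m <- layer("m")
    ## /m1 inverts the reference frame: flip tetrahedral signs so that
    ## enantiomers get opposite, comparable labels
    if (length(m) && m[1] == "1")
        tlab <- chartr("+-", "-+", tlab)
    list(constitution = const,
         tetra = if (length(tlab)) paste0("t:", tlab) else character(),
         dbond = {
             b <- layer("b")
             if (length(b)) paste0("b:", b) else character()
         },
         formula = formula)
}

.sideStereoInfo <- function(mols) lapply(mols, function(m) .inchiStereo(.moleculeInChI(m)))

#' Assess stereochemistry via InChI stereo layers
#'
#' Computes standard InChI strings for every reactant and product of the
#' student's and the reference reaction, pairs molecules across the two
#' reactions by identical formula/connectivity/hydrogen layers, and
#' compares the stereo descriptors: tetrahedral centers from the `/t`
#' layer (signs normalized by the `/m` mirror flag so enantiomers
#' disagree on every center) and double-bond Z/E centers from `/b`.
#' Totals are summed over all molecules of the reference; a reference
#' molecule with no constitutional partner in the answer has all its
#' centers counted incorrect and is flagged in the detail table.
#'
#' The comparison presumes the two reactions are constitutionally
#' identical molecule-by-molecule, which the grading pipeline guarantees
#' by only reaching this stage at `gSim = 1`: a constitutional change
#' could silently alter descriptor priorities.
#'
#' @param answer,reference \linkS4class{Reaction} objects.
#' @return a \linkS4class{StereoAssessment}.
#' @export
stereoAssess <- function(answer, reference) {
    stopifnot(is(answer, "Reaction"), is(reference, "Reaction"))
    correct <- 0L; total <- 0L
    detail <- data.frame(side = character(), formula = character(),
                         centers = integer(), correct = integer(),
                         paired = logical(), stringsAsFactors = FALSE)
    for (side in c("reactants", "products")) {
        refInfo <- .sideStereoInfo(slot(reference, side))
        ansInfo <- .sideStereoInfo(slot(answer, side))
        used <- logical(length(ansInfo))
        for (ri in refInfo) {
            centers <- c(ri$tetra, ri$dbond)
            hit <- which(!used & vapply(ansInfo, function(ai)
                identical(ai$constitution, ri$constitution), logical(1)))
            if (length(hit)) {
                used[hit[1]] <- TRUE
                ai <- ansInfo[[hit[1]]]
                ok <- sum(centers %in% c(ai$tetra, ai$dbond))
                paired <- TRUE
            } else {
                ok <- 0L
                paired <- FALSE
            }
            correct <- correct + as.integer(ok)
            total <- total + length(centers)
            detail <- rbind(detail, data.frame(
                side = side, formula = ri$formula,
                centers = length(centers), correct = as.integer(ok),
                paired = paired, stringsAsFactors = FALSE))
        }
    }
    new("StereoAssessment", correct = correct, total = total, detail = detail)
}

#' Stereochemistry stage of the grade
#'
#' The proportion of correctly drawn stereo centers over the total stereo
#' centers of the reference - but only when the constitutional similarity
#' is perfect.  Any `gSim` short of 1 returns 0: with a constitutional
#' difference the InChI priority labels are not comparable, so the stereo
#' stage cannot award partial credit.  A reference without stereo centers
#' (0/0) passes the stage with 1.
#'
#' @param assessment a \linkS4class{StereoAssessment}.
#' @param gSim the best reference similarity.
#' @return the post-stereo score in `[0, 1]`.
#' @export
stereoGrade <- function(assessment, gSim) {
    stopifnot(is(assessment, "StereoAssessment"))
    if (gSim < 1 - 1e-12) return(0)
    if (assessment@total == 0L) return(1)
    assessment@correct / assessment@total
}
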