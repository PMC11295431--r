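#' @include fragments.R
NULL

#' Count-based Tanimoto similarity
#'
#' The count form of the Tanimoto coefficient over the union of fragment
#' keys: sum(A*B) / (sum(A^2) + sum(B^2) - sum(A*B)).  Counts, not bits:
#' a fragment occurring twice weighs more than one occurring once.
#' Symmetric, bounded in `[0, 1]`, and 1 exactly for identical vectors.
#' Two empty vectors compare as 0 with a warning - a blank answer to a
#' blank-CGR question must not score 1.
#'
#' @param a,b \linkS4class{FragmentVector} objects.
#' @return similarity in `[0, 1]`.
#' @examples
#' fv <- function(...) new("FragmentVector", counts = c(...))
#' tanimoto(fv(x = 2L, y = 1L), fv(x = 1L, y = 1L, z = 1L))  # 3/(5+3-3) = 0.6
#' @rdname tanimoto
#' @export
setMethod("tanimoto", signature("FragmentVector", "FragmentVector"),
    function(a, b) {
        ca <- a@counts; cb <- b@counts
        if (!length(ca) && !length(cb)) {
            warning("both fragment vectors are empty; Tanimoto defined as 0",
                    call. = FALSE)
            return(0)
        }
        keys <- union(names(ca), names(cb))
        av <- as.numeric(ca[keys]); av[is.na(av)] <- 0
        bv <- as.numeric(cb[keys]); bv[is.na(bv)] <- 0
        ab <- sum(av * bv)
        ab / (sum(av^2) + sum(bv^2) - ab)
    })

#' Best similarity against the reference answers
#'
#' The maximal Tanimoto similarity of a student's fragment vector over
#' the 1..N teacher reference vectors, and the reference achieving it.
#' Ties go to the lowest index, and the template adjustment is computed
#' against that reference.
#'
#' @param answer a \linkS4class{FragmentVector}.
#' @param references non-empty list of \linkS4class{FragmentVector}.
#' @return list with `gSim` (numeric) and `index` (1-based integer), plus
#'   `all` with the per-reference similarities.
#' @export
bestReferenceSimilarity <- function(answer, references) {
    stopifnot(is(answer, "FragmentVector"), length(references) >= 1L)
    sims <- vapply(references, function(r) suppressWarnings(tanimoto(answer, r)),
                   numeric(1))
    idx <- which.max(sims)          # which.max returns the first maximum
    list(gSim = sims[idx], index = as.integer(idx), all = sims)
}
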