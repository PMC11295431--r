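#' @include write.R
NULL

.sideMaps <- function(mols) {
    do.call(rbind, c(list(data.frame(map = integer(), element = character(),
                                     stringsAsFactors = FALSE)),
                     lapply(mols, function(m) {
                         at <- m@atoms
                         data.frame(map = at$map, element = at$element,
                                    stringsAsFactors = FALSE)[at$map > 0L, ,
                                                              drop = FALSE]
                     })))
}

#' Validate an atom-to-atom mapping
#'
#' Checks the atom map numbers of a reaction: within each side every map
#' number must be used at most once (injectivity), and a map number
#' present on both sides must label atoms of the same element.  Map
#' numbers present on one side only (orphans: leaving groups, unbalanced
#' classroom equations) and unmapped atoms (map 0) are legal; they are
#' reported but do not invalidate the mapping.  Problems are reported,
#' never thrown.
#'
#' @param rxn a \linkS4class{Reaction}.
#' @return a \linkS4class{MappingReport}; `valid` is `TRUE` iff there are
#'   no duplicates and no element mismatches.
#' @examples
#' validateMapping(parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]"))
#' # duplicate map number on one side:
#' validateMapping(parseReaction("[CH3:1][CH3:1]>>[CH3:1][CH3:2]"))
#' @rdname validateMapping
#' @export
setMethod("validateMapping", "Reaction", function(rxn) {
    r <- .sideMaps(rxn@reactants)
    p <- .sideMaps(rxn@products)
    dupR <- unique(r$map[duplicated(r$map)])
    dupP <- unique(p$map[duplicated(p$map)])
    dups <- sort(unique(c(dupR, dupP)))
    shared <- intersect(r$map, p$map)
    mism <- sort(unique(Filter(function(m) {
        !identical(r$element[match(m, r$map)], p$element[match(m, p$map)])
    }, setdiff(shared, dups))))
    new("MappingReport",
        valid = length(dups) == 0L && length(mism) == 0L,
        mappedPairs = length(shared),
        orphansReactant = sort(setdiff(r$map, p$map)),
        orphansProduct = sort(setdiff(p$map, r$map)),
        duplicates = as.integer(dups),
        elementMismatches = as.integer(mism))
})

#' Renumber an atom-to-atom mapping consistently
#'
#' Applies a permutation to the map numbers of both sides of a reaction.
#' Consistent renumbering describes the same transformation: the CGR, the
#' fragment vector and hence the grade are unchanged.  Used to exercise
#' that invariance in tests and fixtures.
#'
#' @param rxn a \linkS4class{Reaction}.
#' @param perm named integer vector: `perm[as.character(old)]` is the new
#'   map number.  Map numbers absent from `perm` (and unmapped atoms) are
#'   left untouched.  Must be injective over the supplied values.
#' @return the renumbered \linkS4class{Reaction}.
#' @export
permuteMapNumbers <- function(rxn, perm) {
    stopifnot(is(rxn, "Reaction"))
    if (anyDuplicated(perm)) stop("permutation is not injective", call. = FALSE)
    relabel <- function(mol) {
        idx <- match(as.character(mol@atoms$map), names(perm))
        hit <- !is.na(idx) & mol@atoms$map > 0L
        ## `source` is kept: InChI generation ignores atom maps, and the
        ## graph (not the text) is authoritative for everything else
        mol@atoms$map[hit] <- as.integer(perm[idx[hit]])
        mol
    }
    rxn@reactants <- lapply(rxn@reactants, relabel)
    rxn@products <- lapply(rxn@products, relabel)
    rxn
}
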