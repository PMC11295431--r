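#' @import methods
NULL

#' Accessors for molecular and reaction objects
#'
#' `atoms()` and `bonds()` return the atom and bond tables of a
#' \linkS4class{Molecule} or \linkS4class{CGR}; `reactants()` and
#' `products()` return the molecule lists of a \linkS4class{Reaction};
#' `counts()` returns the named count vector of a
#' \linkS4class{FragmentVector}.
#'
#' @param x object to access.
#' @return `atoms()`/`bonds()` a `data.frame`; `reactants()`/`products()` a
#'   list of \linkS4class{Molecule}; `counts()` a named integer vector.
#' @name accessors
#' @aliases atoms bonds reactants products counts
#' @examples
#' rxn <- parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
#' atoms(reactants(rxn)[[1]])
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setGeneric("reactants", function(x) standardGeneric("reactants"))

#' @rdname accessors
#' @export
setGeneric("products", function(x) standardGeneric("products"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname writeReaction
#' @export
setGeneric("writeReaction", function(rxn, dialect = c("reaction_smiles", "rxn_v2000"))
    standardGeneric("writeReaction"))

#' @rdname validateMapping
#' @export
setGeneric("validateMapping", function(rxn) standardGeneric("validateMapping"))

#' @rdname aromatize
#' @export
setGeneric("aromatize", function(x) standardGeneric("aromatize"))

#' @rdname buildCGR
#' @export
setGeneric("buildCGR", function(rxn, aromatize = TRUE) standardGeneric("buildCGR"))

#' @rdname enumerateFragments
#' @export
setGeneric("enumerateFragments", function(x, scheme = fragmentationScheme())
    standardGeneric("enumerateFragments"))

#' @rdname tanimoto
#' @export
setGeneric("tanimoto", function(a, b) standardGeneric("tanimoto"))

#' @rdname gradeAnswer
#' @export
setGeneric("gradeAnswer", function(answer, question) standardGeneric("gradeAnswer"))
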