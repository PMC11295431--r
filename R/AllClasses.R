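#' @include AllGenerics.R
NULL

.BOND_ORDERS <- c("single", "double", "triple", "aromatic")
.CGR_ORDERS  <- c("none", .BOND_ORDERS)

.emptyAtoms <- function() {
    data.frame(element = character(), charge = integer(), radical = integer(),
               map = integer(), explicit = logical(), aromatic = logical(),
               hcount = integer(), stringsAsFactors = FALSE)
}

.emptyBonds <- function() {
    data.frame(a = integer(), b = integer(), order = character(),
               stringsAsFactors = FALSE)
}

#' Molecule: a connection table with charges, radicals and atom maps
#'
#' A light molecular graph.  Atoms are rows of the `atoms` slot
#' (`element`, formal `charge`, unpaired-electron `radical` count, atom
#' `map` number with 0 meaning unmapped, `explicit` flag for hydrogens
#' drawn as graph nodes, `aromatic` perception flag and implicit-hydrogen
#' `hcount`); bonds are rows of the `bonds` slot (`a`, `b` atom indices,
#' 1-based, and an `order` among single/double/triple/aromatic).
#' Implicit hydrogens are bookkeeping only, never graph nodes.
#'
#' The `source`/`sourceFormat` slots retain the serialized form the
#' molecule was parsed from (reaction SMILES token or molfile block) so
#' that stereochemistry, which the graph does not carry, can be handed to
#' the InChI generator verbatim.
#'
#' @slot atoms data.frame of atoms.
#' @slot bonds data.frame of bonds.
#' @slot source character, original serialized text or `NA`.
#' @slot sourceFormat one of `"smiles"`, `"molblock"`, `"none"`.
#' @exportClass Molecule
setClass("Molecule",
    representation(atoms = "data.frame", bonds = "data.frame",
                   source = "character", sourceFormat = "character"),
    prototype(atoms = .emptyAtoms(), bonds = .emptyBonds(),
              source = NA_character_, sourceFormat = "none"))

setValidity("Molecule", function(object) {
    at <- object@atoms; bd <- object@bonds
    msgs <- character()
    if (!all(c("element", "charge", "radical", "map", "explicit") %in% names(at)))
        msgs <- c(msgs, "atom table lacks required columns")
    else {
        bad <- setdiff(at$element, .PERIODIC_SYMBOLS)
        if (length(bad))
            msgs <- c(msgs, paste0("unknown element symbol(s): ",
                                   paste(unique(bad), collapse = ", ")))
        if (any(at$map < 0)) msgs <- c(msgs, "negative atom map number")
        if (any(at$radical < 0)) msgs <- c(msgs, "negative radical count")
    }
    if (nrow(bd)) {
        if (any(bd$a == bd$b)) msgs <- c(msgs, "bond with identical endpoints")
        if (any(bd$a < 1 | bd$b < 1 | bd$a > nrow(at) | bd$b > nrow(at)))
            msgs <- c(msgs, "bond endpoint out of range")
        if (!all(bd$order %in% .BOND_ORDERS))
            msgs <- c(msgs, "bond order outside single/double/triple/aromatic")
        key <- paste(pmin(bd$a, bd$b), pmax(bd$a, bd$b))
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate bond between the same atom pair")
    }
    if (length(msgs)) msgs else TRUE
})

#' Reaction: mapped reactants and products
#'
#' The unit both teachers and students submit.  A non-template reaction
#' must have at least one reactant and one product molecule; an object
#' flagged `template` may leave either side empty (a teacher-supplied
#' partial drawing the student completes).
#'
#' @slot reactants,products lists of \linkS4class{Molecule}.
#' @slot template logical flag.
#' @exportClass Reaction
setClass("Reaction",
    representation(reactants = "list", products = "list", template = "logical"),
    prototype(reactants = list(), products = list(), template = FALSE))

setValidity("Reaction", function(object) {
    ok <- vapply(c(object@reactants, object@products), is, logical(1), "Molecule")
    if (!all(ok)) return("reactants/products must be Molecule objects")
    if (!isTRUE(object@template) &&
        (length(object@reactants) == 0L || length(object@products) == 0L))
        return("a non-template reaction needs at least one reactant and one product")
    TRUE
})

#' MappingReport: diagnosis of an atom-to-atom mapping
#'
#' Produced by [validateMapping()].  `valid` is `TRUE` exactly when no map
#' number is duplicated within a side and every cross-side pair agrees on
#' the element.  Orphans (a map number on one side only) are reported but
#' do not invalidate: leaving groups and unbalanced classroom equations
#' are common and are absorbed by the CGR builder.
#'
#' @slot valid logical.
#' @slot mappedPairs integer, map numbers present on both sides.
#' @slot orphansReactant,orphansProduct integer vectors of one-sided map numbers.
#' @slot duplicates integer vector of map numbers used twice on one side.
#' @slot elementMismatches integer vector of pairs differing in element.
#' @exportClass MappingReport
setClass("MappingReport",
    representation(valid = "logical", mappedPairs = "integer",
                   orphansReactant = "integer", orphansProduct = "integer",
                   duplicates = "integer", elementMismatches = "integer"))

setValidity("MappingReport", function(object) {
    want <- length(object@duplicates) == 0L && length(object@elementMismatches) == 0L
    if (!identical(object@valid, want))
        return("valid must be TRUE iff duplicates and elementMismatches are empty")
    TRUE
})

#' CGR: Condensed Graph of Reaction
#'
#' A single graph superimposing reactants and products by their atom map.
#' Each atom row carries the pair of formal charges and radical counts on
#' the two sides plus an `origin` (`both`, `reactant_only`,
#' `product_only`); each bond row carries the pair of bond orders
#' (`rOrder`, `pOrder`), with `"none"` where the bond is absent on a side.
#' A bond or atom whose pair members differ is *dynamic* and encodes part
#' of the transformation (e.g. a formed single bond is `none -> single`,
#' rendered `0>1`).
#'
#' @slot atoms data.frame: `element`, `rCharge`, `pCharge`, `rRadical`,
#'   `pRadical`, `origin`, `map`, `explicit`.
#' @slot bonds data.frame: `a`, `b`, `rOrder`, `pOrder`.
#' @exportClass CGR
setClass("CGR",
    representation(atoms = "data.frame", bonds = "data.frame"),
    prototype(
        atoms = data.frame(element = character(), rCharge = integer(),
                           pCharge = integer(), rRadical = integer(),
                           pRadical = integer(), origin = character(),
                           map = integer(), explicit = logical(),
                           stringsAsFactors = FALSE),
        bonds = data.frame(a = integer(), b = integer(),
                           rOrder = character(), pOrder = character(),
                           stringsAsFactors = FALSE)))

setValidity("CGR", function(object) {
    bd <- object@bonds
    msgs <- character()
    if (!all(object@atoms$origin %in% c("both", "reactant_only", "product_only")))
        msgs <- c(msgs, "origin outside both/reactant_only/product_only")
    if (nrow(bd)) {
        if (!all(bd$rOrder %in% .CGR_ORDERS) || !all(bd$pOrder %in% .CGR_ORDERS))
            msgs <- c(msgs, "CGR bond order outside none/single/double/triple/aromatic")
        if (any(bd$rOrder == "none" & bd$pOrder == "none"))
            msgs <- c(msgs, "CGR bond absent on both sides")
        if (any(bd$a < 1 | bd$b < 1 | bd$a > nrow(object@atoms) |
                bd$b > nrow(object@atoms) | bd$a == bd$b))
            msgs <- c(msgs, "CGR bond endpoint invalid")
    }
    if (length(msgs)) msgs else TRUE
})

#' FragmentationScheme: how a CGR is cut into linear fragments
#'
#' Controls the fragment enumeration: `kind` selects whether fragment
#' strings spell out atoms and bonds, atoms only, or bonds only; paths of
#' `minLen` to `maxLen` atoms are enumerated; `formalCharge` and
#' `radicals` toggle the corresponding atom-label decorations.  The
#' default, sequences of 2-4 atoms and bonds with formal charges and
#' radical/lone-pair marks on (`IAB(2-4) FC_UR`), is the scheme the
#' grading service uses.
#'
#' @slot kind one of `"atoms_and_bonds"`, `"atoms_only"`, `"bonds_only"`.
#' @slot minLen,maxLen integer path lengths in atoms, 2 <= min <= max <= 12.
#' @slot formalCharge,radicals logical decoration toggles.
#' @exportClass FragmentationScheme
setClass("FragmentationScheme",
    representation(kind = "character", minLen = "integer", maxLen = "integer",
                   formalCharge = "logical", radicals = "logical"),
    prototype(kind = "atoms_and_bonds", minLen = 2L, maxLen = 4L,
              formalCharge = TRUE, radicals = TRUE))

setValidity("FragmentationScheme", function(object) {
    if (!object@kind %in% c("atoms_and_bonds", "atoms_only", "bonds_only"))
        return("kind must be one of atoms_and_bonds, atoms_only, bonds_only")
    if (object@minLen < 2L || object@minLen > object@maxLen || object@maxLen > 12L)
        return("need 2 <= minLen <= maxLen <= 12")
    TRUE
})

#' FragmentVector: sparse counts of canonical fragment strings
#'
#' The descriptor vector of a CGR: a named integer vector mapping each
#' canonical (direction-minimal) fragment string to its occurrence count.
#' Two vectors align by key, so no global fragment dictionary is needed
#' for pairwise similarity.
#'
#' @slot counts named integer vector, all counts >= 1.
#' @exportClass FragmentVector
setClass("FragmentVector",
    representation(counts = "integer"),
    prototype(counts = integer()))

setValidity("FragmentVector", function(object) {
    cnt <- object@counts
    if (length(cnt)) {
        if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
            return("counts must be named by fragment strings")
        if (anyDuplicated(names(cnt))) return("duplicate fragment keys")
        if (any(cnt < 1L)) return("all counts must be >= 1")
    }
    TRUE
})

#' QuestionSpec: a teacher's grading question
#'
#' One to N reference reactions considered correct (alternative answers
#' accommodate tautomers, mesomers, drawings with/without explicit
#' hydrogens), an optional reaction template, the softness exponent
#' `alpha` in [0.1, 10], the cutoff `threshold` in [0, 1], a stereo flag
#' and the fragmentation scheme.
#'
#' @slot references list of \linkS4class{Reaction}.
#' @slot template a \linkS4class{Reaction} or `NULL`.
#' @slot alpha,threshold numeric softness parameters.
#' @slot stereo logical, whether stereochemistry is graded.
#' @slot scheme a \linkS4class{FragmentationScheme}.
#' @exportClass QuestionSpec
setClass("QuestionSpec",
    representation(references = "list", template = "ANY",
                   alpha = "numeric", threshold = "numeric",
                   stereo = "logical", scheme = "FragmentationScheme"),
    prototype(references = list(), template = NULL, alpha = 1, threshold = 0,
              stereo = FALSE, scheme = new("FragmentationScheme")))

setValidity("QuestionSpec", function(object) {
    if (length(object@references) < 1L)
        return("at least one reference reaction is required")
    if (!all(vapply(object@references, is, logical(1), "Reaction")))
        return("references must be Reaction objects")
    if (!is.null(object@template) && !is(object@template, "Reaction"))
        return("template must be a Reaction or NULL")
    if (object@alpha < 0.1 || object@alpha > 10)
        return("alpha must lie in [0.1, 10]")
    if (object@threshold < 0 || object@threshold > 1)
        return("threshold must lie in [0, 1]")
    TRUE
})

#' StereoAssessment: InChI-layer stereochemistry comparison
#'
#' Counts of correctly drawn stereo centers (tetrahedral R/S from the
#' InChI /t layer normalized by /m, double-bond Z/E from /b) over the
#' total stereo centers of the reference reaction, with a per-molecule
#' detail table.
#'
#' @slot correct,total integer center counts, 0 <= correct <= total.
#' @slot detail data.frame of per-molecule comparisons.
#' @exportClass StereoAssessment
setClass("StereoAssessment",
    representation(correct = "integer", total = "integer", detail = "data.frame"),
    prototype(correct = 0L, total = 0L,
              detail = data.frame(side = character(), formula = character(),
                                  centers = integer(), correct = integer(),
                                  paired = logical(), stringsAsFactors = FALSE)))

setValidity("StereoAssessment", function(object) {
    if (object@correct < 0L || object@correct > object@total)
        return("need 0 <= correct <= total")
    TRUE
})

#' GradeResult: the grade and all intermediates
#'
#' `gSim` is the best count-Tanimoto similarity against the references,
#' `bestReference` the 1-based index achieving it (ties: lowest index),
#' `gTpl` the template-vs-best-reference similarity (`NA` without a
#' template), `gRest` the post-template / post-stereo score and `grade`
#' the final mark after the softness transform.  `diagnostics` keeps the
#' mapping report, per-reference similarities, fragment-vector sizes and,
#' when computed, the stereo assessment.
#'
#' @slot gSim,gTpl,gRest,grade numeric scores in [0, 1] (`gTpl` may be `NA`).
#' @slot bestReference integer index.
#' @slot diagnostics list.
#' @exportClass GradeResult
setClass("GradeResult",
    representation(gSim = "numeric", bestReference = "integer",
                   gTpl = "numeric", gRest = "numeric", grade = "numeric",
                   diagnostics = "list"))

setValidity("GradeResult", function(object) {
    sc <- c(object@gSim, object@gRest, object@grade,
            if (!is.na(object@gTpl)) object@gTpl)
    if (any(sc < 0 | sc > 1)) return("scores must lie in [0, 1]")
    TRUE
})

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("atoms", "Molecule", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("atoms", "CGR", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "CGR", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("reactants", "Reaction", function(x) x@reactants)
#' @rdname accessors
#' @export
setMethod("products", "Reaction", function(x) x@products)
#' @rdname accessors
#' @export
setMethod("counts", "FragmentVector", function(x) x@counts)

setMethod("show", "Molecule", function(object) {
    cat(sprintf("Molecule: %d atoms, %d bonds (%d mapped)\n",
                nrow(object@atoms), nrow(object@bonds),
                sum(object@atoms$map > 0L)))
})

setMethod("show", "Reaction", function(object) {
    cat(sprintf("%s: %d reactant(s) >> %d product(s)\n",
                if (object@template) "Reaction template" else "Reaction",
                length(object@reactants), length(object@products)))
})

setMethod("show", "MappingReport", function(object) {
    cat(sprintf("MappingReport: %s (%d mapped pairs)\n",
                if (object@valid) "valid" else "INVALID", object@mappedPairs))
    if (length(object@duplicates))
        cat("  duplicated map numbers:", paste(object@duplicates, collapse = " "), "\n")
    if (length(object@elementMismatches))
        cat("  element mismatches at maps:",
            paste(object@elementMismatches, collapse = " "), "\n")
    if (length(object@orphansReactant))
        cat("  reactant-only maps:", paste(object@orphansReactant, collapse = " "), "\n")
    if (length(object@orphansProduct))
        cat("  product-only maps:", paste(object@orphansProduct, collapse = " "), "\n")
})

setMethod("show", "CGR", function(object) {
    dyn <- sum(object@bonds$rOrder != object@bonds$pOrder)
    cat(sprintf("CGR: %d atoms, %d bonds (%d dynamic)\n",
                nrow(object@atoms), nrow(object@bonds), dyn))
})

setMethod("show", "FragmentationScheme", function(object) {
    cat(sprintf("FragmentationScheme: %s, %d-%d atoms, charges=%s, radicals=%s\n",
                object@kind, object@minLen, object@maxLen,
                object@formalCharge, object@radicals))
})

setMethod("show", "FragmentVector", function(object) {
    cat(sprintf("FragmentVector: %d distinct fragments, total count %d\n",
                length(object@counts), sum(object@counts)))
    if (length(object@counts)) {
        head <- utils::head(sort(object@counts, decreasing = TRUE), 5L)
        for (i in seq_along(head))
            cat(sprintf("  %-20s %d\n", names(head)[i], head[i]))
        if (length(object@counts) > 5L) cat("  ...\n")
    }
})

setMethod("show", "QuestionSpec", function(object) {
    cat(sprintf("QuestionSpec: %d reference(s)%s, alpha=%g, t=%g, stereo=%s\n",
                length(object@references),
                if (!is.null(object@template)) " + template" else "",
                object@alpha, object@threshold, object@stereo))
})

setMethod("show", "StereoAssessment", function(object) {
    cat(sprintf("StereoAssessment: %d/%d stereo centers correct\n",
                object@correct, object@total))
})

setMethod("show", "GradeResult", function(object) {
    cat(sprintf("GradeResult: g=%.4f (gSim=%.4f ref#%d%s, gRest=%.4f)\n",
                object@grade, object@gSim, object@bestReference,
                if (!is.na(object@gTpl)) sprintf(", gTpl=%.4f", object@gTpl) else "",
                object@gRest))
})
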