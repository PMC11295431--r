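#' @include aromatize.R
NULL

.ORDER_DIGIT <- c(none = 0L, single = 1L, double = 2L, triple = 3L, aromatic = 4L)
.STATIC_BOND_SYMBOL <- c(single = "-", double = "=", triple = "#", aromatic = ":")

## "1", "2", ... for static orders is only used inside dynamic pair labels.
.bondPairLabel <- function(r, p) {
    if (r == p) unname(.STATIC_BOND_SYMBOL[r])
    else paste0(.ORDER_DIGIT[[r]], ">", .ORDER_DIGIT[[p]])
}

## Flatten one side of a reaction into a single atom/bond table.
.flattenSide <- function(mols) {
    at <- .emptyAtoms(); bd <- .emptyBonds()
    for (m in mols) {
        off <- nrow(at)
        at <- rbind(at, m@atoms)
        if (nrow(m@bonds)) {
            b <- m@bonds; b$a <- b$a + off; b$b <- b$b + off
            bd <- rbind(bd, b)
        }
    }
    list(atoms = at, bonds = bd)
}

#' Superimpose a mapped reaction into a Condensed Graph of Reaction
#'
#' Builds the CGR by overlaying reactant and product atoms bearing the
#' same map number: each distinct map number becomes one CGR atom, plus
#' one atom per unmapped or orphan (one-sided) atom.  Bond order pairs
#' are read off the two sides, with `none` where a bond is absent on a
#' side, so a formed single bond is `none -> single` (rendered `0>1`) and
#' a broken one `1>0`.  Orphan (one-sided) and unmapped atoms are kept,
#' so unbalanced student equations still grade rather than crash: a bond
#' from a mapped atom to an orphan is genuinely formed or broken (a
#' leaving group departs, `1>0`), while a bond between two one-sided
#' atoms - a spectator molecule or a template fragment - represents
#' untransformed matter and is kept static.  Both sides are aromatized first (disable
#' with `aromatize = FALSE` if already done).  Atom order is made
#' deterministic by a Morgan-style canonical ranking over element, charge
#' and radical pairs, origin and incident order pairs.
#'
#' @param rxn a mapped \linkS4class{Reaction}; its mapping must validate
#'   (no duplicates, no element mismatches), otherwise an error citing
#'   the \linkS4class{MappingReport} is thrown.
#' @param aromatize logical, aromatize both sides first.
#' @return a \linkS4class{CGR}.
#' @examples
#' da <- parseReaction(
#'   "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1")
#' cgr <- buildCGR(da)
#' dynamicBonds(cgr)
#' @rdname buildCGR
#' @export
setMethod("buildCGR", "Reaction", function(rxn, aromatize = TRUE) {
    rep <- validateMapping(rxn)
    if (!rep@valid) {
        probs <- c(
            if (length(rep@duplicates))
                sprintf("duplicated map numbers: %s",
                        paste(rep@duplicates, collapse = " ")),
            if (length(rep@elementMismatches))
                sprintf("element mismatches at maps: %s",
                        paste(rep@elementMismatches, collapse = " ")))
        stop("invalid atom-to-atom mapping: ", paste(probs, collapse = "; "),
             call. = FALSE)
    }
    if (aromatize) {
        rxn@reactants <- lapply(rxn@reactants, .aromatizeMolecule)
        rxn@products <- lapply(rxn@products, .aromatizeMolecule)
    }
    r <- .flattenSide(rxn@reactants)
    p <- .flattenSide(rxn@products)

    ## node table: mapped pairs first, then one-sided atoms
    shared <- intersect(r$atoms$map[r$atoms$map > 0L],
                        p$atoms$map[p$atoms$map > 0L])
    nodeOfR <- integer(nrow(r$atoms)); nodeOfP <- integer(nrow(p$atoms))
    element <- character(); rCharge <- integer(); pCharge <- integer()
    rRadical <- integer(); pRadical <- integer(); origin <- character()
    map <- integer(); explicit <- logical()
    addNode <- function(el, rc, pc, rr, prr, org, mp, ex) {
        element <<- c(element, el); rCharge <<- c(rCharge, rc)
        pCharge <<- c(pCharge, pc); rRadical <<- c(rRadical, rr)
        pRadical <<- c(pRadical, prr); origin <<- c(origin, org)
        map <<- c(map, mp); explicit <<- c(explicit, ex)
        length(element)
    }
    for (i in seq_len(nrow(r$atoms))) {
        a <- r$atoms[i, ]
        if (a$map > 0L && a$map %in% shared) {
            j <- match(a$map, p$atoms$map)
            b <- p$atoms[j, ]
            id <- addNode(a$element, a$charge, b$charge, a$radical, b$radical,
                          "both", a$map, a$explicit)
            nodeOfR[i] <- id; nodeOfP[j] <- id
        } else {
            ## one-sided: mirror state so the atom itself is not dynamic
            nodeOfR[i] <- addNode(a$element, a$charge, a$charge, a$radical,
                                  a$radical, "reactant_only", a$map, a$explicit)
        }
    }
    for (j in seq_len(nrow(p$atoms))) {
        if (nodeOfP[j] > 0L) next
        b <- p$atoms[j, ]
        nodeOfP[j] <- addNode(b$element, b$charge, b$charge, b$radical,
                              b$radical, "product_only", b$map, b$explicit)
    }
    at <- data.frame(element = element, rCharge = rCharge, pCharge = pCharge,
                     rRadical = rRadical, pRadical = pRadical, origin = origin,
                     map = map, explicit = explicit, stringsAsFactors = FALSE)

    ## merge bonds keyed on the node pair
    key <- character(); ra <- integer(); rb <- integer()
    rOrd <- character(); pOrd <- character()
    slot <- new.env(parent = emptyenv())
    addBond <- function(u, v, side, ord) {
        k <- paste(min(u, v), max(u, v))
        idx <- get0(k, envir = slot)
        if (is.null(idx)) {
            ra <<- c(ra, min(u, v)); rb <<- c(rb, max(u, v))
            rOrd <<- c(rOrd, "none"); pOrd <<- c(pOrd, "none")
            idx <- length(ra)
            assign(k, idx, envir = slot)
        }
        if (side == "r") rOrd[idx] <<- ord else pOrd[idx] <<- ord
        ## a bond between two one-sided atoms (spectator molecule, template
        ## fragment) is not transformed: mirror it as static.  A bond from a
        ## mapped atom to a one-sided atom really is formed/broken.
        if (origin[u] != "both" && origin[v] != "both") {
            rOrd[idx] <<- ord; pOrd[idx] <<- ord
        }
    }
    for (i in seq_len(nrow(r$bonds)))
        addBond(nodeOfR[r$bonds$a[i]], nodeOfR[r$bonds$b[i]], "r", r$bonds$order[i])
    for (i in seq_len(nrow(p$bonds)))
        addBond(nodeOfP[p$bonds$a[i]], nodeOfP[p$bonds$b[i]], "p", p$bonds$order[i])
    bd <- data.frame(a = ra, b = rb, rOrder = rOrd, pOrder = pOrd,
                     stringsAsFactors = FALSE)

    cgr <- new("CGR", atoms = at, bonds = bd)
    .canonicalizeCGR(cgr)
})

## Morgan-style canonical ranking: refine atom labels by neighborhood three
## times, then order atoms by (label, map, input index).  Fragment vectors
## are order-free, but a deterministic order makes the debug block and the
## signature stable.
.canonicalizeCGR <- function(cgr) {
    at <- cgr@atoms; bd <- cgr@bonds
    n <- nrow(at)
    if (n < 2L) return(cgr)
    lab <- vapply(seq_len(n), function(k) .cgrAtomLabel(at[k, ], full = TRUE),
                  character(1))
    inc <- lapply(seq_len(n), function(k) which(bd$a == k | bd$b == k))
    for (k in seq_len(n)) {
        bl <- sort(vapply(inc[[k]], function(e)
            .bondPairLabel(bd$rOrder[e], bd$pOrder[e]), character(1)))
        lab[k] <- paste0(lab[k], "|", paste(bl, collapse = ""))
    }
    for (round in 1:3) {
        rk <- match(lab, sort(unique(lab)))
        lab <- vapply(seq_len(n), function(k) {
            nb <- vapply(inc[[k]], function(e) {
                o <- if (bd$a[e] == k) bd$b[e] else bd$a[e]
                sprintf("%04d%s", rk[o], .bondPairLabel(bd$rOrder[e], bd$pOrder[e]))
            }, character(1))
            paste0(rk[k], ":", paste(sort(nb), collapse = ","))
        }, character(1))
    }
    ord <- order(lab, at$map, seq_len(n))
    newPos <- match(seq_len(n), ord)
    at <- at[ord, , drop = FALSE]
    rownames(at) <- NULL
    bd$a <- newPos[bd$a]; bd$b <- newPos[bd$b]
    swap <- bd$a > bd$b
    tmp <- bd$a[swap]; bd$a[swap] <- bd$b[swap]; bd$b[swap] <- tmp
    bd <- bd[order(bd$a, bd$b), , drop = FALSE]
    rownames(bd) <- NULL
    new("CGR", atoms = at, bonds = bd)
}

## Atom label used in signatures and canonical ordering (not the fragment
## grammar): element plus charge/radical pairs and origin.
.cgrAtomLabel <- function(a, full = FALSE) {
    lab <- a$element
    if (a$rCharge != 0L || a$pCharge != 0L)
        lab <- paste0(lab, "c", a$rCharge, ">", a$pCharge)
    if (a$rRadical != 0L || a$pRadical != 0L)
        lab <- paste0(lab, "r", a$rRadical, ">", a$pRadical)
    if (full && a$origin != "both") lab <- paste0(lab, "!", a$origin)
    lab
}

#' Dynamic bonds and atoms of a CGR
#'
#' A bond is dynamic when its reactant and product orders differ (formed
#' `0>1`, broken `1>0`, order change `2>1`, ...); an atom is dynamic when
#' its formal charge or radical count changes.  An identity reaction has
#' neither.
#'
#' @param cgr a \linkS4class{CGR}.
#' @return `dynamicBonds()`: the rows of `bonds(cgr)` with unequal order
#'   pair plus a `label` column (`"r>p"` digits, 0=none, 1, 2, 3,
#'   4=aromatic); `dynamicAtoms()`: the rows of `atoms(cgr)` with unequal
#'   charge or radical pair.
#' @examples
#' cgr <- buildCGR(parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]"))
#' dynamicBonds(cgr)$label  # "2>1"
#' @export
dynamicBonds <- function(cgr) {
    stopifnot(is(cgr, "CGR"))
    bd <- cgr@bonds[cgr@bonds$rOrder != cgr@bonds$pOrder, , drop = FALSE]
    bd$label <- sprintf("%d>%d", .ORDER_DIGIT[bd$rOrder], .ORDER_DIGIT[bd$pOrder])
    rownames(bd) <- NULL
    bd
}

#' @rdname dynamicBonds
#' @export
dynamicAtoms <- function(cgr) {
    stopifnot(is(cgr, "CGR"))
    at <- cgr@atoms
    dyn <- at$rCharge != at$pCharge | at$rRadical != at$pRadical
    at[dyn, , drop = FALSE]
}

#' Canonical CGR signature
#'
#' A plain-text signature of a CGR that is invariant under atom
#' reindexing and consistent map renumbering: the sorted multiset of atom
#' labels and of bond strings (endpoint labels around the order-pair
#' label).  Intended for test assertions and debugging, not as a complete
#' graph-isomorphism certificate.
#'
#' @param cgr a \linkS4class{CGR}.
#' @return a single string.
#' @export
cgrSignature <- function(cgr) {
    stopifnot(is(cgr, "CGR"))
    at <- cgr@atoms; bd <- cgr@bonds
    alab <- vapply(seq_len(nrow(at)), function(k) .cgrAtomLabel(at[k, ]),
                   character(1))
    blab <- vapply(seq_len(nrow(bd)), function(e) {
        u <- alab[bd$a[e]]; v <- alab[bd$b[e]]
        mid <- .bondPairLabel(bd$rOrder[e], bd$pOrder[e])
        paste0(min(u, v), "[", mid, "]", max(u, v))
    }, character(1))
    paste0("atoms{", paste(sort(alab), collapse = ","),
           "}bonds{", paste(sort(blab), collapse = ","), "}")
}

#' Export a CGR as a debug block
#'
#' An SDF-like block: a V2000-style connection table over the CGR atoms
#' with the reactant-side bond orders, followed by a
#' `> <DYNAMIC_BONDS>` property field with one `i j r>p` line per dynamic
#' bond, digits 0=none, 1, 2, 3, 4=aromatic.
#'
#' @param cgr a \linkS4class{CGR}.
#' @return character vector of lines.
#' @export
writeCGRBlock <- function(cgr) {
    stopifnot(is(cgr, "CGR"))
    at <- cgr@atoms; bd <- cgr@bonds
    lines <- c("", "  cgrgrade CGR", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)))
    for (k in seq_len(nrow(at)))
        lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0%3d  0  0",
                                  0, 0, 0, at$element[k], 0L, at$map[k]))
    ordCode <- c(none = 0L, single = 1L, double = 2L, triple = 3L, aromatic = 4L)
    for (k in seq_len(nrow(bd)))
        lines <- c(lines, sprintf("%3d%3d%3d%3d", bd$a[k], bd$b[k],
                                  max(1L, ordCode[[bd$rOrder[k]]]), 0L))
    lines <- c(lines, "M  END", "> <DYNAMIC_BONDS>")
    dyn <- dynamicBonds(cgr)
    for (k in seq_len(nrow(dyn)))
        lines <- c(lines, sprintf("%d %d %s", dyn$a[k], dyn$b[k], dyn$label[k]))
    c(lines, "")
}
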