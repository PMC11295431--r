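#' @include parse-rxn.R
NULL

.SMILES_BOND_OUT <- c(single = "", double = "=", triple = "#", aromatic = ":")

## One molecule -> SMILES, all atoms as bracket atoms so that implicit-H
## counts, charges and atom maps survive a round trip.  Disconnected
## molfile fragments are joined with '.'.
.writeSmilesMolecule <- function(mol) {
    at <- mol@atoms; bd <- mol@bonds
    n <- nrow(at)
    if (!n) return("")
    adj <- lapply(seq_len(n), function(k) integer())
    for (i in seq_len(nrow(bd))) {
        adj[[bd$a[i]]] <- c(adj[[bd$a[i]]], i)
        adj[[bd$b[i]]] <- c(adj[[bd$b[i]]], i)
    }
    other <- function(e, v) if (bd$a[e] == v) bd$b[e] else bd$a[e]

    atomToken <- function(k) {
        el <- at$element[k]; hc <- at$hcount[k]
        tok <- el
        if (!is.na(hc) && hc > 0L) tok <- paste0(tok, "H", if (hc > 1L) hc else "")
        ch <- at$charge[k]
        if (ch != 0L)
            tok <- paste0(tok, if (ch > 0L) "+" else "-",
                          if (abs(ch) > 1L) abs(ch) else "")
        if (at$map[k] > 0L) tok <- paste0(tok, ":", at$map[k])
        paste0("[", tok, "]")
    }

    visited <- logical(n)
    usedEdge <- logical(max(1L, nrow(bd)))
    children <- lapply(seq_len(n), function(k) integer())   # ordered tree edges
    closures <- lapply(seq_len(n), function(k) character()) # ring digits per atom
    nextRing <- 0L

    classify <- function(v) {                # DFS: tree vs ring-closure edges
        visited[v] <<- TRUE
        for (e in adj[[v]]) {
            if (usedEdge[e]) next
            w <- other(e, v)
            if (visited[w]) {
                usedEdge[e] <<- TRUE
                nextRing <<- nextRing + 1L
                dig <- .ringDigit(bd$order[e], nextRing)
                closures[[v]] <<- c(closures[[v]], dig)
                closures[[w]] <<- c(closures[[w]], dig)
            } else {
                usedEdge[e] <<- TRUE
                children[[v]] <<- c(children[[v]], e)
                classify(w)
            }
        }
    }
    build <- function(v) {
        out <- paste0(atomToken(v), paste(closures[[v]], collapse = ""))
        kids <- children[[v]]
        for (idx in seq_along(kids)) {
            e <- kids[idx]
            sub <- paste0(.SMILES_BOND_OUT[bd$order[e]], build(other(e, v)))
            out <- if (idx < length(kids)) paste0(out, "(", sub, ")")
                   else paste0(out, sub)
        }
        out
    }
    comps <- character(0)
    for (root in seq_len(n)) {
        if (visited[root]) next
        classify(root)
        comps <- c(comps, build(root))
    }
    paste(comps, collapse = ".")
}

.ringDigit <- function(order, num) {
    digit <- if (num < 10L) as.character(num) else sprintf("%%%02d", num)
    paste0(.SMILES_BOND_OUT[order], digit)
}

.writeMolblock <- function(mol) {
    at <- mol@atoms; bd <- mol@bonds
    lines <- c("", "  cgrgrade", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)))
    for (k in seq_len(nrow(at)))
        lines <- c(lines, sprintf(
            "%10.4f%10.4f%10.4f %-3s%2d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d",
            0, 0, 0, at$element[k], 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
            at$map[k], 0L, 0L))
    ordCode <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
    for (k in seq_len(nrow(bd)))
        lines <- c(lines, sprintf("%3d%3d%3d%3d",
                                  bd$a[k], bd$b[k], ordCode[[bd$order[k]]], 0L))
    propPairs <- function(tag, idx, val) {
        out <- character(0)
        while (length(idx)) {
            take <- seq_len(min(8L, length(idx)))
            out <- c(out, paste0(tag, sprintf("%3d", length(take)),
                                 paste0(sprintf("%4d%4d", idx[take], val[take]),
                                        collapse = "")))
            idx <- idx[-take]; val <- val[-take]
        }
        out
    }
    chgIdx <- which(at$charge != 0L)
    if (length(chgIdx))
        lines <- c(lines, propPairs("M  CHG", chgIdx, at$charge[chgIdx]))
    radIdx <- which(at$radical > 0L)
    if (length(radIdx)) {
        code <- ifelse(at$radical[radIdx] == 1L, 2L, 3L)
        lines <- c(lines, propPairs("M  RAD", radIdx, code))
    }
    c(lines, "M  END")
}

#' Serialize a reaction
#'
#' Writes a \linkS4class{Reaction} as reaction SMILES (all atoms as
#' bracket atoms, so implicit-hydrogen counts, charges and atom maps are
#' preserved) or as MDL RXN V2000 with the atom-atom-mapping column and
#' `M  CHG` / `M  RAD` property lines.  Parsing the output reproduces the
#' reaction up to atom-index permutation.  Radicals have no reaction-SMILES
#' notation and round-trip through the RXN dialect only.
#'
#' @param rxn a \linkS4class{Reaction}.
#' @param dialect `"reaction_smiles"` or `"rxn_v2000"`.
#' @return a single string (`reaction_smiles`) or a character vector of
#'   lines (`rxn_v2000`).
#' @rdname writeReaction
#' @examples
#' rxn <- parseReaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
#' writeReaction(rxn)
#' cat(writeReaction(rxn, "rxn_v2000"), sep = "\n")
#' @export
setMethod("writeReaction", "Reaction", function(rxn,
        dialect = c("reaction_smiles", "rxn_v2000")) {
    dialect <- match.arg(dialect)
    validObject(rxn)
    if (dialect == "reaction_smiles") {
        r <- paste(vapply(rxn@reactants, .writeSmilesMolecule, character(1)),
                   collapse = ".")
        p <- paste(vapply(rxn@products, .writeSmilesMolecule, character(1)),
                   collapse = ".")
        paste0(r, ">>", p)
    } else {
        lines <- c("$RXN", "", " cgrgrade", "",
                   sprintf("%3d%3d", length(rxn@reactants), length(rxn@products)))
        for (mol in c(rxn@reactants, rxn@products))
            lines <- c(lines, "$MOL", .writeMolblock(mol))
        lines
    }
})
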