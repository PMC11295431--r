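#' @include mapping.R
NULL

## Enumerate simple cycles of 3..maxLen atoms.  Each cycle is reported once
## (smallest atom first, direction fixed by its second atom).  Molecules in
## grading exercises are small, so plain DFS is adequate.
.findRings <- function(bonds, n, maxLen = 8L) {
    if (!nrow(bonds) || n < 3L) return(list())
    nbr <- lapply(seq_len(n), function(k)
        sort(unique(c(bonds$b[bonds$a == k], bonds$a[bonds$b == k]))))
    cycles <- list()
    dfs <- function(path) {
        v <- path[length(path)]
        for (w in nbr[[v]]) {
            if (w == path[1] && length(path) >= 3L) {
                if (path[2] < path[length(path)])
                    cycles[[length(cycles) + 1L]] <<- path
            } else if (w > path[1] && !(w %in% path) && length(path) < maxLen) {
                dfs(c(path, w))
            }
        }
    }
    for (s in seq_len(n)) dfs(s)
    cycles
}

.bondIndex <- function(bonds, a, b) {
    which((bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a))
}

## Pi-electron contribution of `k` to candidate ring `ring`, or NA if the
## atom cannot take part in a conjugated system.  `inRing` flags atoms that
## lie on any cycle (a double bond into another ring, as at a fusion bond,
## still contributes its electron; a double bond to an acyclic atom, as in a
## quinone carbonyl, removes the atom's electron from the ring).
.piContribution <- function(at, bonds, k, ring, inRing) {
    inc <- which(bonds$a == k | bonds$b == k)
    partners <- ifelse(bonds$a[inc] == k, bonds$b[inc], bonds$a[inc])
    ords <- bonds$order[inc]
    el <- at$element[k]; ch <- at$charge[k]; rad <- at$radical[k]
    if (any(ords == "triple")) return(NA_integer_)
    if (any(ords == "aromatic" & partners %in% ring)) return(1L)
    dbl <- ords == "double"
    if (any(dbl)) {
        if (sum(dbl) > 1L) return(NA_integer_)
        return(if (inRing[partners[dbl]]) 1L else 0L)
    }
    if (rad > 0L) return(1L)
    if (el == "C") {
        if (ch > 0L) return(0L)
        if (ch < 0L) return(2L)
        return(NA_integer_)                  # saturated carbon: not conjugated
    }
    if (el == "B") return(0L)
    if (el %in% c("N", "P", "O", "S", "Se", "As")) {
        if (ch > 0L) return(NA_integer_)     # e.g. quaternary N+: no lone pair
        return(2L)
    }
    NA_integer_
}

.aromatizeMolecule <- function(mol) {
    at <- mol@atoms; bd <- mol@bonds
    rings <- .findRings(bd, nrow(at))
    if (!length(rings)) return(mol)
    inRing <- logical(nrow(at))
    inRing[unlist(rings)] <- TRUE
    repeat {
        changed <- FALSE
        for (ring in rings) {
            m <- length(ring)
            ringBonds <- vapply(seq_len(m), function(i)
                .bondIndex(bd, ring[i], ring[if (i == m) 1L else i + 1L])[1],
                integer(1))
            if (all(bd$order[ringBonds] == "aromatic")) next
            pis <- vapply(ring, function(k)
                .piContribution(at, bd, k, ring, inRing), integer(1))
            if (anyNA(pis)) next
            if (sum(pis) %% 4L != 2L) next   # Hueckel 4n+2
            bd$order[ringBonds] <- "aromatic"
            at$aromatic[ring] <- TRUE
            changed <- TRUE
        }
        if (!changed) break
    }
    mol@atoms <- at; mol@bonds <- bd
    mol
}

#' Aromatize a molecule or reaction
#'
#' Rewrites bonds of rings perceived as aromatic (Hückel-style 4n+2 count
#' of pi electrons over conjugated simple rings of up to 8 atoms, applied
#' iteratively so fused systems such as naphthalene resolve) with order
#' `aromatic`.  Acyclic bonds are never touched and bonds are only ever
#' promoted, so the operation is idempotent.  Applied to a
#' \linkS4class{Reaction} it aromatizes every reactant and product, the
#' normalization required before CGR superposition so that a Kekulé
#' drawing and an aromatic drawing of the same ring compare equal.
#'
#' @param x a \linkS4class{Molecule} or \linkS4class{Reaction}.
#' @return the same class of object, aromatized.
#' @examples
#' benzene <- reactants(parseReaction("C1=CC=CC=C1>>C1=CC=CC=C1"))[[1]]
#' table(bonds(aromatize(benzene))$order)
#' @rdname aromatize
#' @export
setMethod("aromatize", "Molecule", function(x) .aromatizeMolecule(x))

#' @rdname aromatize
#' @export
setMethod("aromatize", "Reaction", function(x) {
    x@reactants <- lapply(x@reactants, .aromatizeMolecule)
    x@products <- lapply(x@products, .aromatizeMolecule)
    x
})
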