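#' @include AllClasses.R
NULL

.SMILES_BOND <- c("-" = "single", "=" = "double", "#" = "triple",
                  ":" = "aromatic", "/" = "single", "\\" = "single")

.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
.AROMATIC_BRACKET <- c(.AROMATIC_ORGANIC, "se", "as")

.smilesError <- function(pos, msg)
    stop(sprintf("SMILES parse error at position %d: %s", pos, msg), call. = FALSE)

## Parse one molecule token of a reaction SMILES (no dots).  `offset` shifts
## reported error positions to the coordinates of the full reaction string.
.parseSmilesMolecule <- function(s, offset = 0L) {
    n <- nchar(s)
    if (n == 0L) .smilesError(offset + 1L, "empty molecule token")
    element <- character(); charge <- integer(); radical <- integer()
    map <- integer(); aromaticA <- logical(); hcount <- integer()
    ba <- integer(); bb <- integer(); border <- character()

    addBond <- function(i, j, sym, pos) {
        if (i == j) .smilesError(pos, "ring bond to the same atom")
        ord <- if (!is.na(sym)) unname(.SMILES_BOND[sym])
               else if (aromaticA[i] && aromaticA[j]) "aromatic" else "single"
        ba <<- c(ba, i); bb <<- c(bb, j); border <<- c(border, ord)
    }

    prev <- NA_integer_
    stack <- integer()
    pending <- NA_character_
    ring <- list()       # closure number -> list(atom, bond, pos)
    i <- 1L
    while (i <= n) {
        ch <- substr(s, i, i)
        pos <- offset + i
        if (ch %in% names(.SMILES_BOND)) {
            if (!is.na(pending)) .smilesError(pos, "two consecutive bond symbols")
            pending <- ch; i <- i + 1L
        } else if (ch == "(") {
            if (is.na(prev)) .smilesError(pos, "branch before any atom")
            stack <- c(stack, prev); i <- i + 1L
        } else if (ch == ")") {
            if (!length(stack)) .smilesError(pos, "unbalanced closing parenthesis")
            prev <- stack[length(stack)]; stack <- stack[-length(stack)]
            i <- i + 1L
        } else if (grepl("^[0-9%]$", ch)) {
            if (ch == "%") {
                num <- substr(s, i + 1L, i + 2L)
                if (!grepl("^[0-9]{2}$", num))
                    .smilesError(pos, "'%' must be followed by two digits")
                i <- i + 3L
            } else {
                num <- ch; i <- i + 1L
            }
            if (is.na(prev)) .smilesError(pos, "ring closure before any atom")
            key <- as.character(as.integer(num))
            if (is.null(ring[[key]])) {
                ring[[key]] <- list(atom = prev, bond = pending, pos = pos)
            } else {
                op <- ring[[key]]
                sym <- if (!is.na(pending)) pending else op$bond
                if (!is.na(pending) && !is.na(op$bond) && pending != op$bond)
                    .smilesError(pos, sprintf("ring closure %s bond symbols disagree", key))
                addBond(op$atom, prev, sym, pos)
                ring[[key]] <- NULL
            }
            pending <- NA_character_
        } else if (ch == "[") {
            rest <- substr(s, i, n)
            m <- regmatches(rest, regexec(
                "^\\[([0-9]*)([A-Za-z][a-z]?)(@@|@)?(H[0-9]*)?((?:\\+[0-9]+|-[0-9]+|\\++|-+))?(?::([0-9]+))?\\]",
                rest))[[1]]
            if (!length(m)) .smilesError(pos, "malformed bracket atom")
            sym <- m[3]
            arom <- sym %in% .AROMATIC_BRACKET
            el <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
            if (!el %in% .PERIODIC_SYMBOLS)
                .smilesError(pos, sprintf("unknown element symbol '%s'", sym))
            hc <- if (m[5] == "") 0L
                  else if (m[5] == "H") 1L else as.integer(substr(m[5], 2, nchar(m[5])))
            chg <- if (m[6] == "") 0L
                   else if (grepl("^[+-][0-9]", m[6]))
                       as.integer(m[6])
                   else (nchar(m[6]) * if (substr(m[6], 1, 1) == "+") 1L else -1L)
            mp <- if (is.na(m[7]) || m[7] == "") 0L else as.integer(m[7])
            element <- c(element, el); charge <- c(charge, chg)
            radical <- c(radical, 0L); map <- c(map, mp)
            aromaticA <- c(aromaticA, arom); hcount <- c(hcount, hc)
            idx <- length(element)
            if (!is.na(prev)) addBond(prev, idx, pending, pos)
            prev <- idx; pending <- NA_character_
            i <- i + nchar(m[1])
        } else if (grepl("^[A-Za-z]$", ch)) {
            two <- substr(s, i, i + 1L)
            if (two %in% c("Cl", "Br")) { el <- two; arom <- FALSE; i <- i + 2L }
            else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
                el <- ch; arom <- FALSE; i <- i + 1L
            } else if (ch %in% .AROMATIC_ORGANIC) {
                el <- toupper(ch); arom <- TRUE; i <- i + 1L
            } else .smilesError(pos, sprintf("unknown element symbol '%s'", ch))
            element <- c(element, el); charge <- c(charge, 0L)
            radical <- c(radical, 0L); map <- c(map, 0L)
            aromaticA <- c(aromaticA, arom); hcount <- c(hcount, NA_integer_)
            idx <- length(element)
            if (!is.na(prev)) addBond(prev, idx, pending, pos)
            prev <- idx; pending <- NA_character_
        } else .smilesError(pos, sprintf("unexpected character '%s'", ch))
    }
    if (length(stack)) .smilesError(offset + n, "unbalanced opening parenthesis")
    if (length(ring)) .smilesError(offset + n, sprintf(
        "unclosed ring bond(s): %s", paste(names(ring), collapse = ", ")))
    if (!is.na(pending)) .smilesError(offset + n, "dangling bond symbol")

    at <- data.frame(element = element, charge = charge, radical = radical,
                     map = map, explicit = element == "H",
                     aromatic = aromaticA, hcount = hcount,
                     stringsAsFactors = FALSE)
    bd <- data.frame(a = ba, b = bb, order = border, stringsAsFactors = FALSE)
    ## fill implicit-H counts for organic-subset atoms now that orders are known
    for (k in which(is.na(at$hcount))) {
        os <- sum(.BOND_ORDER_VALUE[bd$order[bd$a == k | bd$b == k]])
        at$hcount[k] <- .implicitHCount(at$element[k], at$charge[k],
                                        at$radical[k], os)
    }
    new("Molecule", atoms = at, bonds = bd, source = s, sourceFormat = "smiles")
}

## Split a reaction-SMILES side into molecule tokens at top-level dots.
.parseSmilesSide <- function(side, offset) {
    if (side == "") return(list())
    toks <- strsplit(side, ".", fixed = TRUE)[[1]]
    out <- vector("list", length(toks))
    off <- offset
    for (k in seq_along(toks)) {
        out[[k]] <- .parseSmilesMolecule(toks[k], off)
        off <- off + nchar(toks[k]) + 1L
    }
    out
}

.parseReactionSmiles <- function(text, template = FALSE) {
    text <- trimws(text)
    sep <- gregexpr(">", text, fixed = TRUE)[[1]]
    if (length(sep) != 2L || sep[1] < 0L)
        .smilesError(max(1L, sep[length(sep)]),
                     "a reaction SMILES needs exactly two '>' separators")
    parts <- substring(text, c(1L, sep[1] + 1L, sep[2] + 1L),
                       c(sep[1] - 1L, sep[2] - 1L, nchar(text)))
    offs <- c(0L, sep[1], sep[2])
    reac <- .parseSmilesSide(parts[1], offs[1])
    ## agents are spectators: kept on the reactant side rather than dropped
    agents <- .parseSmilesSide(parts[2], offs[2])
    prod <- .parseSmilesSide(parts[3], offs[3])
    new("Reaction", reactants = c(reac, agents), products = prod,
        template = template)
}
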