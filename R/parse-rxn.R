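#' @include parse-smiles.R
NULL

.rxnError <- function(line, msg)
    stop(sprintf("RXN parse error at line %d: %s", line, msg), call. = FALSE)

.molfileInt <- function(s) {
    s <- trimws(s)
    if (s == "") 0L else suppressWarnings(as.integer(s))
}

## MDL legacy per-atom charge codes (atom block field ccc); code 4 marks a
## doublet radical.  Overridden wholesale by M  CHG / M  RAD lines if present.
.LEGACY_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

## M  RAD codes: 1 singlet (no unpaired electrons), 2 doublet (one),
## 3 triplet (two).
.RAD_TO_UNPAIRED <- c(`1` = 0L, `2` = 1L, `3` = 2L)

## Parse one V2000 molfile given as a character vector of lines.
## `first` is the 1-based line number of the molfile header in the whole
## file, for error messages.
.parseMolblock <- function(lines, first = 1L) {
    if (length(lines) < 4L) .rxnError(first, "truncated molfile")
    counts <- lines[4]
    if (grepl("V3000", counts, fixed = TRUE))
        .rxnError(first + 3L, "V3000 connection tables are not supported; export V2000")
    natoms <- .molfileInt(substr(counts, 1, 3))
    nbonds <- .molfileInt(substr(counts, 4, 6))
    if (is.na(natoms) || is.na(nbonds))
        .rxnError(first + 3L, sprintf("malformed counts line '%s'", counts))
    need <- 4L + natoms + nbonds
    if (length(lines) < need) .rxnError(first + length(lines), "molfile shorter than its counts line promises")

    element <- character(natoms); charge <- integer(natoms)
    radical <- integer(natoms); map <- integer(natoms)
    for (k in seq_len(natoms)) {
        ln <- lines[4L + k]
        lno <- first + 3L + k
        if (nchar(ln) >= 34) {
            sym <- trimws(substr(ln, 32, 34))
            chgCode <- .molfileInt(substr(ln, 37, 39))
            mp <- if (nchar(ln) >= 61) .molfileInt(substr(ln, 61, 63)) else 0L
        } else {
            toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
            if (length(toks) < 4L) .rxnError(lno, "short atom line")
            sym <- toks[4]
            chgCode <- if (length(toks) >= 6L) .molfileInt(toks[6]) else 0L
            mp <- if (length(toks) >= 14L) .molfileInt(toks[14]) else 0L
        }
        if (!sym %in% .PERIODIC_SYMBOLS)
            .rxnError(lno, sprintf("unknown element symbol '%s'", sym))
        element[k] <- sym
        charge[k] <- if (!is.na(chgCode) && as.character(chgCode) %in% names(.LEGACY_CHARGE))
            .LEGACY_CHARGE[[as.character(chgCode)]] else 0L
        radical[k] <- if (identical(chgCode, 4L)) 1L else 0L
        map[k] <- if (is.na(mp)) 0L else mp
    }

    ba <- integer(nbonds); bb <- integer(nbonds); border <- character(nbonds)
    for (k in seq_len(nbonds)) {
        ln <- lines[4L + natoms + k]
        lno <- first + 3L + natoms + k
        if (nchar(ln) >= 9) {
            a <- .molfileInt(substr(ln, 1, 3)); b <- .molfileInt(substr(ln, 4, 6))
            t <- .molfileInt(substr(ln, 7, 9))
        } else {
            toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
            if (length(toks) < 3L) .rxnError(lno, "short bond line")
            a <- .molfileInt(toks[1]); b <- .molfileInt(toks[2])
            t <- .molfileInt(toks[3])
        }
        if (is.na(a) || is.na(b) || a < 1L || b < 1L || a > natoms || b > natoms)
            .rxnError(lno, "bond endpoint out of range")
        if (!t %in% 1:4) .rxnError(lno, sprintf("unsupported bond type %s", t))
        ba[k] <- a; bb[k] <- b
        border[k] <- c("single", "double", "triple", "aromatic")[t]
    }

    ## property block: M  CHG / M  RAD override legacy atom-block values
    prop <- lines[seq_len(length(lines) - need) + need]
    chgLines <- grep("^M  CHG", prop, value = TRUE)
    radLines <- grep("^M  RAD", prop, value = TRUE)
    if (length(chgLines)) charge[] <- 0L
    if (length(radLines)) radical[] <- 0L
    applyPairs <- function(lines, target) {
        for (ln in lines) {
            toks <- strsplit(trimws(substr(ln, 7, nchar(ln))), "[[:space:]]+")[[1]]
            cnt <- .molfileInt(toks[1])
            for (j in seq_len(cnt)) {
                idx <- .molfileInt(toks[2 * j]); val <- .molfileInt(toks[2 * j + 1])
                if (!is.na(idx) && idx >= 1L && idx <= natoms)
                    target[idx] <- val
            }
        }
        target
    }
    charge <- applyPairs(chgLines, charge)
    if (length(radLines)) {
        rad <- applyPairs(radLines, integer(natoms))
        radical <- vapply(rad, function(v) {
            if (as.character(v) %in% names(.RAD_TO_UNPAIRED))
                .RAD_TO_UNPAIRED[[as.character(v)]] else 0L
        }, integer(1))
    }

    at <- data.frame(element = element, charge = charge, radical = radical,
                     map = map, explicit = element == "H",
                     aromatic = rep(FALSE, natoms),
                     hcount = rep(NA_integer_, natoms), stringsAsFactors = FALSE)
    at$aromatic <- vapply(seq_len(natoms), function(k)
        any(border[ba == k | bb == k] == "aromatic"), logical(1))
    bd <- data.frame(a = ba, b = bb, order = border, stringsAsFactors = FALSE)
    for (k in seq_len(natoms)) {
        os <- sum(.BOND_ORDER_VALUE[bd$order[bd$a == k | bd$b == k]])
        at$hcount[k] <- .implicitHCount(at$element[k], at$charge[k],
                                        at$radical[k], os)
    }
    new("Molecule", atoms = at, bonds = bd,
        source = paste(lines, collapse = "\n"), sourceFormat = "molblock")
}

.parseReactionRxn <- function(text, template = FALSE) {
    lines <- strsplit(text, "\r?\n")[[1]]
    if (!length(lines) || !grepl("^\\$RXN", lines[1]))
        .rxnError(1L, "missing $RXN header")
    if (grepl("V3000", lines[1], fixed = TRUE))
        .rxnError(1L, "RXN V3000 is not supported; export V2000")
    if (length(lines) < 5L) .rxnError(length(lines), "truncated RXN file")
    counts <- lines[5]
    nr <- .molfileInt(substr(counts, 1, 3))
    np <- .molfileInt(substr(counts, 4, 6))
    if (is.na(nr) || is.na(np)) {
        toks <- strsplit(trimws(counts), "[[:space:]]+")[[1]]
        nr <- .molfileInt(toks[1]); np <- if (length(toks) > 1L) .molfileInt(toks[2]) else NA
    }
    if (is.na(nr) || is.na(np))
        .rxnError(5L, sprintf("malformed reaction counts line '%s'", counts))

    molStarts <- grep("^\\$MOL", lines)
    if (length(molStarts) != nr + np)
        .rxnError(if (length(molStarts)) molStarts[length(molStarts)] else 5L,
                  sprintf("expected %d $MOL blocks, found %d", nr + np, length(molStarts)))
    molEnds <- c(molStarts[-1] - 1L, length(lines))
    mols <- vector("list", nr + np)
    for (k in seq_along(molStarts)) {
        block <- lines[(molStarts[k] + 1L):molEnds[k]]
        endIdx <- grep("^M  END", block)
        if (length(endIdx)) block <- block[seq_len(endIdx[1])]
        mols[[k]] <- .parseMolblock(block, first = molStarts[k] + 1L)
    }
    new("Reaction",
        reactants = mols[seq_len(nr)],
        products = if (np) mols[nr + seq_len(np)] else list(),
        template = template)
}

#' Parse an atom-mapped reaction
#'
#' Reads a reaction from MDL RXN V2000 text (with the atom-atom-mapping
#' column and `M  CHG` / `M  RAD` property lines) or from a daylight-style
#' reaction SMILES with `:n` atom maps.  Atom order, charges, radicals,
#' explicit hydrogens and map numbers are preserved exactly as written;
#' map numbers are optional at parse time (0 means unmapped).  Agents in
#' the middle field of a reaction SMILES are kept as spectator reactants.
#' V3000 connection tables are rejected.
#'
#' @param text the serialized reaction (a single string, or for RXN a
#'   character vector of lines).
#' @param dialect `"reaction_smiles"`, `"rxn_v2000"` or `"auto"` (default:
#'   text starting with `$RXN` is treated as RXN).
#' @param template logical; template objects may leave one side empty.
#' @return a \linkS4class{Reaction}.
#' @examples
#' rxn <- parseReaction(
#'   "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1")
#' validateMapping(rxn)
#' @seealso [writeReaction()], [validateMapping()], [buildCGR()]
#' @export
parseReaction <- function(text,
                          dialect = c("auto", "reaction_smiles", "rxn_v2000"),
                          template = FALSE) {
    dialect <- match.arg(dialect)
    if (length(text) > 1L) text <- paste(text, collapse = "\n")
    if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
        stop("'text' must be a non-empty string", call. = FALSE)
    if (dialect == "auto")
        dialect <- if (grepl("^\\s*\\$RXN", text)) "rxn_v2000" else "reaction_smiles"
    rxn <- switch(dialect,
        reaction_smiles = .parseReactionSmiles(text, template = template),
        rxn_v2000 = .parseReactionRxn(text, template = template))
    validObject(rxn)
    rxn
}

#' Read a reaction from a file
#'
#' Convenience wrapper around [parseReaction()]: `.rxn` files are parsed
#' as RXN V2000, anything else as reaction SMILES (first non-empty line).
#'
#' @param path file path.
#' @param template logical, passed to [parseReaction()].
#' @return a \linkS4class{Reaction}.
#' @export
readReaction <- function(path, template = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    if (grepl("\\.rxn$", path, ignore.case = TRUE) ||
        any(grepl("^\\s*\\$RXN", lines[1])))
        parseReaction(lines, "rxn_v2000", template = template)
    else {
        lines <- lines[nzchar(trimws(lines))]
        if (!length(lines)) stop("empty reaction file: ", path, call. = FALSE)
        parseReaction(lines[1], "reaction_smiles", template = template)
    }
}
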