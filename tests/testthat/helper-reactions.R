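# Shared fixtures: all inputs are built in code, nothing on disk.

DA_REF <- paste0("[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]",
                 ">>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1")
# penta-1,3-diene instead of butadiene, consistently mapped (methyl = spectator)
DA_METHYL <- paste0("[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH:6][CH3:7]",
                    ">>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH:6]1[CH3:7]")
# correct structures, product ring numbered in the reversed direction:
# wrong dynamic bonds at the reaction center
DA_MISMAP <- paste0("[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]",
                    ">>[CH2:1]1[CH2:6][CH2:5][CH:4]=[CH:3][CH2:2]1")

fv <- function(...) new("FragmentVector", counts = c(...))

# Independent brute-force fragment enumerator: igraph finds every simple
# path between every vertex pair, then paths in the length window are
# canonicalized and counted.  Deliberately a different algorithm from the
# package's DFS.
oracleFragments <- function(cgr, scheme = fragmentationScheme()) {
    n <- nrow(atoms(cgr))
    bd <- bonds(cgr)
    if (n < 2L || !nrow(bd)) return(stats::setNames(integer(), character()))
    g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(bd$a), to = as.character(bd$b)),
        directed = FALSE,
        vertices = data.frame(name = as.character(seq_len(n))))
    keys <- character()
    for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
        paths <- igraph::all_simple_paths(g, from = as.character(s),
                                          to = as.character(t),
                                          cutoff = scheme@maxLen - 1L)
        for (p in paths) {
            idx <- as.integer(names(p))
            if (length(idx) >= scheme@minLen && length(idx) <= scheme@maxLen)
                keys <- c(keys, canonicalFragmentString(cgr, idx, scheme))
        }
    }
    tab <- table(keys)
    stats::setNames(as.integer(tab), names(tab))
}

# Random small CGR: random connected graph, random order pairs, occasional
# charge/radical dynamics.  Uses the session RNG; callers set the seed.
randomCGR <- function(maxAtoms = 8L) {
    n <- sample(2:maxAtoms, 1L)
    el <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
    rC <- ifelse(stats::runif(n) < 0.1, sample(c(-1L, 1L), n, replace = TRUE), 0L)
    pC <- ifelse(stats::runif(n) < 0.1, sample(c(-1L, 1L), n, replace = TRUE), rC)
    rR <- ifelse(stats::runif(n) < 0.05, 1L, 0L)
    at <- data.frame(element = el, rCharge = rC, pCharge = pC,
                     rRadical = rR, pRadical = rR, origin = "both",
                     map = seq_len(n), explicit = FALSE,
                     stringsAsFactors = FALSE)
    orders <- c("none", "single", "double", "triple", "aromatic")
    pairOrders <- function(k) {
        r <- sample(orders, k, replace = TRUE, prob = c(.15, .4, .2, .05, .2))
        p <- ifelse(stats::runif(k) < 0.5, r,
                    sample(orders, k, replace = TRUE))
        bad <- r == "none" & p == "none"
        p[bad] <- "single"
        list(r = r, p = p)
    }
    a <- integer(); b <- integer()
    if (n > 1L) for (k in 2:n) {       # random spanning tree keeps it connected
        a <- c(a, sample(seq_len(k - 1L), 1L)); b <- c(b, k)
    }
    extra <- sample(0:2, 1L)
    for (i in seq_len(extra)) {
        u <- sample(n, 2L)
        if (!any((a == min(u) & b == max(u))))
            { a <- c(a, min(u)); b <- c(b, max(u)) }
    }
    po <- pairOrders(length(a))
    new("CGR", atoms = at,
        bonds = data.frame(a = a, b = b, rOrder = po$r, pOrder = po$p,
                           stringsAsFactors = FALSE))
}

# Random consistent renumbering of a reaction's map numbers.
randomMapPermutation <- function(rxn) {
    maps <- unique(unlist(lapply(c(reactants(rxn), products(rxn)),
                                 function(m) atoms(m)$map)))
    maps <- sort(maps[maps > 0L])
    stats::setNames(sample(length(maps)), maps)
}

pythonOracle <- function(code) {
    out <- suppressWarnings(system2("python", "-", input = code,
                                    stdout = TRUE, stderr = FALSE))
    trimws(out[length(out)])
}
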