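#' Cross-tabulate two cohorts' module assignments
#'
#' For every pair of named modules (one per cohort) over the shared gene
#' universe, counts the overlap and scores it with the one-sided
#' (enrichment) Fisher exact test — the hypergeometric tail
#' `P(X >= overlap)` given the module sizes.
#'
#' @param assignA,assignB [ModuleAssignment-class] objects on overlapping
#'   gene universes.
#' @return data.frame `moduleA`, `moduleB`, `sizeA`, `sizeB`, `overlap`,
#'   `p` (one-sided Fisher).
#' @export
moduleOverlapTest <- function(assignA, assignB) {
    universe <- intersect(names(moduleLabels(assignA)),
                          names(moduleLabels(assignB)))
    if (!length(universe)) stop("empty shared gene universe")
    N <- length(universe)
    modsA <- moduleNames(assignA); modsB <- moduleNames(assignB)
    out <- expand.grid(moduleA = modsA, moduleB = modsB,
                       stringsAsFactors = FALSE)
    res <- t(apply(out, 1, function(r) {
        gA <- intersect(moduleGenes(assignA, r[["moduleA"]]), universe)
        gB <- intersect(moduleGenes(assignB, r[["moduleB"]]), universe)
        ov <- length(intersect(gA, gB))
        p <- fisherExact2x2(ov, length(gA) - ov, length(gB) - ov,
                            N - length(gA) - length(gB) + ov,
                            alternative = "greater")$p.value
        c(length(gA), length(gB), ov, p)
    }))
    out$sizeA <- as.integer(res[, 1]); out$sizeB <- as.integer(res[, 2])
    out$overlap <- as.integer(res[, 3]); out$p <- res[, 4]
    out
}

# is module m of cohort a preserved (within `classes`) in cohort b?
.preservedIn <- function(results, a, m, b, classes) {
    r <- results[[paste0(a, "->", b)]]
    if (is.null(r)) return(FALSE)
    st <- preservationStats(r)
    m %in% st$module[st$class %in% classes]
}

#' Extract gene sets conserved across a cancer group
#'
#' Searches for chains of mutually preserved modules: one module per cohort
#' of the group such that every directed pair is preserved at the required
#' class (default strong) and every module pair overlaps significantly
#' (one-sided Fisher `p <= pThreshold`). Each complete chain yields a
#' conserved set — the intersection of member genes across its modules.
#' Sets are named `Set1, Set2, ...` by decreasing size; duplicated gene
#' sets are collapsed.
#'
#' @param group cohort labels to search over (order-invariant).
#' @param results named list of [PreservationResult-class] keyed
#'   `"A->B"` (as produced by [preservationMatrix()] in its `results` slot,
#'   or assembled by hand).
#' @param assignments named list of [ModuleAssignment-class].
#' @param pThreshold Fisher overlap threshold, default 0.05.
#' @param requiredClass preservation class(es) required in every directed
#'   pair; default `"strong"`.
#' @return list of [ConservedGeneSet-class] (possibly empty).
#' @export
extractConservedSets <- function(group, results, assignments,
                                 pThreshold = 0.05,
                                 requiredClass = "strong") {
    group <- sort(group)
    if (length(group) == 1L) {
        a <- assignments[[group]]
        return(lapply(seq_along(moduleNames(a)), function(i) {
            m <- moduleNames(a)[i]
            new("ConservedGeneSet", name = paste0("Set", i),
                genes = sort(moduleGenes(a, m)), cancers = group,
                sourceModules = setNames(m, group))
        }))
    }
    # precompute pairwise overlap tables once
    ovl <- list()
    for (a in group) for (b in group) if (a < b)
        ovl[[paste0(a, "|", b)]] <-
            moduleOverlapTest(assignments[[a]], assignments[[b]])
    okPair <- function(a, mA, b, mB) {
        if (a > b) { tmp <- a; a <- b; b <- tmp; tm <- mA; mA <- mB; mB <- tm }
        t <- ovl[[paste0(a, "|", b)]]
        row <- t[t$moduleA == mA & t$moduleB == mB, ]
        nrow(row) == 1 && row$p <= pThreshold
    }
    edge <- function(a, mA, b, mB) {
        .preservedIn(results, a, mA, b, requiredClass) &&
        .preservedIn(results, b, mB, a, requiredClass) &&
        okPair(a, mA, b, mB)
    }
    chains <- list(list())
    for (cc in group) {
        nxt <- list()
        for (ch in chains) for (m in moduleNames(assignments[[cc]])) {
            ok <- all(vapply(names(ch), function(prev)
                edge(prev, ch[[prev]], cc, m), logical(1)))
            if (ok) { ch2 <- ch; ch2[[cc]] <- m; nxt <- c(nxt, list(ch2)) }
        }
        chains <- nxt
        if (!length(chains)) return(list())
    }
    sets <- lapply(chains, function(ch) {
        genes <- Reduce(intersect, lapply(group, function(cc)
            moduleGenes(assignments[[cc]], ch[[cc]])))
        list(genes = sort(genes), modules = unlist(ch))
    })
    sets <- sets[vapply(sets, function(s) length(s$genes) > 0, logical(1))]
    if (!length(sets)) return(list())
    keys <- vapply(sets, function(s) paste(s$genes, collapse = ","), "")
    sets <- sets[!duplicated(keys)]
    ord <- order(-vapply(sets, function(s) length(s$genes), 0L))
    lapply(seq_along(ord), function(i) {
        s <- sets[[ord[i]]]
        new("ConservedGeneSet", name = paste0("Set", i), genes = s$genes,
            cancers = group, sourceModules = s$modules)
    })
}

#' Restrict a conserved set to additional cancers (subset-set derivation)
#'
#' For each extra cohort, picks the module with the most significant overlap
#' with the set and intersects the set's genes with it — the mechanism that
#' derives a narrower "subset" signature conserved in a wider cancer group.
#'
#' @param set a [ConservedGeneSet-class].
#' @param extraAssignments named list of [ModuleAssignment-class] for the
#'   additional cohorts.
#' @return a new [ConservedGeneSet-class] named `"<name>-s"`.
#' @export
refineConservedSet <- function(set, extraAssignments) {
    genes <- set@genes
    src <- set@sourceModules
    for (cc in names(extraAssignments)) {
        a <- extraAssignments[[cc]]
        mods <- moduleNames(a)
        if (!length(mods) || !length(genes)) { genes <- character(); break }
        ov <- vapply(mods, function(m)
            length(intersect(genes, moduleGenes(a, m))), 0L)
        best <- mods[which.max(ov)]
        genes <- sort(intersect(genes, moduleGenes(a, best)))
        src[cc] <- best
    }
    new("ConservedGeneSet", name = paste0(set@name, "-s"), genes = genes,
        cancers = sort(c(set@cancers, names(extraAssignments))),
        sourceModules = src)
}

#' Thresholded interaction network on a gene subset
#'
#' Keeps an (undirected) edge between two genes iff their topological
#' overlap is at least `edgeThreshold`.
#'
#' @param net a [CoexpressionNetwork-class] with TOM computed.
#' @param genes gene subset (must lie in the network's universe).
#' @param edgeThreshold TOM weight cutoff in \[0, 1\]; default 0.02.
#' @return a [GeneNetwork-class].
#' @export
interactionNetwork <- function(net, genes, edgeThreshold = 0.02) {
    if (edgeThreshold < 0 || edgeThreshold > 1)
        stop("edgeThreshold must lie in [0,1]")
    tom <- tomMatrix(net)
    missing <- setdiff(genes, rownames(tom))
    if (length(missing))
        stop("genes outside the network universe: ",
             paste(head(missing, 5), collapse = ", "))
    genes <- sort(genes)
    sub <- tom[genes, genes, drop = FALSE]
    idx <- which(upper.tri(sub) & sub >= edgeThreshold, arr.ind = TRUE)
    edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                        weight = sub[idx])
    new("GeneNetwork", nodes = genes, edges = edges)
}

#' Hub genes of an interaction network
#'
#' Genes with degree at or above `minDegree` (default 10 interacting
#' partners), sorted by degree descending, ties broken lexicographically.
#'
#' @param network a [GeneNetwork-class].
#' @param minDegree interaction-count threshold, default 10.
#' @return character vector of hub gene ids (named with degrees).
#' @export
findHubs <- function(network, minDegree = 10) {
    d <- nodeDegree(network)
    d <- d[d >= minDegree]
    d <- d[order(-d, names(d))]
    structure(names(d), degree = unname(d))
}

#' Classifier genes common to every cohort of a group
#'
#' Intersects per-cancer hub sets; optionally partitions the intersection by
#' source conserved set.
#'
#' @param hubSets named list (one per cohort) of hub gene vectors.
#' @param sourceSets optional named list of gene vectors (or
#'   [ConservedGeneSet-class]) to partition the classifiers by.
#' @return if `sourceSets` is NULL, a sorted character vector; otherwise a
#'   named list of classifier genes per source set (genes outside every
#'   source set under `"other"`).
#' @export
commonClassifiers <- function(hubSets, sourceSets = NULL) {
    common <- sort(Reduce(intersect, hubSets))
    if (is.null(sourceSets)) return(common)
    sourceSets <- lapply(sourceSets, function(s)
        if (is(s, "ConservedGeneSet")) s@genes else s)
    out <- lapply(sourceSets, function(g) intersect(common, g))
    rest <- setdiff(common, unlist(sourceSets))
    if (length(rest)) out$other <- rest
    out
}
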