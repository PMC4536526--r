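# observed preservation statistics of a gene index set, given precomputed
# correlation and adjacency matrices of the reference and test cohorts
.presStats <- function(idx, corRef, corTest, adjRef, adjTest) {
    off <- upper.tri(matrix(0, length(idx), length(idx)))
    cR <- corRef[idx, idx]; cT <- corTest[idx, idx]
    aR <- adjRef[idx, idx]; aT <- adjTest[idx, idx]
    kR <- rowSums(aR) - 1; kT <- rowSums(aT) - 1
    c(meanAbsCor = mean(abs(cT[off])),
      meanAdj = mean(aT[off]),
      corKIM = suppressWarnings(cor(kR, kT)),
      corCor = suppressWarnings(cor(cR[off], cT[off])))
}

#' Permutation module-preservation statistics (Zsummary, medianRank)
#'
#' Each reference module with >= 3 genes shared between cohorts is scored in
#' the TEST cohort on four observed statistics: two density statistics (mean
#' within-module |correlation| and mean within-module adjacency) and two
#' connectivity statistics (correlation of intramodular connectivity between
#' cohorts and correlation of the two cohorts' within-module correlation
#' matrices' off-diagonal entries). A null distribution is built from
#' `nPerm` random gene sets of the same size drawn from the shared universe;
#' each statistic is standardized against its null (`Z = (obs - mean)/sd`),
#' `Zdensity` / `Zconnectivity` average the pair, and
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. Modules are additionally
#' ranked (1 = best) on each observed statistic; `medianRank` is the median
#' of the four ranks.
#'
#' @param refAssign [ModuleAssignment-class] from the reference cohort.
#' @param refCohort,testCohort [CancerCohort-class] objects (or matrices)
#'   sharing gene identifiers.
#' @param nPerm random gene sets per module size (>= 50; default 200).
#' @param seed integer seed for the permutation draws.
#' @param power soft-threshold exponent for the adjacency statistic.
#' @return a [PreservationResult-class].
#' @export
modulePreservation <- function(refAssign, refCohort, testCohort,
                               nPerm = 200, seed = 1, power = 6) {
    stopifnot(nPerm >= 50)
    xr <- if (is(refCohort, "CancerCohort")) exprsMatrix(refCohort)
          else refCohort
    xt <- if (is(testCohort, "CancerCohort")) exprsMatrix(testCohort)
          else testCohort
    refName <- if (is(refCohort, "CancerCohort")) cohortName(refCohort)
               else "ref"
    testName <- if (is(testCohort, "CancerCohort")) cohortName(testCohort)
                else "test"
    universe <- sort(intersect(rownames(xr), rownames(xt)))
    if (length(universe) < 10)
        stop("shared gene universe too small (", length(universe), ")")
    corRef <- .safeCor(xr[universe, , drop = FALSE])
    corTest <- .safeCor(xt[universe, , drop = FALSE])
    adjRef <- abs(corRef)^power; diag(adjRef) <- 1
    adjTest <- abs(corTest)^power; diag(adjTest) <- 1

    mods <- moduleNames(refAssign)
    shared <- lapply(mods, function(m)
        which(universe %in% moduleGenes(refAssign, m)))
    names(shared) <- mods
    small <- vapply(shared, length, 0L) < 3
    if (any(small)) {
        warning("module(s) with < 3 shared genes skipped: ",
                paste(mods[small], collapse = ", "))
        shared <- shared[!small]
    }
    if (!length(shared))
        return(new("PreservationResult", refCohort = refName,
                   testCohort = testName,
                   stats = data.frame(module = character(),
                                      nGenes = integer(),
                                      Zdensity = numeric(),
                                      Zconnectivity = numeric(),
                                      Zsummary = numeric(),
                                      medianRank = numeric(),
                                      class = character())))

    obs <- t(vapply(shared, .presStats, numeric(4),
                    corRef, corTest, adjRef, adjTest))
    # one null ensemble per distinct module size, shared across modules
    sizes <- vapply(shared, length, 0L)
    nulls <- withr::with_seed(seed, {
        out <- list()
        for (s in sort(unique(sizes))) {
            out[[as.character(s)]] <- t(vapply(seq_len(nPerm), function(i) {
                .presStats(sample(length(universe), s),
                           corRef, corTest, adjRef, adjTest)
            }, numeric(4)))
        }
        out
    })
    zs <- t(vapply(seq_along(shared), function(i) {
        nl <- nulls[[as.character(sizes[i])]]
        mu <- colMeans(nl); sdv <- apply(nl, 2, sd)
        z <- (obs[i, ] - mu) / sdv
        if (any(sdv == 0)) {
            warning("zero null sd for module '", names(shared)[i],
                    "'; Z reported as +Inf")
            z[sdv == 0] <- Inf
        }
        z
    }, numeric(4)))
    zDens <- rowMeans(zs[, 1:2, drop = FALSE])
    zConn <- rowMeans(zs[, 3:4, drop = FALSE])
    zSum <- (zDens + zConn) / 2
    ranks <- apply(-obs, 2, rank, ties.method = "average")
    if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
    medRank <- apply(ranks, 1, median)
    stats <- data.frame(module = names(shared), nGenes = sizes,
                        Zdensity = zDens, Zconnectivity = zConn,
                        Zsummary = zSum, medianRank = medRank,
                        class = classifyPreservation(zSum, medRank),
                        row.names = NULL)
    new("PreservationResult", refCohort = refName, testCohort = testName,
        stats = stats)
}

#' Classify preservation strength from Zsummary and medianRank
#'
#' Strong: `Zsummary > 10` and `medianRank < 10`; moderate:
#' `2 < Zsummary <= 10` and `medianRank < 10`; otherwise none. The
#' boundaries (exactly 10, exactly 2) fall to the lower class.
#'
#' @param zsummary,medianRank numeric vectors (recycled together).
#' @return character vector of `"strong"`, `"moderate"`, `"none"`.
#' @examples
#' classifyPreservation(c(12, 5, 1), c(3, 4, 20))
#' @export
classifyPreservation <- function(zsummary, medianRank) {
    stopifnot(!any(is.na(zsummary)), !any(is.na(medianRank)))
    ifelse(zsummary > 10 & medianRank < 10, "strong",
           ifelse(zsummary > 2 & medianRank < 10, "moderate", "none"))
}

#' Percent of a cohort's modules preserved in another cohort
#'
#' `preserved / total * 100`, reported to 2 decimals.
#'
#' @param nPreserved,nTotal module counts; `nTotal >= 1`.
#' @return percentage in \[0, 100\].
#' @examples
#' percentPreservation(5, 10)   # 50
#' percentPreservation(5, 11)   # 45.45
#' @export
percentPreservation <- function(nPreserved, nTotal) {
    stopifnot(nTotal >= 1, nPreserved <= nTotal, nPreserved >= 0)
    round(nPreserved / nTotal * 100, 2)
}

#' Pairwise percent-preservation matrix over a set of cohorts
#'
#' For every ordered cohort pair (A, B), A's modules are scored in B with
#' [modulePreservation()] and cell (A, B) is the percentage classified in
#' `countClasses` (default strong + moderate). The matrix is asymmetric by
#' construction (different module counts and preservation per direction).
#' The diagonal is 100 by definition: every module is self-preserved.
#'
#' @param cohorts named list of [CancerCohort-class].
#' @param assignments named list of [ModuleAssignment-class] (same names).
#' @param nPerm,seed,power passed to [modulePreservation()]; per-pair seeds
#'   are derived deterministically from `seed`.
#' @param countClasses preservation classes counted as "preserved".
#' @return a [PreservationMatrix-class].
#' @export
preservationMatrix <- function(cohorts, assignments, nPerm = 200, seed = 1,
                               power = 6,
                               countClasses = c("strong", "moderate")) {
    nm <- names(cohorts)
    stopifnot(length(nm) >= 2, setequal(nm, names(assignments)))
    k <- length(nm)
    pct <- pres <- tot <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    results <- list()
    for (i in seq_len(k)) {
        nTot <- length(moduleNames(assignments[[nm[i]]]))
        for (j in seq_len(k)) {
            if (i == j) {
                pres[i, j] <- tot[i, j] <- nTot
                pct[i, j] <- if (nTot) 100 else NA_real_
                next
            }
            r <- modulePreservation(assignments[[nm[i]]], cohorts[[nm[i]]],
                                    cohorts[[nm[j]]], nPerm = nPerm,
                                    seed = seed + 131 * i + j, power = power)
            results[[paste0(nm[i], "->", nm[j])]] <- r
            nPres <- sum(preservationStats(r)$class %in% countClasses)
            pres[i, j] <- nPres
            tot[i, j] <- nTot
            pct[i, j] <- if (nTot) percentPreservation(nPres, nTot)
                         else NA_real_
        }
    }
    new("PreservationMatrix", percent = pct, preserved = pres, total = tot,
        results = results)
}
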