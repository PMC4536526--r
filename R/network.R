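#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power, builds the (unsigned or signed) adjacency,
#' computes whole-network connectivity k, bins log10(k), and regresses
#' log10 frequency on log10 mean-k per bin. The signed fit index is R^2 with
#' the sign of the slope flipped, so only a decaying degree distribution can
#' qualify. The chosen power is the smallest candidate with signed R^2 at or
#' above `rsqCut`; if none qualifies, the candidate with the best signed R^2.
#'
#' @param cohort a [CancerCohort-class] (or plain genes x samples matrix).
#' @param candidatePowers integer candidates, default 1:20.
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @param rsqCut qualifying scale-free fit, default 0.8.
#' @param nBreaks connectivity bins for the frequency regression.
#' @return list with `power` (chosen) and `fitTable` (data.frame `power`,
#'   `rsq` signed fit index, `meanK` mean connectivity).
#' @export
pickSoftThreshold <- function(cohort, candidatePowers = 1:20,
                              mode = c("unsigned", "signed"),
                              rsqCut = 0.8, nBreaks = 10) {
    mode <- match.arg(mode)
    x <- if (is(cohort, "CancerCohort")) exprsMatrix(cohort) else cohort
    stopifnot(ncol(x) >= 3, nrow(x) >= 2)
    x <- .dropConstantGenes(x)
    cc <- .safeCor(x)
    fit <- vapply(candidatePowers, function(p) {
        a <- if (mode == "unsigned") abs(cc)^p else ((1 + cc) / 2)^p
        k <- rowSums(a) - 1
        c(.scaleFreeRsq(k, nBreaks), mean(k))
    }, numeric(2))
    tab <- data.frame(power = candidatePowers, rsq = fit[1, ],
                      meanK = fit[2, ])
    ok <- which(!is.na(tab$rsq) & tab$rsq >= rsqCut)
    if (length(ok)) {
        power <- tab$power[ok[1]]
    } else if (any(!is.na(tab$rsq))) {
        power <- tab$power[which.max(tab$rsq)]
        warning("no candidate power reaches scale-free R^2 >= ", rsqCut,
                "; using best fit (power ", power, ")")
    } else {
        power <- if (6 %in% candidatePowers) 6L else
            candidatePowers[ceiling(length(candidatePowers) / 2)]
        warning("scale-free fit undefined (too few genes); ",
                "falling back to power ", power)
    }
    list(power = power, fitTable = tab)
}

.scaleFreeRsq <- function(k, nBreaks) {
    k <- k[k > 0]
    if (length(k) < nBreaks || diff(range(k)) == 0) return(NA_real_)
    # equal-width bins on k; empty bins stay in with a small
    # pseudo-frequency (standard scale-free fit index convention), so the
    # decay of the degree distribution is visible to the regression
    br <- seq(min(k), max(k), length.out = nBreaks + 1)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- as.vector(table(bin)) / length(k)
    kmean <- tapply(k, bin, mean)
    mids <- (br[-1] + br[-length(br)]) / 2
    kmean[is.na(kmean) | kmean == 0] <- mids[is.na(kmean) | kmean == 0]
    f <- lm(log10(freq + 1e-9) ~ log10(kmean))
    -sign(coef(f)[2]) * summary(f)$r.squared
}

.dropConstantGenes <- function(x) {
    v <- apply(x, 1, var, na.rm = TRUE)
    bad <- !is.finite(v) | v < .Machine$double.eps
    if (any(bad)) {
        warning(sum(bad), " constant gene(s) dropped before network ",
                "construction: ", paste(head(rownames(x)[bad], 5),
                                        collapse = ", "))
        x <- x[!bad, , drop = FALSE]
    }
    x
}

# pairwise-complete Pearson correlation with NA -> 0 guard
.safeCor <- function(x) {
    cc <- cor(t(x), use = "pairwise.complete.obs")
    if (anyNA(cc)) {
        warning("undefined correlations set to 0")
        cc[is.na(cc)] <- 0
    }
    cc
}

#' Build the soft-thresholded co-expression adjacency of a cohort
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned) or `((1 + cor)/2)^beta` (signed);
#' diagonal set to 1 by convention. Constant genes are dropped with a
#' warning.
#'
#' @param cohort a [CancerCohort-class] or genes x samples matrix.
#' @param power soft-threshold exponent beta (>= 1).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return a [CoexpressionNetwork-class] (TOM not yet computed).
#' @export
coexpressionNetwork <- function(cohort, power = 6,
                                mode = c("unsigned", "signed")) {
    mode <- match.arg(mode)
    stopifnot(power >= 1)
    x <- if (is(cohort, "CancerCohort")) exprsMatrix(cohort) else cohort
    label <- if (is(cohort, "CancerCohort")) cohortName(cohort) else "cohort"
    x <- .dropConstantGenes(x)
    cc <- .safeCor(x)
    a <- if (mode == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
    diag(a) <- 1
    new("CoexpressionNetwork", cohort = label, power = as.numeric(power),
        mode = mode, adjacency = a,
        tom = matrix(numeric(0), 0, 0))
}

#' Topological overlap similarity of a network
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j (the shared-neighbour sum excludes u = i, j), with unit diagonal.
#' The denominator is >= 1 whenever adjacency is in \[0,1\], so the ratio is
#' well defined and bounded by 1.
#'
#' @param net a [CoexpressionNetwork-class] with adjacency computed.
#' @return the network with its `tom` slot filled.
#' @export
tomSimilarity <- function(net) {
    a <- net@adjacency
    diag(a) <- 0
    k <- rowSums(a)
    num <- a %*% a + a          # (A^2)_ij sums over all u; diag(a)=0 removes u=i,j terms
    kmin <- outer(k, k, pmin)
    tom <- num / (kmin + 1 - a)
    diag(tom) <- 1
    tom <- (tom + t(tom)) / 2   # enforce exact symmetry against FP noise
    dimnames(tom) <- dimnames(net@adjacency)
    net@tom <- tom
    validObject(net)
    net
}

#' Detect co-expression modules by clustering the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' `cutHeight` (auto = 0.99). Under soft thresholding, unrelated genes have
#' topological overlap near 0, so their dissimilarity sits essentially at 1,
#' above the cut: they fall out as singletons or slivers and are collected
#' under the unassigned label. Surviving branches smaller than
#' `minModuleSize` are likewise unassigned. Named modules are labelled
#' `M1, M2, ...` by decreasing size (ties broken by smallest member gene id),
#' which makes labels invariant to gene-order permutations.
#'
#' @param net a [CoexpressionNetwork-class] with TOM computed
#'   (see [tomSimilarity()]).
#' @param minModuleSize smallest named module, default 30 (>= 3).
#' @param cutHeight static cut height on 1 - TOM, or `"auto"` for 0.99.
#' @param unassigned reserved label for unclustered genes, default `"grey"`.
#' @return a [ModuleAssignment-class].
#' @export
detectModules <- function(net, minModuleSize = 30, cutHeight = "auto",
                          unassigned = "grey") {
    stopifnot(minModuleSize >= 3)
    if (identical(cutHeight, "auto")) cutHeight <- 0.99
    tom <- tomMatrix(net)
    genes <- rownames(tom)
    hc <- hclust(as.dist(1 - tom), method = "average")
    cl <- cutree(hc, h = cutHeight)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= minModuleSize]
    lab <- rep(unassigned, length(genes))
    names(lab) <- genes
    if (length(keep)) {
        # order clusters by size desc, tie-break on smallest gene id
        ord <- order(-as.integer(sizes[keep]),
                     vapply(keep, function(k) min(genes[cl == k]), ""))
        for (i in seq_along(ord))
            lab[cl == as.integer(keep[ord[i]])] <- paste0("M", i)
    }
    new("ModuleAssignment", labels = lab, unassigned = unassigned)
}
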