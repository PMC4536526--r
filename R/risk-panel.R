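#' Identify survival-associated risk genes by median-split log-rank
#'
#' Each candidate gene dichotomizes the cohort at its median expression
#' (ties: `>= median` is the high group); the two groups are compared by
#' log-rank. Genes at or below `pThreshold` are kept. The risk direction is
#' +1 (high expression hazardous) when the high-expression group's
#' Kaplan-Meier survival at `horizonDays` is the lower one, else -1.
#'
#' @param cohort a [CancerCohort-class] with survival annotation.
#' @param genes candidate universe (e.g. conserved-set genes); default all.
#' @param pThreshold log-rank significance cutoff, default 0.01.
#' @param horizonDays evaluation horizon for the direction call; default
#'   the mean observed follow-up time.
#' @return data.frame `gene`, `p`, `direction` sorted by p (class
#'   `riskGeneTable`).
#' @export
identifyRiskGenes <- function(cohort, genes = NULL, pThreshold = 0.01,
                              horizonDays = NULL) {
    x <- exprsMatrix(cohort)
    surv <- survivalTable(cohort)
    keep <- complete.cases(surv[c("time_days", "event")])
    surv <- surv[keep, ]
    x <- x[, surv$sample_id, drop = FALSE]
    if (is.null(genes)) genes <- rownames(x)
    genes <- intersect(genes, rownames(x))
    if (is.null(horizonDays)) horizonDays <- mean(surv$time_days)
    rows <- lapply(genes, function(g) {
        v <- x[g, ]
        hi <- v >= median(v)
        if (all(hi) || !any(hi)) {
            message("gene ", g, " constant at its median; skipped")
            return(NULL)
        }
        lt <- tryCatch(logrankTest(surv$time_days, surv$event, hi),
                       error = function(e) NULL)
        if (is.null(lt) || is.na(lt$p.value) || lt$p.value > pThreshold)
            return(NULL)
        sHi <- survivalAt(kmEstimate(surv$time_days[hi], surv$event[hi]),
                          horizonDays)
        sLo <- survivalAt(kmEstimate(surv$time_days[!hi], surv$event[!hi]),
                          horizonDays)
        data.frame(gene = g, p = lt$p.value,
                   direction = if (sHi < sLo) 1L else -1L)
    })
    out <- do.call(rbind, c(rows, list(data.frame(gene = character(),
                                                  p = numeric(),
                                                  direction = integer()))))
    out <- out[order(out$p, out$gene), ]
    row.names(out) <- NULL
    class(out) <- c("riskGeneTable", "data.frame")
    out
}

#' Risk genes shared across a cancer group
#'
#' Intersection of per-cancer risk-gene identities, tolerating up to
#' `allowedOutliers` cohorts in which a gene may be missing (the mechanism
#' that admits one deviant cohort).
#'
#' @param riskLists named list of risk tables ([identifyRiskGenes()]
#'   output) or plain gene vectors, one per cancer.
#' @param allowedOutliers cohorts a gene may miss, default 0.
#' @return sorted character vector of common risk genes.
#' @export
commonRiskGenes <- function(riskLists, allowedOutliers = 0) {
    stopifnot(length(riskLists) >= 2)
    genes <- lapply(riskLists, function(l)
        if (is.data.frame(l)) l$gene else l)
    tab <- table(unlist(lapply(genes, unique)))
    sort(names(tab)[tab >= length(genes) - allowedOutliers])
}

#' Actual patient risk from survival follow-up and a per-cancer horizon
#'
#' Death before the horizon: high risk. Observed (event or censoring) time
#' at or past the horizon: low risk. Censored before the horizon:
#' indeterminate — excluded from downstream confusion counts.
#'
#' @param survival data.frame `sample_id`, `time_days`, `event`.
#' @param thresholdYears per-cancer horizon in years (e.g. 3 for breast and
#'   ovarian, 1 for colon/rectal/lung, 2 for glioblastoma).
#' @param daysPerYear default 365.25.
#' @return data.frame `sample_id`, `actual` in
#'   \{"high", "low", "indeterminate"\}.
#' @export
assignActualRisk <- function(survival, thresholdYears,
                             daysPerYear = 365.25) {
    stopifnot(thresholdYears > 0)
    if (any(survival$time_days < 0, na.rm = TRUE))
        stop("negative follow-up times")
    thr <- thresholdYears * daysPerYear
    actual <- ifelse(survival$time_days >= thr, "low",
                     ifelse(survival$event == 1, "high", "indeterminate"))
    data.frame(sample_id = survival$sample_id, actual = actual,
               row.names = NULL)
}

# normalize a panel argument to a data.frame gene / direction
.panelTable <- function(panel, cancer = NULL) {
    if (is(panel, "RiskPanel")) {
        stopifnot(!is.null(cancer))
        p <- panelGenes(panel, cancer)
    } else if (is.data.frame(panel)) {
        p <- panel[c("gene", "direction")]
    } else {
        p <- data.frame(gene = panel, direction = 1L)
    }
    if (!nrow(p)) stop("empty panel")
    p
}

#' Predict patient risk from panel-gene expression
#'
#' A panel gene votes "risky" for a sample when its expression lies on the
#' risky side of the cohort median: strictly above for direction +1,
#' strictly below for -1. A sample is predicted high risk when more than
#' half of the evaluated panel genes vote risky; an exact half votes low
#' (conservative tie rule).
#'
#' @param cohort a [CancerCohort-class] or genes x samples matrix.
#' @param panel a [RiskPanel-class] (with `cancer`), a data.frame with
#'   `gene`/`direction`, or a gene vector (directions +1).
#' @param cancer cohort label selecting the panel when a RiskPanel is given.
#' @return data.frame `sample_id`, `predicted` in \{"high", "low"\},
#'   `n_risky`, `n_eval`.
#' @export
predictRisk <- function(cohort, panel, cancer = NULL) {
    x <- if (is(cohort, "CancerCohort")) exprsMatrix(cohort) else cohort
    p <- .panelTable(panel, cancer)
    p <- p[p$gene %in% rownames(x), ]
    if (!nrow(p)) stop("no panel genes present in the expression matrix")
    risky <- vapply(seq_len(nrow(p)), function(i) {
        v <- x[p$gene[i], ]
        md <- median(v)
        if (p$direction[i] > 0) v > md else v < md
    }, logical(ncol(x)))
    if (is.null(dim(risky))) risky <- matrix(risky, nrow = 1)
    nRisky <- rowSums(risky)
    data.frame(sample_id = colnames(x),
               predicted = ifelse(nRisky > nrow(p) / 2, "high", "low"),
               n_risky = nRisky, n_eval = nrow(p), row.names = NULL)
}

#' Confusion summary of predicted vs actual risk
#'
#' High risk is the positive class. Indeterminate actual labels are
#' excluded. Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP); an empty
#' denominator yields NA (undefined), not 0.
#'
#' @param predicted data.frame from [predictRisk()].
#' @param actual data.frame from [assignActualRisk()].
#' @return a `confusionSummary` list: TP, FP, TN, FN, sensitivity,
#'   specificity, nEvaluated, nIndeterminate.
#' @export
evaluatePrediction <- function(predicted, actual) {
    m <- merge(predicted, actual, by = "sample_id")
    nInd <- sum(m$actual == "indeterminate")
    m <- m[m$actual != "indeterminate", ]
    TP <- sum(m$predicted == "high" & m$actual == "high")
    FP <- sum(m$predicted == "high" & m$actual == "low")
    TN <- sum(m$predicted == "low" & m$actual == "low")
    FN <- sum(m$predicted == "low" & m$actual == "high")
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                   sensitivity = sens, specificity = spec,
                   nEvaluated = nrow(m), nIndeterminate = nInd),
              class = "confusionSummary")
}

#' @export
print.confusionSummary <- function(x, ...) {
    cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d | sens=%.3f spec=%.3f (%d evaluated, %d indeterminate)\n",
                x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity,
                x$nEvaluated, x$nIndeterminate))
    invisible(x)
}

#' Compare two risk signatures by McNemar's test
#'
#' Per-sample correctness of each prediction against the actual risk label
#' (indeterminate excluded); the discordant counts feed
#' [mcnemarTest()].
#'
#' @param predA,predB data.frames from [predictRisk()] on the same samples.
#' @param actual data.frame from [assignActualRisk()].
#' @return an `htest` (with `discordant` counts attached).
#' @export
compareSignatures <- function(predA, predB, actual) {
    m <- merge(merge(predA[c("sample_id", "predicted")],
                     predB[c("sample_id", "predicted")],
                     by = "sample_id", suffixes = c("A", "B")),
               actual, by = "sample_id")
    m <- m[m$actual != "indeterminate", ]
    okA <- m$predictedA == m$actual
    okB <- m$predictedB == m$actual
    b <- sum(okA & !okB); c <- sum(!okA & okB)
    res <- mcnemarTest(b, c)
    res$discordant <- c(b = b, c = c)
    res
}

#' Assemble per-cancer prognostic panels and their pan-cancer union
#'
#' Applies a per-cancer composition rule: `"common-set1"` uses the shared
#' Set-1 risk genes, `"common-set2"` the shared Set-2 risk genes,
#' `"combined"` both, and `"common+individual"` the Set-1 common genes plus
#' that cancer's `nIndividual` most significant own risk genes not already
#' in the common lists (ties by gene id). Genes duplicated within a cancer
#' are kept once.
#'
#' @param commonSet1,commonSet2 data.frames `gene`/`direction` (or gene
#'   vectors, directions +1).
#' @param individual named list of per-cancer risk tables
#'   ([identifyRiskGenes()] output), needed for `"common+individual"`.
#' @param rules named character: cancer -> rule.
#' @param nIndividual individual genes to add, default 3.
#' @return a [RiskPanel-class].
#' @export
assemblePanel <- function(commonSet1, commonSet2 = NULL, individual = list(),
                          rules, nIndividual = 3) {
    s1 <- if (is.null(commonSet1) || !length(commonSet1))
        data.frame(gene = character(), direction = integer())
        else .panelTable(commonSet1)
    s2 <- if (is.null(commonSet2) || !length(commonSet2))
        data.frame(gene = character(), direction = integer())
        else .panelTable(commonSet2)
    withRule <- function(df, rule) {
        if (!nrow(df)) return(data.frame(gene = character(),
                                         direction = integer(),
                                         rule = character()))
        cbind(df, rule = rule)
    }
    rows <- list()
    for (cc in names(rules)) {
        rule <- match.arg(rules[[cc]],
                          c("common-set1", "common-set2", "combined",
                            "common+individual"))
        part <- switch(rule,
            "common-set1" = withRule(s1, rule),
            "common-set2" = withRule(s2, rule),
            "combined" = withRule(rbind(s1, s2), rule),
            "common+individual" = {
                ind <- individual[[cc]]
                if (is.null(ind)) ind <- data.frame(gene = character(),
                                                    p = numeric(),
                                                    direction = integer())
                ind <- ind[!ind$gene %in% c(s1$gene, s2$gene), ]
                ind <- ind[order(ind$p, ind$gene), ]
                if (nrow(ind) < nIndividual)
                    warning("cancer ", cc, ": only ", nrow(ind),
                            " individual risk gene(s) available")
                ind <- head(ind, nIndividual)
                rbind(withRule(s1, "common-set1"),
                      withRule(data.frame(gene = ind$gene,
                                          direction = ind$direction),
                               "individual"))
            })
        if (!nrow(part)) next
        part <- part[!duplicated(part$gene), ]
        rows[[cc]] <- data.frame(cancer = cc, part, row.names = NULL)
    }
    panels <- do.call(rbind, c(rows, list(data.frame(cancer = character(),
                                                     gene = character(),
                                                     direction = integer(),
                                                     rule = character()))))
    if (!nrow(panels)) warning("all panel lists empty")
    row.names(panels) <- NULL
    new("RiskPanel", panels = panels)
}
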