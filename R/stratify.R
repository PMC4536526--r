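#' Per-sample classifier-set expression score
#'
#' Each classifier gene is standardized across samples (z-score); the set
#' score of a sample is the mean z over the classifier genes present in the
#' matrix. Missing genes are skipped with a message.
#'
#' @param cohort a [CancerCohort-class] (or genes x samples matrix).
#' @param genes classifier gene ids (>= 1 present required).
#' @return named numeric vector, one score per sample.
#' @export
setScore <- function(cohort, genes) {
    x <- if (is(cohort, "CancerCohort")) exprsMatrix(cohort) else cohort
    present <- intersect(genes, rownames(x))
    if (!length(present))
        stop("none of the classifier genes are present in the matrix")
    if (length(present) < length(genes))
        message(length(genes) - length(present),
                " classifier gene(s) absent; skipped")
    z <- t(scale(t(x[present, , drop = FALSE])))
    z[!is.finite(z)] <- 0   # constant genes contribute nothing
    colMeans(z, na.rm = TRUE)
}

#' Assign samples to expression classes from set scores
#'
#' Two-set mode (both scores given): Class 1 = both scores > 0 (classifiers
#' of both sets expressed), Class 2 = Set-1 score only > 0, Class 3 = Set-2
#' score only > 0, Class 4 = neither (both sets down). One-set mode
#' (`scoreSet2 = NULL`): Class 1 = score > 0, Class 2 otherwise. A score of
#' exactly 0 counts as "down".
#'
#' @param scoreSet1 named per-sample score for the first classifier set.
#' @param scoreSet2 optional score for the second set (same samples).
#' @return data.frame `sample_id`, `class` (integer), `score_set1`,
#'   (`score_set2`).
#' @export
classifySamples <- function(scoreSet1, scoreSet2 = NULL) {
    if (is.null(scoreSet2)) {
        cls <- ifelse(scoreSet1 > 0, 1L, 2L)
        return(data.frame(sample_id = names(scoreSet1), class = cls,
                          score_set1 = unname(scoreSet1),
                          row.names = NULL))
    }
    stopifnot(identical(names(scoreSet1), names(scoreSet2)))
    up1 <- scoreSet1 > 0; up2 <- scoreSet2 > 0
    cls <- ifelse(up1 & up2, 1L, ifelse(up1, 2L, ifelse(up2, 3L, 4L)))
    data.frame(sample_id = names(scoreSet1), class = cls,
               score_set1 = unname(scoreSet1),
               score_set2 = unname(scoreSet2), row.names = NULL)
}

#' Associate expression classes with survival
#'
#' Kaplan-Meier curve per class plus the overall (and, when more than two
#' classes, all pairwise) log-rank tests. Samples without survival records
#' are dropped with a message.
#'
#' @param classes data.frame from [classifySamples()].
#' @param survival data.frame `sample_id`, `time_days`, `event`.
#' @return list with `curves` (named list of `kmCurve`), `overall`
#'   (log-rank `htest` or NULL if a single class), `pairwise` (named list
#'   of `htest`), and `n` per class.
#' @export
classSurvival <- function(classes, survival) {
    m <- merge(classes, survival, by = "sample_id")
    drop <- nrow(classes) - nrow(m)
    if (drop > 0) message(drop, " sample(s) without survival records dropped")
    m <- m[complete.cases(m[c("time_days", "event")]), ]
    present <- sort(unique(m$class))
    curves <- lapply(setNames(present, paste0("class", present)),
                     function(cl) {
                         i <- m$class == cl
                         kmEstimate(m$time_days[i], m$event[i])
                     })
    if (length(present) < 2) {
        warning("single non-empty class; log-rank tests skipped")
        return(list(curves = curves, overall = NULL, pairwise = list(),
                    n = table(m$class)))
    }
    overall <- logrankTest(m$time_days, m$event, m$class)
    pairwise <- list()
    if (length(present) > 2) {
        for (i in seq_along(present)) for (j in seq_along(present)) {
            if (i >= j) next
            sel <- m$class %in% present[c(i, j)]
            key <- paste0(present[i], "vs", present[j])
            pairwise[[key]] <- tryCatch(
                logrankTest(m$time_days[sel], m$event[sel], m$class[sel]),
                error = function(e) NULL)
        }
    }
    list(curves = curves, overall = overall, pairwise = pairwise,
         n = table(m$class))
}
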