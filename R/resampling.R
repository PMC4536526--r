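#' Revalidate a panel over random resampled datasets (RDs)
#'
#' Draws `nRd` patient subsets of size `rdSize` (without replacement by
#' default), predicts risk within each RD with [predictRisk()] (medians are
#' recomputed inside the RD), and tests predicted high vs low risk by
#' two-group log-rank. An RD in which every patient lands in one predicted
#' group is counted non-significant and flagged.
#'
#' @param cohort a [CancerCohort-class] with survival annotation.
#' @param panel panel accepted by [predictRisk()].
#' @param nRd number of random datasets, default 100.
#' @param rdSize patients per RD (<= cohort size unless `replace`).
#' @param seed integer; one seed drives all draws.
#' @param alpha per-RD significance level, default 0.05.
#' @param replace bootstrap (with replacement) instead of subsampling.
#' @param cancer passed through to [predictRisk()] for RiskPanel input.
#' @return list with `perRD` (data.frame `rd`, `n_high`, `n_low`, `chisq`,
#'   `p`, `degenerate`), `fractionSignificant`, `alpha`.
#' @export
resampleValidate <- function(cohort, panel, nRd = 100, rdSize,
                             seed = 1, alpha = 0.05, replace = FALSE,
                             cancer = NULL) {
    stopifnot(nRd >= 1)
    n <- ncol(cohort)
    if (!replace && rdSize > n)
        stop("rdSize exceeds cohort size (", n, ")")
    perRD <- withr::with_seed(seed, {
        do.call(rbind, lapply(seq_len(nRd), function(r) {
            idx <- sample(n, rdSize, replace = replace)
            sub <- cohort[, idx]
            if (replace) colnames(sub) <- make.unique(colnames(sub))
            pred <- predictRisk(sub, panel, cancer = cancer)
            surv <- survivalTable(sub)
            m <- merge(pred, surv, by = "sample_id")
            nh <- sum(m$predicted == "high"); nl <- sum(m$predicted == "low")
            if (nh == 0 || nl == 0) {
                return(data.frame(rd = r, n_high = nh, n_low = nl,
                                  chisq = NA_real_, p = NA_real_,
                                  degenerate = TRUE))
            }
            lt <- tryCatch(logrankTest(m$time_days, m$event, m$predicted),
                           error = function(e) NULL)
            data.frame(rd = r, n_high = nh, n_low = nl,
                       chisq = if (is.null(lt)) NA_real_
                               else unname(lt$statistic),
                       p = if (is.null(lt)) NA_real_ else lt$p.value,
                       degenerate = is.null(lt))
        }))
    })
    if (any(perRD$degenerate))
        message(sum(perRD$degenerate),
                " RD(s) degenerate (single predicted group); ",
                "counted non-significant")
    frac <- mean(!is.na(perRD$p) & perRD$p < alpha)
    list(perRD = perRD, fractionSignificant = frac, alpha = alpha)
}
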