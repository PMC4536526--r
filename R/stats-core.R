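#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct observed times,
#' where `d_i` deaths and `n_i` at-risk (censored-at-t samples count as at
#' risk at t).
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return a `kmCurve` data.frame: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (the step value just after `time`).
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 0, 1))
#' @export
kmEstimate <- function(times, events) {
    stopifnot(length(times) == length(events), length(times) > 0,
              all(times >= 0), all(events %in% c(0, 1)))
    tt <- sort(unique(times))
    nRisk <- vapply(tt, function(t) sum(times >= t), numeric(1))
    nEvent <- vapply(tt, function(t) sum(times == t & events == 1),
                     numeric(1))
    nCens <- vapply(tt, function(t) sum(times == t & events == 0),
                    numeric(1))
    surv <- cumprod(1 - nEvent / nRisk)
    structure(data.frame(time = tt, n_risk = nRisk, n_event = nEvent,
                         n_censor = nCens, survival = surv),
              class = c("kmCurve", "data.frame"))
}

#' Survival probability of a Kaplan-Meier curve at time t
#' @param curve a `kmCurve` from [kmEstimate()].
#' @param t time point (same units as the curve).
#' @return S(t); 1 before the first observed time.
#' @export
survivalAt <- function(curve, t) {
    i <- findInterval(t, curve$time)
    ifelse(i == 0, 1, curve$survival[pmax(i, 1)])
}

#' Log-rank test for k survival groups
#'
#' Observed-minus-expected statistic with the multi-death hypergeometric
#' variance at each distinct event time; chi-squared with (k - 1) degrees of
#' freedom.
#'
#' @param times,events follow-up times and 0/1 indicators.
#' @param group group membership (factor or vector; >= 2 non-empty levels).
#' @return an object of class `htest` with `statistic` (chisq), `parameter`
#'   (df), `p.value`, and `observed`/`expected` per group.
#' @export
logrankTest <- function(times, events, group) {
    group <- factor(group)
    group <- droplevels(group)
    k <- nlevels(group)
    stopifnot(length(times) == length(events),
              length(times) == length(group))
    if (k < 2) stop("log-rank needs at least 2 non-empty groups")
    if (!any(events == 1))
        stop("log-rank undefined: no events observed")
    dtimes <- sort(unique(times[events == 1]))
    O <- E <- numeric(k)
    V <- matrix(0, k, k)
    for (t in dtimes) {
        atRisk <- times >= t
        nj <- sum(atRisk)
        nij <- vapply(levels(group),
                      function(g) sum(atRisk & group == g), numeric(1))
        dj <- sum(times == t & events == 1)
        dij <- vapply(levels(group),
                      function(g) sum(times == t & events == 1 & group == g),
                      numeric(1))
        O <- O + dij
        E <- E + dj * nij / nj
        if (nj > 1) {
            mult <- dj * (nj - dj) / (nj - 1)
            V <- V + mult * (diag(nij / nj, k) -
                             outer(nij, nij) / nj^2)
        }
    }
    idx <- seq_len(k - 1)
    ome <- (O - E)[idx]
    Vs <- V[idx, idx, drop = FALSE]
    chi2 <- tryCatch(drop(ome %*% solve(Vs, ome)),
                     error = function(e) {
                         # variance singular: pseudo-inverse
                         s <- svd(Vs)
                         pos <- s$d > max(s$d) * 1e-10
                         drop(ome %*% s$v[, pos, drop = FALSE] %*%
                              ((t(s$u[, pos, drop = FALSE]) %*% ome) /
                               s$d[pos]))
                     })
    structure(list(statistic = c(chisq = chi2),
                   parameter = c(df = k - 1),
                   p.value = pchisq(chi2, df = k - 1, lower.tail = FALSE),
                   observed = setNames(O, levels(group)),
                   expected = setNames(E, levels(group)),
                   method = "Log-rank test",
                   data.name = deparse(substitute(times))),
              class = "htest")
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric p for the table `[a b; c d]`. With
#' `alternative = "greater"` this is the enrichment tail
#' `P(X >= a)` given the margins — the one-sided overlap test used for
#' module cross-tabulation.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return an `htest` with the p-value and the observed odds configuration.
#' @examples
#' fisherExact2x2(10, 0, 0, 10)$p.value   # 1 / choose(20, 10)
#' @export
fisherExact2x2 <- function(a, b, c, d,
                           alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
    n <- a + b + c + d
    if (n == 0) {
        p <- 1
    } else {
        m1 <- a + b; m2 <- c + d; k <- a + c
        lo <- max(0, k - m2); hi <- min(m1, k)
        supp <- lo:hi
        dens <- dhyper(supp, m1, m2, k)
        p <- if (alternative == "greater") sum(dens[supp >= a])
             else sum(dens[dens <= dhyper(a, m1, m2, k) * (1 + 1e-7)])
        p <- min(1, p)
    }
    structure(list(statistic = c(overlap = a), p.value = p,
                   method = paste("Fisher exact test (", alternative, ")"),
                   data.name = sprintf("2x2 table [%d %d; %d %d]",
                                       a, b, c, d)),
              class = "htest")
}

#' McNemar test on discordant pair counts
#'
#' For `b + c >= 25`: continuity-corrected chi-squared
#' `(|b - c| - 1)^2 / (b + c)` on 1 df. For smaller discordant totals the
#' exact two-sided binomial p at rate 1/2 is used. `b + c = 0` gives p = 1.
#'
#' @param b,c discordant counts (A-right/B-wrong and A-wrong/B-right).
#' @return an `htest`.
#' @export
mcnemarTest <- function(b, c) {
    stopifnot(b >= 0, c >= 0)
    n <- b + c
    if (n == 0) {
        p <- 1; stat <- 0; method <- "McNemar test (no discordance)"
    } else if (n >= 25) {
        stat <- (abs(b - c) - 1)^2 / n
        p <- pchisq(stat, df = 1, lower.tail = FALSE)
        method <- "McNemar chi-squared test (continuity corrected)"
    } else {
        stat <- (abs(b - c) - 1)^2 / n
        p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
        if (b == c) p <- 1
        method <- "McNemar exact binomial test"
    }
    structure(list(statistic = c(chisq = stat), p.value = p,
                   method = method,
                   data.name = sprintf("discordant b = %d, c = %d", b, c)),
              class = "htest")
}

#' Principal component analysis of an expression submatrix
#'
#' Centered (optionally scaled) SVD-based PCA. Components are sign-fixed so
#' the largest-magnitude loading of each component is positive; variance
#' fractions are relative to total variance, hence sum to <= 1 when
#' truncated.
#'
#' @param x samples x genes numeric matrix.
#' @param nComponents number of components to keep.
#' @param scale. scale genes to unit variance (default FALSE: expression is
#'   assumed already normalized).
#' @return an `exprPCA` list: `loadings` (genes x comps, unit columns),
#'   `scores` (samples x comps), `varExplained` (fractions, descending).
#' @export
pcaExpression <- function(x, nComponents = 3, scale. = FALSE) {
    stopifnot(is.matrix(x), nComponents >= 1)
    rk <- min(nrow(x) - 1, ncol(x))
    if (nComponents > rk) {
        warning("nComponents exceeds rank; truncated to ", rk)
        nComponents <- rk
    }
    xc <- scale(x, center = TRUE, scale = scale.)
    s <- svd(xc, nu = nComponents, nv = nComponents)
    totVar <- sum(s$d^2)
    load <- s$v
    scores <- s$u %*% diag(s$d[seq_len(nComponents)], nComponents)
    for (j in seq_len(nComponents)) {
        if (load[which.max(abs(load[, j])), j] < 0) {
            load[, j] <- -load[, j]
            scores[, j] <- -scores[, j]
        }
    }
    dimnames(load) <- list(colnames(x), paste0("PC", seq_len(nComponents)))
    dimnames(scores) <- list(rownames(x), colnames(load))
    structure(list(loadings = load, scores = scores,
                   varExplained = s$d[seq_len(nComponents)]^2 / totVar),
              class = "exprPCA")
}
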