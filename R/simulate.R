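#' GroundTruth: planted structure behind a simulated multi-cancer dataset
#'
#' @slot moduleOf named character, gene -> module label or `"background"`.
#' @slot modulesPerCancer list: cancer -> labels of modules planted there.
#' @slot riskGenes planted risk genes.
#' @slot riskDirections named numeric, +1/-1 per risk gene (loading sign).
#' @slot riskScores list: cancer -> per-sample latent risk score.
#' @export
setClass("GroundTruth",
         representation(moduleOf = "character", modulesPerCancer = "list",
                        riskGenes = "character", riskDirections = "numeric",
                        riskScores = "list"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@moduleOf), "genes,",
        length(unique(object@moduleOf[object@moduleOf != "background"])),
        "planted modules,", length(object@riskGenes), "risk genes\n")
})

#' SimulationConfig: recipe for a synthetic multi-cancer study
#'
#' @slot cancers cohort labels.
#' @slot samplesPerCancer named integer, samples per cohort.
#' @slot nGenes total genes per cohort (shared gene universe).
#' @slot moduleSpecs list of module recipes: `name`, `size`,
#'   `cancers` (subset in which the module is planted),
#'   `cor` (expected pairwise within-module correlation, in (0,1)).
#' @slot riskSpec list: `genes` (planted risk genes), `logHazardPerUnit`,
#'   `baselineHazard` (events per day at score 0), `censoringRate` in \[0,1).
#' @slot seed integer master seed.
#' @slot mixedSigns if TRUE, module loadings are random +/-1 (exercises
#'   unsigned networks); default all +1.
#' @slot missingRate missing-at-random NA fraction; default 0.
#' @slot loadingSpread half-width of the per-gene hub-magnitude gradient.
#' @export
setClass("SimulationConfig",
         representation(cancers = "character",
                        samplesPerCancer = "integer", nGenes = "integer",
                        moduleSpecs = "list", riskSpec = "list",
                        seed = "integer", mixedSigns = "logical",
                        missingRate = "numeric",
                        loadingSpread = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    ms <- object@moduleSpecs
    sizes <- vapply(ms, function(m) m$size, numeric(1))
    if (sum(sizes) > object@nGenes)
        msg <- c(msg, "module sizes exceed n_genes")
    cors <- vapply(ms, function(m) m$cor, numeric(1))
    if (any(cors <= 0 | cors >= 1))
        msg <- c(msg, "within_correlation must lie strictly in (0,1)")
    for (m in ms)
        if (!all(m$cancers %in% object@cancers))
            msg <- c(msg, paste0("module '", m$name,
                                 "' names an unknown cancer"))
    rs <- object@riskSpec
    if (length(rs)) {
        if (rs$baselineHazard < 0)
            msg <- c(msg, "baseline hazard must be non-negative")
        if (rs$censoringRate < 0 || rs$censoringRate >= 1)
            msg <- c(msg, "censoring rate must lie in [0,1)")
    }
    if (length(object@samplesPerCancer) != length(object@cancers))
        msg <- c(msg, "one sample size per cancer required")
    if (length(msg)) msg else TRUE
})

#' Build a SimulationConfig
#'
#' Gene ids are assigned deterministically: module genes first, in
#' `moduleSpecs` order (`g0001`, `g0002`, ...), then background genes.
#' `riskGenes` therefore can be given either as explicit gene ids or via the
#' convenience `riskModule`/`nRiskGenes` pair (first `nRiskGenes` genes of
#' that module).
#'
#' @param cancers cohort labels.
#' @param samplesPerCancer integer vector (recycled if length 1).
#' @param moduleSpecs list of lists with `size`, `cancers`, `cor`
#'   (and optional `name`; defaults M1, M2, ...).
#' @param nBackgroundGenes independent-noise genes appended after modules.
#' @param riskGenes explicit risk-gene ids (overrides `riskModule`).
#' @param riskModule,nRiskGenes pick risk genes as the first `nRiskGenes`
#'   members of module `riskModule`.
#' @param logHazardPerUnit log hazard ratio per unit of latent risk score.
#' @param baselineHazard events per day at score 0.
#' @param censoringRate expected fraction censored, in \[0,1).
#' @param seed master seed; all randomness derives from it.
#' @param mixedSigns,missingRate see [SimulationConfig-class].
#' @param loadingSpread half-width of the per-gene hub-magnitude gradient
#'   (uniform on 1 +/- spread, shared across cohorts); 0 gives flat
#'   loadings. Default 0.25.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(cancers, samplesPerCancer, moduleSpecs,
                             nBackgroundGenes = 0L,
                             riskGenes = NULL, riskModule = NULL,
                             nRiskGenes = 0L,
                             logHazardPerUnit = 0,
                             baselineHazard = log(2) / 730,
                             censoringRate = 0.2,
                             seed = 1L, mixedSigns = FALSE,
                             missingRate = 0, loadingSpread = 0.25) {
    if (length(samplesPerCancer) == 1L)
        samplesPerCancer <- rep(samplesPerCancer, length(cancers))
    samplesPerCancer <- setNames(as.integer(samplesPerCancer), cancers)
    for (i in seq_along(moduleSpecs))
        if (is.null(moduleSpecs[[i]]$name))
            moduleSpecs[[i]]$name <- paste0("M", i)
    sizes <- vapply(moduleSpecs, function(m) m$size, numeric(1))
    nGenes <- as.integer(sum(sizes) + nBackgroundGenes)
    ids <- sprintf("g%04d", seq_len(nGenes))
    offs <- cumsum(c(0, sizes))
    names(offs) <- c(vapply(moduleSpecs, function(m) m$name, ""), "bg")
    if (is.null(riskGenes) && !is.null(riskModule)) {
        i <- match(riskModule, names(offs))
        if (is.na(i)) stop("unknown risk module '", riskModule, "'")
        riskGenes <- ids[offs[i] + seq_len(nRiskGenes)]
    }
    if (!is.null(riskGenes) && !all(riskGenes %in% ids))
        stop("risk genes outside the simulated gene universe")
    new("SimulationConfig", cancers = cancers,
        samplesPerCancer = samplesPerCancer, nGenes = nGenes,
        moduleSpecs = moduleSpecs,
        riskSpec = list(genes = as.character(riskGenes),
                        logHazardPerUnit = logHazardPerUnit,
                        baselineHazard = baselineHazard,
                        censoringRate = censoringRate),
        seed = as.integer(seed), mixedSigns = mixedSigns,
        missingRate = missingRate, loadingSpread = loadingSpread)
}

# loading magnitudes m_g = cap(sqrt(rho) * u_g) rescaled (iteratively, the
# cap re-applied) so the mean pairwise within-module correlation m_g * m_h
# equals rho exactly
.moduleLoadings <- function(rho, u) {
    m <- sqrt(rho) * u / mean(u)
    for (i in 1:25) {
        m <- pmin(m, 0.995)
        pp <- (sum(m)^2 - sum(m^2)) / (length(m) * (length(m) - 1))
        m <- m * sqrt(rho / pp)
    }
    pmin(m, 0.995)
}

# gene -> module map implied by a config (module genes first, then background)
.moduleMap <- function(config) {
    sizes <- vapply(config@moduleSpecs, function(m) m$size, numeric(1))
    ids <- sprintf("g%04d", seq_len(config@nGenes))
    moduleOf <- rep("background", config@nGenes)
    offs <- cumsum(c(0, sizes))
    for (i in seq_along(config@moduleSpecs))
        moduleOf[offs[i] + seq_len(sizes[i])] <- config@moduleSpecs[[i]]$name
    setNames(moduleOf, ids)
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", length(object@cancers), "cancers,",
        object@nGenes, "genes,", length(object@moduleSpecs),
        "planted modules, seed", object@seed, "\n")
})

#' Simulate a multi-cancer expression + survival study
#'
#' One latent factor per (module, cohort): for a module with target pairwise
#' correlation rho, gene g of the module gets
#' `x_g = sqrt(rho) * l_g * f + sqrt(1 - rho) * e` with `f`, `e` standard
#' normal and loading `l_g` in \{+1, -1\}, so every within-module pair has
#' `|cor| = rho` in expectation. Genes of modules not planted in a cohort,
#' and background genes, are independent standard normal. A per-gene baseline
#' (uniform on \[6, 12\], shared across cohorts) shifts values onto a
#' log2-intensity-like scale. The latent risk score of a sample is the mean
#' of `l_g * f_{module(g)}` over risk genes (for a background risk gene, its
#' own noise value), and drives exponential event times through a
#' proportional-hazards model (see [simulateSurvival()]).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `cohorts` (list of [CancerCohort-class] including
#'   survival) and `truth` (a [GroundTruth-class]).
#' @examples
#' cfg <- simulationConfig(c("A", "B"), 60,
#'     list(list(size = 20, cancers = c("A", "B"), cor = 0.8)),
#'     nBackgroundGenes = 30, seed = 1)
#' sim <- simulateMulticancer(cfg)
#' @export
simulateMulticancer <- function(config) {
    validObject(config)
    moduleOf <- .moduleMap(config)
    ids <- names(moduleOf)
    rs <- config@riskSpec
    withr::with_seed(config@seed, {
        base <- setNames(runif(config@nGenes, 6, 12), ids)
        loading <- setNames(rep(1, config@nGenes), ids)
        if (config@mixedSigns) {
            inMod <- moduleOf != "background"
            loading[inMod] <- sample(c(-1, 1), sum(inMod), replace = TRUE)
        }
        # per-gene hub magnitude, a gene property shared across cohorts:
        # gives modules the intramodular connectivity gradient real modules
        # have (flat loadings would leave connectivity statistics blind)
        hub <- setNames(runif(config@nGenes, 1 - config@loadingSpread,
                              1 + config@loadingSpread), ids)
        cohorts <- list(); scores <- list()
        for (cc in config@cancers) {
            n <- config@samplesPerCancer[[cc]]
            smp <- sprintf("%s_s%03d", cc, seq_len(n))
            x <- matrix(rnorm(config@nGenes * n), config@nGenes, n,
                        dimnames = list(ids, smp))
            factors <- list()
            for (m in config@moduleSpecs) {
                if (!cc %in% m$cancers) next
                f <- rnorm(n)
                factors[[m$name]] <- f
                g <- ids[moduleOf == m$name]
                mg <- .moduleLoadings(m$cor, hub[g])
                x[g, ] <- outer(loading[g] * mg, f) +
                    sqrt(1 - mg^2) * x[g, , drop = FALSE]
            }
            sc <- numeric(n)
            if (length(rs$genes)) {
                contrib <- vapply(rs$genes, function(g) {
                    m <- moduleOf[[g]]
                    if (m %in% names(factors)) loading[[g]] * factors[[m]]
                    else x[g, ]
                }, numeric(n))
                sc <- rowMeans(contrib)
            }
            x <- x + base
            if (config@missingRate > 0)
                x[runif(length(x)) < config@missingRate] <- NA
            surv <- simulateSurvival(setNames(sc, smp), rs,
                                     seed = NULL)
            cohorts[[cc]] <- CancerCohort(x, cc, survival = surv)
            scores[[cc]] <- setNames(sc, smp)
        }
        modulesPerCancer <- lapply(setNames(config@cancers, config@cancers),
            function(cc) vapply(Filter(function(m) cc %in% m$cancers,
                                       config@moduleSpecs),
                                function(m) m$name, ""))
        truth <- new("GroundTruth", moduleOf = moduleOf,
                     modulesPerCancer = modulesPerCancer,
                     riskGenes = rs$genes,
                     riskDirections = setNames(loading[rs$genes] *
                                               sign(rs$logHazardPerUnit +
                                                    (rs$logHazardPerUnit == 0)),
                                               rs$genes),
                     riskScores = scores)
        list(cohorts = cohorts, truth = truth)
    })
}

#' Simulate survival under a proportional-hazards model
#'
#' Event times are exponential with per-sample hazard
#' `baselineHazard * exp(logHazardPerUnit * score)`. Censoring times are
#' uniform on \[0, u\] with `u` solved numerically so that the expected
#' censored fraction, given the realized hazards, equals `censoringRate`;
#' the recorded time is the minimum and `event` indicates the event came
#' first. `censoringRate = 0` means complete follow-up.
#'
#' @param riskScores named numeric per-sample scores.
#' @param riskSpec list with `logHazardPerUnit`, `baselineHazard`,
#'   `censoringRate` (as in [simulationConfig()]).
#' @param seed integer seed, or NULL to draw from the current RNG state
#'   (used internally by [simulateMulticancer()]).
#' @return data.frame `sample_id`, `time_days`, `event`.
#' @export
simulateSurvival <- function(riskScores, riskSpec, seed = 1L) {
    stopifnot(all(is.finite(riskScores)))
    if (riskSpec$baselineHazard < 0) stop("baseline hazard must be >= 0")
    run <- function() {
        n <- length(riskScores)
        h <- riskSpec$baselineHazard *
            exp(riskSpec$logHazardPerUnit * riskScores)
        tt <- rexp(n, rate = pmax(h, 1e-12))
        ev <- rep(1L, n)
        q <- riskSpec$censoringRate
        if (q > 0) {
            # P(C < T | C ~ U(0,u)) per subject = (1 - exp(-h u)) / (h u),
            # decreasing in u; solve for the target censored fraction
            pcen <- function(u) mean((1 - exp(-h * u)) / (h * u)) - q
            u <- uniroot(pcen, lower = 1e-6 / mean(h), upper = 1e6 / mean(h),
                         extendInt = "downX", tol = 1e-10)$root
            cen <- runif(n, 0, u)
            ev <- as.integer(tt <= cen)
            tt <- pmin(tt, cen)
        }
        data.frame(sample_id = names(riskScores) %||%
                       sprintf("s%03d", seq_len(n)),
                   time_days = tt, event = ev, row.names = NULL)
    }
    if (is.null(seed)) run() else withr::with_seed(seed, run())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
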