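# shared fixture builders (everything generated in code, at test time)

# the study-condition multi-cancer simulation: 6 cohorts, 3 shared planted
# modules (one carrying the risk genes), background noise
studyConfig <- function(seed, nCancers = 6, n = 150) {
    cancers <- paste0("C", seq_len(nCancers))
    simulationConfig(
        cancers, n,
        list(list(size = 40, cancers = cancers, cor = 0.8),
             list(size = 40, cancers = cancers, cor = 0.7),
             list(size = 40, cancers = cancers, cor = 0.7)),
        nBackgroundGenes = 180,
        riskModule = "M1", nRiskGenes = 9,
        logHazardPerUnit = log(2.5),
        baselineHazard = log(2) / 730,
        censoringRate = 0.2,
        seed = seed)
}

# one-cohort simulation with a planted risk module driving survival
riskCohort <- function(seed, n = 400, logHR = log(2.5)) {
    cfg <- simulationConfig("A", n,
        list(list(size = 40, cancers = "A", cor = 0.8)),
        nBackgroundGenes = 160,
        riskModule = "M1", nRiskGenes = 9,
        logHazardPerUnit = logHR,
        baselineHazard = log(2) / 730,
        censoringRate = 0.2, seed = seed)
    simulateMulticancer(cfg)
}

# a matrix of two "genes" with an exact sample correlation r
exactCorPair <- function(r, n = 20) {
    u <- scale(rnorm(n))[, 1]
    v <- scale(residuals(lm(rnorm(n) ~ u)))[, 1]
    x <- rbind(u, r * u + sqrt(1 - r^2) * v)
    dimnames(x) <- list(c("gA", "gB"), paste0("s", seq_len(n)))
    x
}

# build a ModuleAssignment directly from a label vector
mkAssign <- function(labels, unassigned = "grey") {
    new("ModuleAssignment", labels = labels, unassigned = unassigned)
}

# adjusted Rand index between two labelings (restricted to shared names)
ariOf <- function(a, b) {
    g <- intersect(names(a), names(b))
    mclust::adjustedRandIndex(a[g], b[g])
}
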