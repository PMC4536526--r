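test_that("adjacency follows the soft-threshold transform", {
    set.seed(4)
    # perfectly correlated pair
    x <- exactCorPair(1 - 1e-12)
    net <- coexpressionNetwork(x, power = 6)
    expect_equal(net@adjacency["gA", "gB"], 1, tolerance = 1e-6)
    # exact sample correlation 0.5, beta 6, unsigned: 0.5^6
    x <- exactCorPair(0.5)
    net <- coexpressionNetwork(x, power = 6)
    expect_equal(net@adjacency["gA", "gB"], 0.015625, tolerance = 1e-10)
    # signed mode
    nets <- coexpressionNetwork(x, power = 2, mode = "signed")
    expect_equal(nets@adjacency["gA", "gB"], 0.75^2, tolerance = 1e-10)
    expect_true(isSymmetric(net@adjacency))
    expect_equal(unname(diag(net@adjacency)), c(1, 1))
})

test_that("mean connectivity is non-increasing in the power", {
    set.seed(9)
    x <- matrix(rnorm(50 * 30), 50, 30,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    k1 <- mean(connectivity(coexpressionNetwork(x, power = 1)))
    k6 <- mean(connectivity(coexpressionNetwork(x, power = 6)))
    expect_gte(k1, k6)
})

test_that("constant genes are dropped with a warning", {
    set.seed(2)
    x <- rbind(matrix(rnorm(5 * 20), 5, 20), 0)
    rownames(x) <- paste0("g", 1:6)
    expect_warning(net <- coexpressionNetwork(x, power = 2), "constant")
    expect_equal(nrow(net@adjacency), 5)
})

test_that("soft-threshold selection finds a scale-free power on planted data", {
    cfg <- simulationConfig("A", 50,
        list(list(size = 10, cancers = "A", cor = 0.7),
             list(size = 10, cancers = "A", cor = 0.7),
             list(size = 10, cancers = "A", cor = 0.7)),
        nBackgroundGenes = 100, seed = 7)
    sim <- simulateMulticancer(cfg)
    st <- pickSoftThreshold(sim$cohorts$A, candidatePowers = 1:12)
    expect_true(any(st$fitTable$rsq >= 0.8, na.rm = TRUE))
    expect_equal(st$power,
                 st$fitTable$power[which(st$fitTable$rsq >= 0.8)[1]])
    expect_equal(nrow(st$fitTable), 12)
})

test_that("degenerate two-gene input falls back with a warning", {
    set.seed(1)
    x <- matrix(rnorm(2 * 30), 2, 30, dimnames = list(c("a", "b"), NULL))
    expect_warning(st <- pickSoftThreshold(x), "fall")
    expect_true(st$power %in% st$fitTable$power)
})

test_that("TOM matches its defining formula", {
    mkNet <- function(a) new("CoexpressionNetwork", cohort = "t", power = 1,
                             mode = "unsigned", adjacency = a,
                             tom = matrix(numeric(0), 0, 0))
    ones <- matrix(1, 3, 3, dimnames = rep(list(letters[1:3]), 2))
    expect_true(all(tomMatrix(tomSimilarity(mkNet(ones))) == 1))
    eye <- diag(3); dimnames(eye) <- rep(list(letters[1:3]), 2)
    tomI <- tomMatrix(tomSimilarity(mkNet(eye)))
    expect_true(all(tomI[upper.tri(tomI)] == 0))
    # hand-evaluated 3-node case: a12 = 0.5, a13 = a23 = 0.8
    a <- matrix(c(1, .5, .8, .5, 1, .8, .8, .8, 1), 3,
                dimnames = rep(list(letters[1:3]), 2))
    tom <- tomMatrix(tomSimilarity(mkNet(a)))
    # k1 = k2 = 1.3; TOM12 = (0.8*0.8 + 0.5) / (1.3 + 1 - 0.5)
    expect_equal(tom["a", "b"], (0.64 + 0.5) / 1.8, tolerance = 1e-12)
    # k3 = 1.6; TOM13 = (0.5*0.8 + 0.8) / (min(1.3,1.6) + 1 - 0.8)
    expect_equal(tom["a", "c"], 1.2 / 1.5, tolerance = 1e-12)
    expect_true(all(diag(tom) == 1))
    expect_true(all(tom >= 0 & tom <= 1))
})

test_that("planted blocks are detected and noise stays unassigned", {
    cfg <- simulationConfig("A", 120,
        list(list(size = 30, cancers = "A", cor = 0.8),
             list(size = 30, cancers = "A", cor = 0.8)),
        nBackgroundGenes = 20, seed = 3)
    sim <- simulateMulticancer(cfg)
    net <- tomSimilarity(coexpressionNetwork(sim$cohorts$A, power = 6))
    ma <- detectModules(net, minModuleSize = 10)
    expect_length(moduleNames(ma), 2)
    lab <- moduleLabels(ma)
    assigned <- lab[lab != "grey"]
    expect_gte(ariOf(assigned, sim$truth@moduleOf[names(assigned)]), 0.9)
})

test_that("pure noise yields zero named modules", {
    set.seed(12)
    x <- matrix(rnorm(80 * 100), 80, 100,
                dimnames = list(sprintf("g%02d", 1:80), NULL))
    ma <- detectModules(tomSimilarity(coexpressionNetwork(x, power = 6)),
                        minModuleSize = 30)
    expect_length(moduleNames(ma), 0)
    expect_true(all(moduleLabels(ma) == "grey"))
})

test_that("a single block covering all genes forms one module", {
    cfg <- simulationConfig("A", 100,
        list(list(size = 40, cancers = "A", cor = 0.8)), seed = 8)
    sim <- simulateMulticancer(cfg)
    ma <- detectModules(
        tomSimilarity(coexpressionNetwork(sim$cohorts$A, power = 6)),
        minModuleSize = 10)
    expect_length(moduleNames(ma), 1)
    expect_equal(unname(moduleSizes(ma)[1]), 40L)
})

test_that("module labels are equivariant under gene permutation", {
    cfg <- simulationConfig("A", 100,
        list(list(size = 20, cancers = "A", cor = 0.8),
             list(size = 20, cancers = "A", cor = 0.7)),
        nBackgroundGenes = 30, seed = 6)
    sim <- simulateMulticancer(cfg)
    x <- exprsMatrix(sim$cohorts$A)
    ma1 <- detectModules(tomSimilarity(coexpressionNetwork(x, power = 6)),
                         minModuleSize = 10)
    set.seed(99)
    xp <- x[sample(nrow(x)), ]
    ma2 <- detectModules(tomSimilarity(coexpressionNetwork(xp, power = 6)),
                         minModuleSize = 10)
    g <- sort(rownames(x))
    expect_identical(moduleLabels(ma1)[g], moduleLabels(ma2)[g])
})

test_that("detected module count matches planted count at cor >= 0.6", {
    for (rho in c(0.6, 0.9)) {
        cfg <- simulationConfig("A", 100,
            list(list(size = 35, cancers = "A", cor = rho),
                 list(size = 32, cancers = "A", cor = rho),
                 list(size = 30, cancers = "A", cor = rho)),
            nBackgroundGenes = 60, seed = round(100 * rho))
        sim <- simulateMulticancer(cfg)
        ma <- detectModules(
            tomSimilarity(coexpressionNetwork(sim$cohorts$A, power = 6)),
            minModuleSize = 30)
        expect_length(moduleNames(ma), 3)
    }
})
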