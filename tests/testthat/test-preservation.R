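test_that("preservation classes follow the Zsummary/medianRank thresholds", {
    expect_equal(classifyPreservation(12, 3), "strong")
    expect_equal(classifyPreservation(5, 4), "moderate")
    expect_equal(classifyPreservation(1, 20), "none")
    # boundaries fall to the lower class; high medianRank blocks both
    expect_equal(classifyPreservation(10, 5), "moderate")
    expect_equal(classifyPreservation(2, 5), "none")
    expect_equal(classifyPreservation(15, 12), "none")
    expect_equal(classifyPreservation(Inf, 1), "strong")
})

test_that("percent preservation is the exact ratio, to two decimals", {
    expect_identical(percentPreservation(5, 10), 50)
    expect_identical(percentPreservation(5, 11), 45.45)
    expect_identical(percentPreservation(0, 7), 0)
    expect_error(percentPreservation(1, 0))
    expect_error(percentPreservation(5, 4))
})

test_that("a module planted in both cohorts scores Zsummary above 10", {
    cfg <- simulationConfig(c("A", "B"), 200,
        list(list(size = 50, cancers = c("A", "B"), cor = 0.8)),
        nBackgroundGenes = 150, seed = 11)
    sim <- simulateMulticancer(cfg)
    mg <- names(sim$truth@moduleOf)[sim$truth@moduleOf == "M1"]
    lab <- setNames(rep("grey", 200), names(sim$truth@moduleOf))
    lab[mg] <- "M1"
    r <- modulePreservation(mkAssign(lab), sim$cohorts$A, sim$cohorts$B,
                            nPerm = 100, seed = 11)
    st <- preservationStats(r)
    expect_gt(st$Zsummary, 10)
    expect_equal(st$medianRank, 1)   # single evaluated module
    expect_equal(st$class, "strong")
})

test_that("random gene sets score near the null", {
    cfg <- simulationConfig(c("A", "B"), 150,
        list(list(size = 30, cancers = c("A", "B"), cor = 0.7)),
        nBackgroundGenes = 170, seed = 21)
    sim <- simulateMulticancer(cfg)
    ids <- names(sim$truth@moduleOf)
    lab <- setNames(rep("grey", length(ids)), ids)
    withr::with_seed(77, for (j in 1:10) lab[sample(ids, 50)] <-
                             paste0("R", j))
    r <- modulePreservation(mkAssign(lab), sim$cohorts$A, sim$cohorts$B,
                            nPerm = 100, seed = 5)
    z <- preservationStats(r)$Zsummary
    expect_gte(mean(abs(z) < 2), 0.9)
})

test_that("tiny modules are skipped with a warning", {
    cfg <- simulationConfig(c("A", "B"), 60,
        list(list(size = 20, cancers = c("A", "B"), cor = 0.7)),
        nBackgroundGenes = 40, seed = 2)
    sim <- simulateMulticancer(cfg)
    ids <- names(sim$truth@moduleOf)
    lab <- setNames(rep("grey", length(ids)), ids)
    lab[ids[1:20]] <- "M1"
    lab[ids[21:22]] <- "tiny"
    expect_warning(
        r <- modulePreservation(mkAssign(lab), sim$cohorts$A,
                                sim$cohorts$B, nPerm = 50, seed = 1),
        "skipped")
    expect_equal(preservationStats(r)$module, "M1")
})

test_that("Z statistics are invariant to gene and sample order", {
    cfg <- simulationConfig(c("A", "B"), 80,
        list(list(size = 25, cancers = c("A", "B"), cor = 0.8)),
        nBackgroundGenes = 75, seed = 31)
    sim <- simulateMulticancer(cfg)
    ids <- names(sim$truth@moduleOf)
    lab <- setNames(rep("grey", length(ids)), ids)
    lab[ids[1:25]] <- "M1"
    a <- mkAssign(lab)
    xt <- exprsMatrix(sim$cohorts$B)
    r1 <- modulePreservation(a, sim$cohorts$A, xt, nPerm = 50, seed = 3)
    withr::with_seed(8, {
        xp <- xt[sample(nrow(xt)), sample(ncol(xt))]
    })
    r2 <- modulePreservation(a, sim$cohorts$A, xp, nPerm = 50, seed = 3)
    expect_equal(preservationStats(r1)$Zsummary,
                 preservationStats(r2)$Zsummary, tolerance = 1e-12)
})

test_that("median Zsummary of a planted module grows with its correlation", {
    med <- vapply(c(0.3, 0.5, 0.7, 0.9), function(rho) {
        zs <- vapply(1:3, function(s) {
            cfg <- simulationConfig(c("A", "B"), 100,
                list(list(size = 30, cancers = c("A", "B"), cor = rho)),
                nBackgroundGenes = 70, seed = 1000 + s)
            sim <- simulateMulticancer(cfg)
            ids <- names(sim$truth@moduleOf)
            lab <- setNames(rep("grey", length(ids)), ids)
            lab[ids[1:30]] <- "M1"
            preservationStats(
                modulePreservation(mkAssign(lab), sim$cohorts$A,
                                   sim$cohorts$B, nPerm = 50,
                                   seed = s))$Zsummary
        }, numeric(1))
        median(zs)
    }, numeric(1))
    expect_true(all(diff(med) >= 0))
})

test_that("the preservation matrix separates shared from disjoint structure", {
    # two cohorts sharing all planted modules: off-diagonal at 100
    cancers <- c("A", "B")
    cfg <- simulationConfig(cancers, 120,
        list(list(size = 35, cancers = cancers, cor = 0.8),
             list(size = 35, cancers = cancers, cor = 0.7)),
        nBackgroundGenes = 80, seed = 41)
    sim <- simulateMulticancer(cfg)
    assigns <- lapply(sim$cohorts, function(cc)
        detectModules(tomSimilarity(coexpressionNetwork(cc, power = 6)),
                      minModuleSize = 30))
    pm <- preservationMatrix(sim$cohorts, assigns, nPerm = 50, seed = 2)
    expect_equal(unname(diag(percentMatrix(pm))), c(100, 100))
    expect_equal(unname(percentMatrix(pm)["A", "B"]), 100)
    expect_equal(unname(percentMatrix(pm)["B", "A"]), 100)

    # disjoint planted structure: off-diagonal at 0
    cfg2 <- simulationConfig(cancers, 120,
        list(list(size = 35, cancers = "A", cor = 0.8),
             list(size = 35, cancers = "B", cor = 0.8)),
        nBackgroundGenes = 80, seed = 43)
    sim2 <- simulateMulticancer(cfg2)
    assigns2 <- lapply(sim2$cohorts, function(cc)
        detectModules(tomSimilarity(coexpressionNetwork(cc, power = 6)),
                      minModuleSize = 30))
    pm2 <- preservationMatrix(sim2$cohorts, assigns2, nPerm = 50, seed = 2)
    expect_equal(unname(percentMatrix(pm2)["A", "B"]), 0)
    expect_equal(unname(percentMatrix(pm2)["B", "A"]), 0)
})
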