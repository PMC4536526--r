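test_that("planted risk genes are detected with the hazardous direction", {
    sim <- riskCohort(101, n = 200)
    universe <- names(sim$truth@moduleOf)[sim$truth@moduleOf == "M1"]
    rt <- identifyRiskGenes(sim$cohorts$A, genes = universe,
                            pThreshold = 0.01)
    found <- intersect(sim$truth@riskGenes, rt$gene)
    expect_gte(length(found), 8)
    expect_true(all(rt$direction[rt$gene %in% found] == 1L))
})

test_that("null genes are flagged at roughly the nominal rate", {
    cfg <- simulationConfig("A", 200, list(), nBackgroundGenes = 300,
                            logHazardPerUnit = 0,
                            baselineHazard = log(2) / 730,
                            censoringRate = 0.2, seed = 103)
    sim <- simulateMulticancer(cfg)
    rt <- identifyRiskGenes(sim$cohorts$A, pThreshold = 0.05)
    expect_equal(nrow(rt) / 300, 0.05, tolerance = 0.05)
})

test_that("constant genes are skipped and rescaling changes nothing", {
    sim <- riskCohort(107, n = 150)
    x <- exprsMatrix(sim$cohorts$A)
    x["g0001", ] <- 5
    cc <- CancerCohort(x, "A", survival = survivalTable(sim$cohorts$A))
    expect_message(rt <- identifyRiskGenes(cc, genes = c("g0001", "g0002"),
                                           pThreshold = 1), "skipped")
    expect_false("g0001" %in% rt$gene)
    # affine rescaling of a gene leaves p and direction untouched
    x2 <- exprsMatrix(sim$cohorts$A)
    x2["g0002", ] <- 3.7 * x2["g0002", ] + 12
    cc2 <- CancerCohort(x2, "A", survival = survivalTable(sim$cohorts$A))
    r1 <- identifyRiskGenes(sim$cohorts$A, genes = "g0002", pThreshold = 1)
    r2 <- identifyRiskGenes(cc2, genes = "g0002", pThreshold = 1)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
    expect_equal(r1$direction, r2$direction)
})

test_that("common risk genes honour the outlier allowance", {
    lists <- list(A = c("g1", "g2", "g3"), B = c("g1", "g2", "g3"),
                  C = c("g1", "g2", "g4"))
    expect_identical(commonRiskGenes(lists), c("g1", "g2"))
    # a gene may miss one (deviant) cohort; singletons stay out
    expect_identical(commonRiskGenes(lists, allowedOutliers = 1),
                     c("g1", "g2", "g3"))
    same <- list(A = c("g1", "g2"), B = c("g1", "g2"))
    expect_identical(commonRiskGenes(same), c("g1", "g2"))
})

test_that("actual risk labels follow the per-cancer horizon rule", {
    surv <- data.frame(sample_id = c("a", "b", "c"),
                       time_days = c(2 * 365.25, 4 * 365.25, 0.5 * 365.25),
                       event = c(1L, 0L, 0L))
    # 3-year horizon: death at 2y is high risk
    expect_equal(assignActualRisk(surv, 3)$actual[1], "high")
    # 1-year horizon: alive at 4y is low risk
    expect_equal(assignActualRisk(surv, 1)$actual[2], "low")
    # 2-year horizon: censored at 0.5y is indeterminate
    expect_equal(assignActualRisk(surv, 2)$actual[3], "indeterminate")
    expect_error(assignActualRisk(transform(surv, time_days = -1), 2),
                 "negative")
})

test_that("risk prediction uses majority vote with a conservative tie", {
    x <- matrix(c(10, 1, 1, 10,
                  10, 1, 1, 10,
                  10, 1, 10, 1,
                  10, 1, 10, 1), 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
    pan <- data.frame(gene = paste0("g", 1:4), direction = 1L)
    pred <- predictRisk(x, pan)
    # s1: all four above their medians? medians are (5.5,...) per gene row
    expect_equal(pred$predicted, c("high", "low", "low", "low"))
    expect_equal(pred$n_risky, c(4, 0, 2, 2))
    # panel gene order must not matter
    pred2 <- predictRisk(x, pan[4:1, ])
    expect_equal(pred2$predicted, pred$predicted)
    # direction -1 flips the risky side
    predNeg <- predictRisk(x, data.frame(gene = "g1", direction = -1L))
    expect_equal(predNeg$predicted, c("low", "high", "high", "low"))
    expect_error(predictRisk(x, data.frame(gene = "zz", direction = 1L)))
})

test_that("confusion summaries apply the stated formulas", {
    pred <- data.frame(sample_id = paste0("s", 1:8),
                       predicted = c("high", "high", "high", "low",
                                     "high", "low", "low", "low"))
    act <- data.frame(sample_id = paste0("s", 1:8),
                      actual = c("high", "high", "high", "high",
                                 "low", "low", "low", "indeterminate"))
    ev <- evaluatePrediction(pred, act)
    expect_equal(ev$TP, 3); expect_equal(ev$FN, 1)
    expect_equal(ev$FP, 1); expect_equal(ev$TN, 2)
    expect_equal(ev$sensitivity, 0.75)
    expect_equal(ev$specificity, 2 / 3)
    expect_equal(ev$nIndeterminate, 1)
    # perfect prediction
    evp <- evaluatePrediction(
        data.frame(sample_id = c("a", "b"), predicted = c("high", "low")),
        data.frame(sample_id = c("a", "b"), actual = c("high", "low")))
    expect_equal(evp$sensitivity, 1); expect_equal(evp$specificity, 1)
    # no actual positives: sensitivity undefined, not zero
    ev0 <- evaluatePrediction(
        data.frame(sample_id = "a", predicted = "low"),
        data.frame(sample_id = "a", actual = "low"))
    expect_true(is.na(ev0$sensitivity))
})

test_that("signature comparison reduces to McNemar on discordance", {
    act <- data.frame(sample_id = paste0("s", 1:40),
                      actual = rep(c("high", "low"), 20))
    predA <- data.frame(sample_id = act$sample_id, predicted = act$actual)
    expect_equal(compareSignatures(predA, predA, act)$p.value, 1)
    # A correct where B wrong on 20, reverse on 5
    correct <- act$actual
    wrong <- ifelse(correct == "high", "low", "high")
    predB <- predA; predB$predicted[1:20] <- wrong[1:20]
    predA2 <- predA; predA2$predicted[21:25] <- wrong[21:25]
    cmp <- compareSignatures(predA, predB, act)   # b=20, c=0
    cmp2 <- compareSignatures(predA2, predB, act) # b=20, c=5
    expect_equal(unname(cmp2$statistic), 7.84)
    # both always wrong: no discordance
    allWrong <- transform(predA, predicted = wrong)
    expect_equal(compareSignatures(allWrong, allWrong, act)$p.value, 1)
})

test_that("panel assembly follows the composition rules and deduplicates", {
    s1 <- data.frame(gene = paste0("c1_", 1:6), direction = 1L)
    s2 <- data.frame(gene = paste0("c2_", 1:3), direction = 1L)
    ind <- function(g) data.frame(gene = g, p = seq_along(g) / 1000,
                                  direction = 1L)
    rules <- c(GBM = "common-set1", BRCA = "common-set2",
               OVCA = "common-set2", READ = "combined",
               COAD = "common+individual", LUAD = "common+individual")
    pan <- assemblePanel(s1, s2,
        individual = list(COAD = ind(paste0("coad_", 1:5)),
                          LUAD = ind(paste0("luad_", 1:5))),
        rules = rules, nIndividual = 3)
    expect_length(panelUnion(pan), 15)
    expect_equal(nrow(panelGenes(pan, "READ")), 9)
    expect_equal(nrow(panelGenes(pan, "COAD")), 9)
    # individual genes overlapping the common list are not double counted
    expect_warning(
        pan2 <- assemblePanel(s1, s2,
            individual = list(COAD = ind(c(paste0("c1_", 1:2), "x1", "x2"))),
            rules = c(COAD = "common+individual"), nIndividual = 3),
        "individual")
    expect_equal(nrow(panelGenes(pan2, "COAD")), 8)   # 6 common + x1, x2
    expect_lt(length(panelUnion(pan2)), 6 + 4)
    expect_warning(emptyPan <- assemblePanel(NULL, NULL,
        rules = c(A = "common-set1")), "empty")
    expect_length(panelUnion(emptyPan), 0)
})

test_that("a planted panel beats a size-matched random panel", {
    margins <- vapply(1:7, function(s) {
        sim <- riskCohort(300 + s, n = 300)
        truth <- sim$truth
        pan <- data.frame(gene = truth@riskGenes, direction = 1L)
        bg <- names(truth@moduleOf)[truth@moduleOf == "background"]
        rnd <- data.frame(gene = bg[seq_along(truth@riskGenes)],
                          direction = 1L)
        act <- assignActualRisk(survivalTable(sim$cohorts$A), 2)
        sc <- function(p) {
            ev <- evaluatePrediction(predictRisk(sim$cohorts$A, p), act)
            mean(c(ev$sensitivity, ev$specificity), na.rm = TRUE)
        }
        sc(pan) - sc(rnd)
    }, numeric(1))
    expect_gte(median(margins), 0.15)
})
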