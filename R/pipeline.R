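.pipelineDefaults <- list(
    seed = 1L,
    network = list(power = "auto", mode = "unsigned",
                   min_module_size = 30, cut_height = "auto"),
    preservation = list(n_perm = 200, required_class = "strong",
                        overlap_p = 0.05),
    hubs = list(edge_threshold = 0.02, min_degree = 10),
    risk = list(p_threshold = 0.01, threshold_years = 2,
                allowed_outliers = 0),
    panel = list(n_individual = 3),
    resample = list(n_rd = 100, rd_size = NULL, alpha = 0.05)
)

# deep-merge user config over defaults
.mergeConfig <- function(cfg) {
    out <- .pipelineDefaults
    for (k in names(cfg)) {
        out[[k]] <- if (is.list(out[[k]]) && is.list(cfg[[k]]))
            modifyList(out[[k]], cfg[[k]]) else cfg[[k]]
    }
    out
}

#' Run the full conserved-module / risk-panel pipeline
#'
#' Stages, in dependency order: (1) simulate or ingest cohorts; (2) build a
#' co-expression network and detect modules per cohort; (3) pairwise module
#' preservation matrix; (4) conserved gene-set extraction; (5) interaction
#' networks, hubs and common classifiers; (6) classifier-based sample
#' stratification with survival association; (7) per-cancer risk genes and
#' common risk genes; (8) panel assembly, risk prediction and
#' sensitivity/specificity; (9) resampling revalidation. Every output file
#' is recorded with its md5 checksum in `manifest.json`; stages that cannot
#' run (e.g. preservation with a single cohort) are skipped with a recorded
#' warning.
#'
#' @param config path to a YAML configuration, or an equivalent named list.
#'   Must contain either a `simulation` block (see
#'   [simulationConfig()]; keys `cancers`, `samples_per_cancer`, `modules`,
#'   `n_background_genes`, `risk`) or a `cohorts` list of
#'   `{name, expr, survival}` TSV paths. All thresholds live in the blocks
#'   `network`, `preservation`, `hubs`, `risk`, `panel`, `resample` and
#'   default as in the package documentation.
#' @param outDir output directory (created); defaults to `output_dir` in
#'   the config.
#' @return the manifest (invisibly also written to
#'   `file.path(outDir, "manifest.json")`).
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config)) config <- read_yaml(config)
    cfg <- .mergeConfig(config)
    outDir <- outDir %||% cfg$output_dir %||% stop("no output directory")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(cfg$seed)
    manifest <- list(seed = seed, stages = list())
    files <- character()
    note <- function(stage, t0, outputs, warnings = character()) {
        manifest$stages[[stage]] <<- list(
            seconds = round(as.numeric(Sys.time()) - t0, 2),
            outputs = outputs, warnings = warnings)
        files <<- c(files, outputs)
    }

    ## 1. cohorts ------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    truth <- NULL
    if (!is.null(cfg$simulation)) {
        s <- cfg$simulation
        mods <- lapply(s$modules, function(m)
            list(size = m$size, cancers = as.character(m$cancers),
                 cor = m$cor, name = m$name %||% NULL))
        r <- s$risk %||% list()
        scfg <- simulationConfig(
            cancers = as.character(s$cancers),
            samplesPerCancer = unlist(s$samples_per_cancer),
            moduleSpecs = mods,
            nBackgroundGenes = s$n_background_genes %||% 0L,
            riskModule = r$module %||% NULL,
            nRiskGenes = r$n_genes %||% 0L,
            logHazardPerUnit = r$log_hazard_per_unit %||% 0,
            baselineHazard = r$baseline_hazard %||% (log(2) / 730),
            censoringRate = r$censoring_rate %||% 0.2,
            seed = seed)
        sim <- simulateMulticancer(scfg)
        cohorts <- sim$cohorts
        truth <- sim$truth
        out <- character()
        for (cc in names(cohorts)) {
            pe <- file.path(outDir, paste0(cc, "_expr.tsv"))
            ps <- file.path(outDir, paste0(cc, "_survival.tsv"))
            writeExpressionTSV(cohorts[[cc]], pe)
            writeSurvivalTSV(survivalTable(cohorts[[cc]]), ps)
            out <- c(out, pe, ps)
        }
        pg <- file.path(outDir, "ground_truth.json")
        write_json(list(module_of = as.list(truth@moduleOf),
                        risk_genes = truth@riskGenes),
                   pg, auto_unbox = TRUE)
        note("cohorts", t0, c(out, pg))
    } else if (!is.null(cfg$cohorts)) {
        cohorts <- list()
        for (co in cfg$cohorts)
            cohorts[[co$name]] <- readCohort(co$expr, co$name,
                                             survPath = co$survival %||% NULL)
        note("cohorts", t0, character())
    } else stop("config needs a 'simulation' or 'cohorts' block")

    ## 2. networks and modules -----------------------------------------
    t0 <- as.numeric(Sys.time())
    nets <- list(); assigns <- list(); out <- character()
    for (cc in names(cohorts)) {
        pw <- cfg$network$power
        if (identical(pw, "auto"))
            pw <- pickSoftThreshold(cohorts[[cc]],
                                    mode = cfg$network$mode)$power
        net <- tomSimilarity(coexpressionNetwork(cohorts[[cc]], power = pw,
                                                 mode = cfg$network$mode))
        assigns[[cc]] <- detectModules(net,
            minModuleSize = cfg$network$min_module_size,
            cutHeight = cfg$network$cut_height)
        nets[[cc]] <- net
        p <- file.path(outDir, paste0(cc, "_modules.tsv"))
        writeModuleTSV(assigns[[cc]], p)
        out <- c(out, p)
    }
    note("modules", t0, out)

    ## 3. preservation --------------------------------------------------
    t0 <- as.numeric(Sys.time())
    presults <- list(); sets <- list()
    if (length(cohorts) < 2) {
        note("preservation", t0, character(),
             "single cohort: preservation skipped")
        warning("single cohort: preservation stage skipped")
    } else {
        pm <- preservationMatrix(cohorts, assigns,
                                 nPerm = cfg$preservation$n_perm,
                                 seed = seed + 1000)
        presults <- pm@results
        p1 <- file.path(outDir, "preservation_matrix.tsv")
        write.table(percentMatrix(pm), p1, sep = "\t", quote = FALSE)
        p2 <- file.path(outDir, "preservation_pairs.tsv")
        allst <- do.call(rbind, lapply(names(presults), function(k) {
            r <- presults[[k]]
            cbind(ref = r@refCohort, test = r@testCohort,
                  preservationStats(r))
        }))
        write.table(allst, p2, sep = "\t", quote = FALSE, row.names = FALSE)
        note("preservation", t0, c(p1, p2))

        ## 4. conserved sets -------------------------------------------
        t0 <- as.numeric(Sys.time())
        sets <- extractConservedSets(names(cohorts), presults, assigns,
            pThreshold = cfg$preservation$overlap_p,
            requiredClass = cfg$preservation$required_class)
        p <- file.path(outDir, "conserved_sets.gmt")
        writeGMT(sets, p)
        note("conserved_sets", t0,
             p, if (!length(sets)) "no conserved sets found")
    }

    ## 5. hubs and classifiers ------------------------------------------
    t0 <- as.numeric(Sys.time())
    classifiers <- list(); out <- character()
    if (length(sets)) {
        allSetGenes <- sort(unique(unlist(lapply(sets, function(s) s@genes))))
        hubSets <- list()
        for (cc in names(cohorts)) {
            gn <- interactionNetwork(nets[[cc]], allSetGenes,
                edgeThreshold = cfg$hubs$edge_threshold)
            hubs <- findHubs(gn, minDegree = cfg$hubs$min_degree)
            hubSets[[cc]] <- hubs
            p <- file.path(outDir, paste0(cc, "_hubs.tsv"))
            write.table(data.frame(gene = hubs,
                                   degree = attr(hubs, "degree")),
                        p, sep = "\t", quote = FALSE, row.names = FALSE)
            out <- c(out, p)
        }
        src <- lapply(setNames(sets, vapply(sets, function(s) s@name, "")),
                      function(s) s@genes)
        classifiers <- commonClassifiers(hubSets, sourceSets = src)
        p <- file.path(outDir, "classifiers.gmt")
        writeGMT(classifiers, p)
        out <- c(out, p)
    }
    note("classifiers", t0, out,
         if (!length(classifiers)) "no classifiers (no conserved sets)"
         else character())

    ## 6. stratification ------------------------------------------------
    t0 <- as.numeric(Sys.time())
    out <- character()
    cl1 <- classifiers[["Set1"]] %||% character()
    cl2 <- classifiers[["Set2"]] %||% character()
    if (length(cl1)) {
        for (cc in names(cohorts)) {
            s1 <- setScore(cohorts[[cc]], cl1)
            cls <- if (length(cl2))
                classifySamples(s1, setScore(cohorts[[cc]], cl2))
                else classifySamples(s1)
            p <- file.path(outDir, paste0(cc, "_classes.tsv"))
            write.table(cls, p, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            out <- c(out, p)
            cs <- tryCatch(classSurvival(cls, survivalTable(cohorts[[cc]])),
                           error = function(e) NULL)
            if (!is.null(cs) && !is.null(cs$overall)) {
                pj <- file.path(outDir, paste0(cc, "_class_survival.json"))
                write_json(list(chisq = unname(cs$overall$statistic),
                                p = cs$overall$p.value,
                                n = as.list(cs$n)),
                           pj, auto_unbox = TRUE, digits = NA)
                out <- c(out, pj)
            }
        }
    }
    note("stratify", t0, out,
         if (!length(cl1)) "no Set1 classifiers; stratification skipped"
         else character())

    ## 7. risk genes ----------------------------------------------------
    t0 <- as.numeric(Sys.time())
    riskTabs <- list(); out <- character()
    universe <- if (length(sets))
        sort(unique(unlist(lapply(sets, function(s) s@genes)))) else NULL
    hasSurv <- vapply(cohorts, function(x)
        "time_days" %in% colnames(colData(x)), logical(1))
    for (cc in names(cohorts)[hasSurv]) {
        rt <- identifyRiskGenes(cohorts[[cc]], genes = universe,
                                pThreshold = cfg$risk$p_threshold)
        riskTabs[[cc]] <- rt
        p <- file.path(outDir, paste0(cc, "_risk_genes.tsv"))
        write.table(rt, p, sep = "\t", quote = FALSE, row.names = FALSE)
        out <- c(out, p)
    }
    common <- if (length(riskTabs) >= 2)
        commonRiskGenes(riskTabs,
                        allowedOutliers = cfg$risk$allowed_outliers)
        else character()
    pc <- file.path(outDir, "common_risk_genes.txt")
    writeLines(common, pc)
    note("risk_genes", t0, c(out, pc))

    ## 8. panel + evaluation -------------------------------------------
    t0 <- as.numeric(Sys.time())
    out <- character(); panel <- NULL
    if (length(common)) {
        dirTab <- do.call(rbind, riskTabs)
        dirTab <- dirTab[dirTab$gene %in% common, ]
        direction <- vapply(split(dirTab$direction, dirTab$gene),
                            function(d) if (mean(d) >= 0) 1L else -1L, 0L)
        commonTab <- data.frame(gene = names(direction),
                                direction = unname(direction))
        rules <- cfg$panel$rules %||%
            setNames(rep("common-set1", length(cohorts)), names(cohorts))
        panel <- assemblePanel(commonTab, individual = riskTabs,
                               rules = unlist(rules),
                               nIndividual = cfg$panel$n_individual)
        pp <- file.path(outDir, "panel.tsv")
        write.table(panel@panels, pp, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        out <- c(out, pp)
        evals <- list()
        for (cc in intersect(names(cohorts)[hasSurv],
                             unique(panel@panels$cancer))) {
            pred <- predictRisk(cohorts[[cc]], panel, cancer = cc)
            act <- assignActualRisk(survivalTable(cohorts[[cc]]),
                                    cfg$risk$threshold_years)
            ev <- evaluatePrediction(pred, act)
            evals[[cc]] <- ev[c("TP", "FP", "TN", "FN",
                                "sensitivity", "specificity")]
            pt <- file.path(outDir, paste0(cc, "_predictions.tsv"))
            write.table(merge(pred, act, by = "sample_id"), pt,
                        sep = "\t", quote = FALSE, row.names = FALSE)
            out <- c(out, pt)
        }
        pe <- file.path(outDir, "panel_evaluation.json")
        write_json(evals, pe, auto_unbox = TRUE, digits = NA)
        out <- c(out, pe)
    }
    note("panel", t0, out,
         if (!length(common)) "no common risk genes; panel skipped"
         else character())

    ## 9. resampling ----------------------------------------------------
    t0 <- as.numeric(Sys.time())
    out <- character()
    if (!is.null(panel)) {
        summaries <- list()
        for (cc in intersect(names(cohorts)[hasSurv],
                             unique(panel@panels$cancer))) {
            rdSize <- cfg$resample$rd_size %||%
                max(20L, floor(ncol(cohorts[[cc]]) / 2))
            rv <- resampleValidate(cohorts[[cc]], panel,
                                   nRd = cfg$resample$n_rd,
                                   rdSize = min(rdSize, ncol(cohorts[[cc]])),
                                   seed = seed + 2000,
                                   alpha = cfg$resample$alpha, cancer = cc)
            p <- file.path(outDir, paste0(cc, "_resampling.tsv"))
            write.table(rv$perRD, p, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            out <- c(out, p)
            summaries[[cc]] <- rv$fractionSignificant
        }
        ps <- file.path(outDir, "resampling_summary.json")
        write_json(summaries, ps, auto_unbox = TRUE, digits = NA)
        out <- c(out, ps)
    }
    note("resample", t0, out,
         if (is.null(panel)) "no panel; resampling skipped" else character())

    manifest$files <- as.list(md5sum(files[file.exists(files)]))
    write_json(manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
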