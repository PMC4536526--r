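#' Read / write the pipeline's plain-text formats
#'
#' Expression TSV: first column `gene_id`, remaining columns one per sample.
#' Survival TSV: columns `sample_id`, `time_days`, `event` (0/1).
#' GMT: one gene set per line — name, description, then member genes.
#'
#' @param path file path.
#' @param cohort cohort label for the constructed [CancerCohort-class].
#' @param survPath optional survival TSV to attach.
#' @name panconserve-io
NULL

#' @rdname panconserve-io
#' @export
readExpressionTSV <- function(path) {
    d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "double"
    m
}

#' @rdname panconserve-io
#' @param x matrix or [CancerCohort-class] to write.
#' @export
writeExpressionTSV <- function(x, path) {
    m <- if (is(x, "CancerCohort")) exprsMatrix(x) else x
    d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname panconserve-io
#' @export
readSurvivalTSV <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "time_days", "event") %in% colnames(d)))
    d
}

#' @rdname panconserve-io
#' @param survival survival data.frame to write.
#' @export
writeSurvivalTSV <- function(survival, path) {
    write.table(survival[c("sample_id", "time_days", "event")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname panconserve-io
#' @export
readCohort <- function(path, cohort, survPath = NULL) {
    m <- readExpressionTSV(path)
    surv <- if (!is.null(survPath)) readSurvivalTSV(survPath) else NULL
    CancerCohort(m, cohort, survival = surv)
}

#' @rdname panconserve-io
#' @param assign a [ModuleAssignment-class].
#' @export
writeModuleTSV <- function(assign, path) {
    d <- data.frame(gene_id = names(moduleLabels(assign)),
                    module_label = unname(moduleLabels(assign)))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname panconserve-io
#' @param sets named list of gene vectors or [ConservedGeneSet-class].
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(seq_along(sets), function(i) {
        s <- sets[[i]]
        if (is(s, "ConservedGeneSet")) {
            nm <- s@name
            desc <- paste(s@cancers, collapse = "-")
            genes <- s@genes
        } else {
            nm <- names(sets)[i] %||% paste0("set", i)
            desc <- "na"
            genes <- s
        }
        paste(c(nm, desc, genes), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' @rdname panconserve-io
#' @export
readGMT <- function(path) {
    out <- lapply(strsplit(readLines(path), "\t"), function(f)
        f[-(1:2)])
    names(out) <- vapply(strsplit(readLines(path), "\t"), `[`, "", 1)
    out
}

#' @rdname panconserve-io
#' @param network a [GeneNetwork-class].
#' @export
writeEdgeListTSV <- function(network, path) {
    write.table(network@edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname panconserve-io
#' @export
writeSIF <- function(network, path) {
    e <- network@edges
    lines <- if (nrow(e)) paste(e$from, "coexp", e$to) else character()
    iso <- setdiff(network@nodes, c(e$from, e$to))
    writeLines(c(lines, iso), path)
    invisible(path)
}
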