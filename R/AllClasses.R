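#' CancerCohort: one tumor cohort's expression and survival data
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples log-scale expression matrix in assay `"exprs"`, the cohort
#' label in `metadata(x)$cohort`, and (optionally) per-sample survival columns
#' `time_days` and `event` in `colData`.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @export
setClass("CancerCohort", contains = "SummarizedExperiment")

setValidity("CancerCohort", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else if (!is.numeric(assay(object, "exprs")))
        msg <- c(msg, "assay 'exprs' must be numeric")
    if (is.null(metadata(object)$cohort) ||
        !is.character(metadata(object)$cohort))
        msg <- c(msg, "metadata(object)$cohort must be a character label")
    cd <- colData(object)
    if ("event" %in% colnames(cd) &&
        !all(cd$event %in% c(0L, 1L, NA)))
        msg <- c(msg, "colData 'event' must be 0/1")
    if ("time_days" %in% colnames(cd) &&
        any(cd$time_days < 0, na.rm = TRUE))
        msg <- c(msg, "colData 'time_days' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a CancerCohort
#'
#' @param exprs numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids); log-scale intensities.
#' @param cohort single character cohort label (e.g. `"BRCA"`).
#' @param survival optional data.frame with columns `sample_id`, `time_days`,
#'   `event` (0 = censored, 1 = death); matched to columns of `exprs` by
#'   `sample_id`, samples without a record get `NA`.
#' @return a [CancerCohort-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' cc <- CancerCohort(m, "DEMO")
#' @export
CancerCohort <- function(exprs, cohort, survival = NULL) {
    stopifnot(is.matrix(exprs), !is.null(rownames(exprs)),
              !is.null(colnames(exprs)),
              is.character(cohort), length(cohort) == 1L)
    cd <- DataFrame(row.names = colnames(exprs))
    if (!is.null(survival)) {
        stopifnot(all(c("sample_id", "time_days", "event") %in%
                      colnames(survival)))
        idx <- match(colnames(exprs), survival$sample_id)
        cd$time_days <- survival$time_days[idx]
        cd$event <- as.integer(survival$event[idx])
    }
    se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
    metadata(se)$cohort <- cohort
    new("CancerCohort", se)
}

#' @rdname CancerCohort
#' @param x a CancerCohort
#' @export
cohortName <- function(x) metadata(x)$cohort

#' @rdname CancerCohort
#' @export
exprsMatrix <- function(x) assay(x, "exprs")

#' Per-sample survival table of a cohort
#'
#' @param x a CancerCohort carrying `time_days`/`event` in `colData`.
#' @return data.frame with columns `sample_id`, `time_days`, `event`.
#' @export
survivalTable <- function(x) {
    cd <- colData(x)
    if (!all(c("time_days", "event") %in% colnames(cd)))
        stop("cohort '", cohortName(x), "' carries no survival annotation")
    data.frame(sample_id = rownames(cd),
               time_days = cd$time_days,
               event = cd$event,
               row.names = NULL)
}

setMethod("show", "CancerCohort", function(object) {
    cat("CancerCohort '", cohortName(object), "': ",
        nrow(object), " genes x ", ncol(object), " samples",
        if ("time_days" %in% colnames(colData(object)))
            " (with survival)" else "",
        "\n", sep = "")
})

#' CoexpressionNetwork: soft-thresholded co-expression network of one cohort
#'
#' Holds the adjacency matrix `a_ij = |cor|^beta` (unsigned) or
#' `((1+cor)/2)^beta` (signed), and after [tomSimilarity()] the topological
#' overlap matrix. Connectivity `k_i` is the adjacency row sum excluding the
#' unit diagonal.
#'
#' @slot cohort cohort label.
#' @slot power soft-threshold exponent beta.
#' @slot mode `"unsigned"` or `"signed"`.
#' @slot adjacency symmetric matrix in \[0,1\], unit diagonal.
#' @slot tom topological overlap matrix (0 x 0 until computed).
#' @export
setClass("CoexpressionNetwork",
         representation(cohort = "character", power = "numeric",
                        mode = "character", adjacency = "matrix",
                        tom = "matrix"))

setValidity("CoexpressionNetwork", function(object) {
    a <- object@adjacency
    msg <- character()
    if (object@power < 1) msg <- c(msg, "power must be >= 1")
    if (!object@mode %in% c("unsigned", "signed"))
        msg <- c(msg, "mode must be 'unsigned' or 'signed'")
    if (nrow(a) && (min(a) < -1e-12 || max(a) > 1 + 1e-12))
        msg <- c(msg, "adjacency entries must lie in [0,1]")
    if (length(object@tom) && !identical(dim(object@tom), dim(a)))
        msg <- c(msg, "tom dimensions must match adjacency")
    if (length(msg)) msg else TRUE
})

#' @rdname CoexpressionNetwork-class
#' @param x a CoexpressionNetwork
#' @export
networkGenes <- function(x) rownames(x@adjacency)

#' Per-gene whole-network connectivity (adjacency row sums minus self)
#' @param x a CoexpressionNetwork
#' @return named numeric vector k_i
#' @export
connectivity <- function(x) rowSums(x@adjacency) - 1

#' @rdname CoexpressionNetwork-class
#' @export
tomMatrix <- function(x) {
    if (!length(x@tom)) stop("TOM not computed; call tomSimilarity() first")
    x@tom
}

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork '", object@cohort, "': ",
        nrow(object@adjacency), " genes, beta = ", object@power,
        " (", object@mode, ")",
        if (length(object@tom)) ", TOM computed" else "", "\n", sep = "")
})

#' ModuleAssignment: gene -> module labelling for one cohort
#'
#' Every gene carries exactly one label; the reserved label (default
#' `"grey"`) marks unassigned genes.
#'
#' @slot labels named character vector, names = gene ids.
#' @slot unassigned the reserved unassigned label.
#' @export
setClass("ModuleAssignment",
         representation(labels = "character", unassigned = "character"))

setValidity("ModuleAssignment", function(object) {
    if (is.null(names(object@labels))) return("labels must be named by gene")
    if (anyDuplicated(names(object@labels)))
        return("each gene must appear exactly once")
    TRUE
})

#' @rdname ModuleAssignment-class
#' @param x a ModuleAssignment
#' @export
moduleLabels <- function(x) x@labels

#' Sizes of the named (non-grey) modules, largest first
#' @param x a ModuleAssignment
#' @export
moduleSizes <- function(x) {
    lab <- x@labels[x@labels != x@unassigned]
    if (!length(lab)) return(integer())
    sort(table(lab), decreasing = TRUE)
}

#' Genes belonging to one module
#' @param x a ModuleAssignment
#' @param module module label
#' @export
moduleGenes <- function(x, module) names(x@labels)[x@labels == module]

#' Names of the named modules (unassigned excluded)
#' @param x a ModuleAssignment
#' @export
moduleNames <- function(x) names(moduleSizes(x))

setMethod("show", "ModuleAssignment", function(object) {
    sz <- moduleSizes(object)
    cat("ModuleAssignment: ", length(object@labels), " genes, ",
        length(sz), " modules",
        if (length(sz)) paste0(" (sizes ",
                               paste(sz, collapse = ", "), ")") else "",
        "; ", sum(object@labels == object@unassigned), " unassigned\n",
        sep = "")
})

#' PreservationResult: per-module preservation of one cohort pair
#'
#' @slot refCohort,testCohort cohort labels.
#' @slot stats data.frame with one row per evaluated reference module:
#'   `module`, `nGenes`, `Zdensity`, `Zconnectivity`, `Zsummary`,
#'   `medianRank`, `class` (strong/moderate/none).
#' @export
setClass("PreservationResult",
         representation(refCohort = "character", testCohort = "character",
                        stats = "data.frame"))

#' @rdname PreservationResult-class
#' @param x a PreservationResult
#' @export
preservationStats <- function(x) x@stats

setMethod("show", "PreservationResult", function(object) {
    cat("PreservationResult ", object@refCohort, " -> ", object@testCohort,
        ": ", nrow(object@stats), " modules (",
        sum(object@stats$class == "strong"), " strong, ",
        sum(object@stats$class == "moderate"), " moderate)\n", sep = "")
})

#' PreservationMatrix: asymmetric percent-preservation grid over cohorts
#'
#' Cell (A, B) is the percentage of A's modules preserved (strong or
#' moderate, configurable) in cohort B.
#'
#' @slot percent numeric matrix in \[0, 100\].
#' @slot preserved,total integer count matrices behind each percentage.
#' @slot results list of [PreservationResult-class] for each directed pair.
#' @export
setClass("PreservationMatrix",
         representation(percent = "matrix", preserved = "matrix",
                        total = "matrix", results = "list"))

#' @rdname PreservationMatrix-class
#' @param x a PreservationMatrix
#' @export
percentMatrix <- function(x) x@percent

setMethod("show", "PreservationMatrix", function(object) {
    cat("PreservationMatrix over", nrow(object@percent), "cohorts\n")
    print(round(object@percent, 2))
})

#' ConservedGeneSet: genes conserved across preserved modules of a group
#'
#' @slot name set label (e.g. `"Set1"`).
#' @slot genes member genes (intersection across the module chain).
#' @slot cancers cohort group the set is conserved in.
#' @slot sourceModules named character: contributing module per cohort.
#' @export
setClass("ConservedGeneSet",
         representation(name = "character", genes = "character",
                        cancers = "character", sourceModules = "character"))

setMethod("show", "ConservedGeneSet", function(object) {
    cat("ConservedGeneSet '", object@name, "': ", length(object@genes),
        " genes conserved in ", paste(object@cancers, collapse = "-"),
        "\n", sep = "")
})

#' GeneNetwork: thresholded interaction network on a gene subset
#'
#' Undirected, no self-edges; edge weight is the TOM similarity.
#'
#' @slot nodes gene ids.
#' @slot edges data.frame `from`, `to`, `weight`.
#' @export
setClass("GeneNetwork",
         representation(nodes = "character", edges = "data.frame"))

#' Node degrees of a GeneNetwork
#' @param x a GeneNetwork
#' @return named integer vector over all nodes (isolated nodes have 0)
#' @export
nodeDegree <- function(x) {
    d <- setNames(integer(length(x@nodes)), x@nodes)
    if (nrow(x@edges)) {
        t1 <- table(factor(x@edges$from, levels = x@nodes))
        t2 <- table(factor(x@edges$to, levels = x@nodes))
        d <- setNames(as.integer(t1 + t2), x@nodes)
    }
    d
}

setMethod("show", "GeneNetwork", function(object) {
    cat("GeneNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
})

#' RiskPanel: per-cancer prognostic gene panels and their pan-cancer union
#'
#' @slot panels data.frame `cancer`, `gene`, `direction` (+1 hazardous when
#'   high, -1 protective), `rule` (composition rule that placed the gene).
#' @export
setClass("RiskPanel", representation(panels = "data.frame"))

setValidity("RiskPanel", function(object) {
    p <- object@panels
    need <- c("cancer", "gene", "direction", "rule")
    if (!all(need %in% colnames(p)))
        return(paste("panels needs columns:", paste(need, collapse = ", ")))
    if (nrow(p) && !all(p$direction %in% c(-1, 1)))
        return("direction must be -1 or +1")
    if (anyDuplicated(p[c("cancer", "gene")]))
        return("a gene may appear once per cancer")
    TRUE
})

#' Genes of one cancer's panel (or the pan-cancer union)
#' @param x a RiskPanel
#' @param cancer cohort label, or NULL for the union over all cancers
#' @return for a cancer: data.frame `gene`, `direction`; for the union:
#'   character vector of distinct genes
#' @export
panelGenes <- function(x, cancer = NULL) {
    p <- x@panels
    if (is.null(cancer)) return(sort(unique(p$gene)))
    p <- p[p$cancer == cancer, c("gene", "direction")]
    row.names(p) <- NULL
    p
}

#' @rdname panelGenes
#' @export
panelUnion <- function(x) panelGenes(x, NULL)

setMethod("show", "RiskPanel", function(object) {
    cat("RiskPanel:", length(unique(object@panels$cancer)), "cancers,",
        length(panelUnion(object)), "distinct genes in the union\n")
})
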