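#' @import methods
#' @importFrom stats cor sd rbinom runif rnorm setNames quantile
#' @importFrom utils read.csv head tail
NULL

.SYM_TOL <- 1e-10

#' Binary circRNA-disease association matrix
#'
#' An \code{AssociationMatrix} is a 0/1 matrix with circRNAs as rows and
#' diseases as columns. Row \eqn{i} is the interaction profile of circRNA
#' \eqn{c_i}; it is the supervision signal of the pipeline and the input of
#' the Gaussian interaction profile (GIP) kernels.
#'
#' @slot .Data binary numeric matrix with unique row and column names.
#' @export
setClass("AssociationMatrix", contains = "matrix")

setValidity("AssociationMatrix", function(object) {
    m <- object@.Data
    if (!is.numeric(m)) return("entries must be numeric 0/1")
    if (!all(m %in% c(0, 1))) return("entries must be 0 or 1")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("row (circRNA) and column (disease) labels are required")
    if (anyDuplicated(rownames(m))) return("duplicate circRNA labels")
    if (anyDuplicated(colnames(m))) return("duplicate disease labels")
    TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values numeric 0/1 matrix (circRNAs x diseases).
#' @param circIds,diseaseIds optional label vectors; taken from
#'   \code{dimnames(values)} when missing.
#' @return an \linkS4class{AssociationMatrix}.
#' @examples
#' A <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2),
#'                        circIds = c("c1", "c2"),
#'                        diseaseIds = c("d1", "d2"))
#' @export
AssociationMatrix <- function(values, circIds = rownames(values),
                              diseaseIds = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(circIds))
        circIds <- paste0("circ_", seq_len(nrow(values)))
    if (is.null(diseaseIds))
        diseaseIds <- paste0("disease_", seq_len(ncol(values)))
    dimnames(values) <- list(circIds, diseaseIds)
    new("AssociationMatrix", values)
}

#' Square similarity matrix with a role tag
#'
#' Symmetric, labelled similarity matrix. The \code{role} records which
#' similarity it carries: GIP kernels (\code{CIS}, \code{DIS}, \code{GIS}),
#' gene-based (\code{CGS}), sequence-based (\code{CES}), semantic
#' (\code{DSS}), fused comprehensive (\code{CS}, \code{DS}) or diffused
#' (\code{CRS}, \code{DRS}). Kernel and correlation roles are bounded in
#' [-1, 1] with unit diagonal; \code{CGS}/\code{CS} inherit the unbounded
#' scale of the gene-count conjugation.
#'
#' @slot role character scalar role tag.
#' @export
setClass("SimilarityMatrix", contains = "matrix",
         representation(role = "character"))

.KERNEL_ROLES <- c("CIS", "DIS", "GIS", "CES", "DSS")
.SIM_ROLES <- c(.KERNEL_ROLES, "CGS", "CS", "DS", "CRS", "DRS")

setValidity("SimilarityMatrix", function(object) {
    m <- object@.Data
    if (nrow(m) != ncol(m)) return("similarity matrix must be square")
    if (length(object@role) != 1L || !object@role %in% .SIM_ROLES)
        return(paste("role must be one of:", paste(.SIM_ROLES, collapse = ", ")))
    if (max(abs(m - t(m))) > .SYM_TOL)
        return("matrix is not symmetric (tolerance 1e-10)")
    if (object@role %in% .KERNEL_ROLES) {
        if (min(m) < -1 - 1e-8 || max(m) > 1 + 1e-8)
            return("kernel/correlation entries must lie in [-1, 1]")
        if (max(abs(diag(m) - 1)) > 1e-8)
            return("kernel/correlation diagonal must be 1")
    }
    TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix.
#' @param role role tag (one of CIS, DIS, GIS, CGS, CES, DSS, CS, DS,
#'   CRS, DRS).
#' @param ids optional labels; taken from \code{rownames(values)} if absent.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values, role, ids = rownames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(ids)) ids <- paste0("node_", seq_len(nrow(values)))
    dimnames(values) <- list(ids, ids)
    # symmetrize away floating-point asymmetry only; real asymmetry is caught
    # by the validity check before this rounding could mask it
    new("SimilarityMatrix", values, role = role)
}

#' @describeIn SimilarityMatrix role accessor.
#' @param x a SimilarityMatrix.
#' @export
simRole <- function(x) x@role

## strip S4 wrappers down to the plain base matrix
.baseMatrix <- function(x) {
    m <- x@.Data
    attr(m, "class") <- NULL
    m
}

#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) .baseMatrix(x))
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) .baseMatrix(x))

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix [%s] %d x %d, range [%.4g, %.4g]\n",
                object@role, nrow(object), ncol(object),
                min(object), max(object)))
})

setMethod("show", "AssociationMatrix", function(object) {
    cat(sprintf("AssociationMatrix %d circRNAs x %d diseases, %d positives\n",
                nrow(object), ncol(object), sum(object)))
})

#' Result of random walk with restart diffusion
#'
#' Row \eqn{l} holds the converged stationary vector for the basis seed on
#' node \eqn{l}. Per-seed iteration counts and final residuals are kept so
#' non-converged seeds (possible only at c = 1) are identifiable.
#'
#' @slot iterations integer vector of per-seed iteration counts.
#' @slot residuals numeric vector of final sup-norm updates.
#' @slot converged logical vector.
#' @export
setClass("DiffusedMatrix", contains = "matrix",
         representation(iterations = "integer", residuals = "numeric",
                        converged = "logical"))

setValidity("DiffusedMatrix", function(object) {
    if (!all(is.finite(object@.Data))) return("non-finite entries")
    n <- nrow(object@.Data)
    if (length(object@iterations) != n || length(object@residuals) != n ||
        length(object@converged) != n)
        return("per-seed metadata lengths must equal the node count")
    TRUE
})

#' @export
setMethod("as.matrix", "DiffusedMatrix", function(x, ...) .baseMatrix(x))

setMethod("show", "DiffusedMatrix", function(object) {
    cat(sprintf("DiffusedMatrix %d x %d (%d/%d seeds converged, max %d iterations)\n",
                nrow(object), ncol(object), sum(object@converged),
                length(object@converged), max(object@iterations)))
})

#' PCA feature matrix
#'
#' Rows are entities (circRNAs or diseases), columns the retained principal
#' components of the centred input.
#'
#' @slot components loading matrix (input columns x retained components).
#' @slot explainedVariance per-component variance, non-increasing.
#' @slot center column means removed before projection.
#' @export
setClass("FeatureMatrix", contains = "matrix",
         representation(components = "matrix",
                        explainedVariance = "numeric",
                        center = "numeric"))

setValidity("FeatureMatrix", function(object) {
    ev <- object@explainedVariance
    if (length(ev) != ncol(object@.Data))
        return("one explained-variance entry per retained component")
    if (length(ev) > 1 && any(diff(ev) > 1e-8))
        return("explained variance must be non-increasing")
    TRUE
})

#' @describeIn FeatureMatrix explained variance accessor.
#' @param x a FeatureMatrix.
#' @export
explainedVariance <- function(x) x@explainedVariance

#' @export
setMethod("as.matrix", "FeatureMatrix", function(x, ...) .baseMatrix(x))

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix %d x %d (%.1f%% variance retained)\n",
                nrow(object), ncol(object),
                100 * sum(object@explainedVariance) /
                    max(sum(object@explainedVariance), .Machine$double.eps)))
})

#' Heterogeneous circRNA-disease network
#'
#' Joins the two node types: the adjacency block matrix
#' \eqn{A_{cd} = [[CS, A], [A^T, DS]]} and the block-diagonal feature
#' matrix \eqn{CD = blockdiag(CF, DF)}, with the row-sum degrees used by
#' the symmetric normalisation of the graph convolution.
#'
#' @slot adjacency (n_c+n_d) square block matrix.
#' @slot features (n_c+n_d) x (p_c+p_d) block-diagonal feature matrix.
#' @slot degrees row sums of the adjacency.
#' @slot nCirc,nDis block sizes.
#' @export
setClass("HeteroNetwork",
         representation(adjacency = "matrix", features = "matrix",
                        degrees = "numeric", nCirc = "integer",
                        nDis = "integer"))

setValidity("HeteroNetwork", function(object) {
    n <- object@nCirc + object@nDis
    if (nrow(object@adjacency) != n || ncol(object@adjacency) != n)
        return("adjacency must be (nCirc+nDis) square")
    if (nrow(object@features) != n)
        return("features must have one row per node")
    if (length(object@degrees) != n)
        return("one degree per node")
    TRUE
})

setMethod("show", "HeteroNetwork", function(object) {
    cat(sprintf("HeteroNetwork: %d circRNAs + %d diseases, %d features\n",
                object@nCirc, object@nDis, ncol(object@features)))
})

#' Trainable parameters of the graph-convolution encoder/decoder
#'
#' @slot We encoder weight, (p_c+p_d) x LFN.
#' @slot Wd bilinear decoder weight, LFN x LFN.
#' @slot B additive bias, (n_c+n_d) x LFN.
#' @slot lfn latent factor number.
#' @export
setClass("GCNParams",
         representation(We = "matrix", Wd = "matrix", B = "matrix",
                        lfn = "integer"))

setValidity("GCNParams", function(object) {
    if (!all(is.finite(object@We), is.finite(object@Wd), is.finite(object@B)))
        return("non-finite parameter entries")
    if (ncol(object@We) != object@lfn || any(dim(object@Wd) != object@lfn) ||
        ncol(object@B) != object@lfn)
        return("parameter shapes inconsistent with lfn")
    TRUE
})

#' Predicted association score matrix
#'
#' Sigmoid-decoded scores in (0,1), circRNAs x diseases, with the per-epoch
#' training loss trace.
#'
#' @slot lossTrace numeric vector of objective values per epoch.
#' @export
setClass("ScoreMatrix", contains = "matrix",
         representation(lossTrace = "numeric"))

setValidity("ScoreMatrix", function(object) {
    m <- object@.Data
    if (!all(is.finite(m))) return("non-finite scores")
    if (min(m) <= 0 || max(m) >= 1) return("scores must lie in (0, 1)")
    TRUE
})

#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) .baseMatrix(x))

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("ScoreMatrix %d x %d, final training loss %.4g\n",
                nrow(object), ncol(object),
                if (length(object@lossTrace)) tail(object@lossTrace, 1) else NA))
})

#' @describeIn ScoreMatrix loss-trace accessor.
#' @param x a ScoreMatrix.
#' @export
lossTrace <- function(x) x@lossTrace

#' Complete circRNA-disease dataset
#'
#' Bundles the four raw inputs the pipeline consumes: the association
#' matrix, circRNA nucleotide sequences (NA for circRNAs without a known
#' sequence), the circRNA-gene association matrix, and the disease DAG as
#' ancestor sets. \code{clusters} carries planted ground-truth cluster
#' labels when the object comes from the synthetic generator.
#'
#' @slot assoc an \linkS4class{AssociationMatrix}.
#' @slot sequences named character vector parallel to the circRNA labels
#'   (NA = no sequence).
#' @slot geneAssoc binary circRNA x gene matrix.
#' @slot dag list with elements \code{ancestors} (named list of ancestor
#'   term sets, diseases absent from the DAG are missing or empty) and
#'   \code{universe} (all DAG terms).
#' @slot clusters list with optional integer vectors \code{circ}, \code{disease}.
#' @export
setClass("CircDiseaseData",
         representation(assoc = "AssociationMatrix", sequences = "character",
                        geneAssoc = "matrix", dag = "list",
                        clusters = "list"))

setValidity("CircDiseaseData", function(object) {
    circ <- rownames(object@assoc)
    if (!identical(names(object@sequences), circ))
        return("sequences must be named by, and ordered as, the circRNA labels")
    if (nrow(object@geneAssoc) > 0 && !identical(rownames(object@geneAssoc), circ))
        return("geneAssoc rows must match the circRNA labels")
    if (!all(c("ancestors", "universe") %in% names(object@dag)))
        return("dag must have 'ancestors' and 'universe'")
    extra <- setdiff(names(object@dag$ancestors), colnames(object@assoc))
    if (length(extra))
        return("dag ancestor sets refer to unknown diseases")
    TRUE
})

setMethod("show", "CircDiseaseData", function(object) {
    cat(sprintf(paste0("CircDiseaseData: %d circRNAs x %d diseases ",
                       "(%d positives)\n  %d sequences, %d genes, ",
                       "%d diseases in DAG\n"),
                nrow(object@assoc), ncol(object@assoc), sum(object@assoc),
                sum(!is.na(object@sequences)), ncol(object@geneAssoc),
                length(object@dag$ancestors)))
})

#' @describeIn CircDiseaseData association-matrix accessor.
#' @param x a CircDiseaseData.
#' @export
associations <- function(x) x@assoc

#' @describeIn CircDiseaseData sequence accessor.
#' @export
circSequences <- function(x) x@sequences

#' @describeIn CircDiseaseData gene-association accessor.
#' @export
geneAssociations <- function(x) x@geneAssoc

#' @describeIn CircDiseaseData disease-DAG accessor.
#' @export
diseaseDag <- function(x) x@dag
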