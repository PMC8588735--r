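## Readers and writers for the on-disk formats: association / gene pair
## lists or dense 0/1 matrices, FASTA sequences, DAG edge lists, and
## labelled dense CSV matrices with bit-exact round trips.

.detectSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

#' Read a binary association table
#'
#' Auto-detects the layout: a 2-column file is a pair list (circRNA,
#' disease; duplicates collapse to a single 1 with a warning; label order
#' is first seen), anything wider is a dense labelled 0/1 matrix (first
#' column = row labels, header = column labels).
#'
#' @param path TSV or CSV file.
#' @return an \linkS4class{AssociationMatrix}.
#' @export
readAssociationTable <- function(path) {
    sep <- .detectSep(path)
    probe <- read.csv(path, sep = sep, header = FALSE, nrows = 1,
                      colClasses = "character")
    if (ncol(probe) == 2L) {
        df <- read.csv(path, sep = sep, header = FALSE,
                       colClasses = "character")
        names(df) <- c("circ", "disease")
        if (anyDuplicated(df)) {
            warning(sprintf("%d duplicate pair(s) collapsed",
                            sum(duplicated(df))))
            df <- unique(df)
        }
        circ <- unique(df$circ); dis <- unique(df$disease)
        m <- matrix(0, length(circ), length(dis),
                    dimnames = list(circ, dis))
        m[cbind(match(df$circ, circ), match(df$disease, dis))] <- 1
        AssociationMatrix(m)
    } else {
        m <- as.matrix(read.csv(path, sep = sep, row.names = 1,
                                check.names = FALSE))
        if (!all(m %in% c(0, 1)))
            stop("dense association matrix must be 0/1")
        AssociationMatrix(m)
    }
}

#' Read circRNA sequences from FASTA
#'
#' Case-insensitive; RNA alphabet is accepted and stored as DNA (U is
#' mapped to T). FASTA ids absent from \code{circIds} are dropped with a
#' warning; circRNAs without a record get \code{NA} ("no sequence").
#'
#' @param path FASTA file.
#' @param circIds ordered circRNA labels to align against; when
#'   \code{NULL} the FASTA order is kept.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path, circIds = NULL) {
    recs <- Biostrings::readBStringSet(path)
    seqs <- chartr("Uu", "Tt", toupper(as.character(recs)))
    names(seqs) <- sub("\\s.*$", "", names(recs))
    if (is.null(circIds)) return(seqs)
    unknown <- setdiff(names(seqs), circIds)
    if (length(unknown))
        warning(sprintf("%d FASTA id(s) not in the association table (dropped): %s",
                        length(unknown),
                        paste(head(unknown, 3), collapse = ", ")))
    out <- setNames(rep(NA_character_, length(circIds)), circIds)
    keep <- intersect(names(seqs), circIds)
    out[keep] <- seqs[keep]
    out
}

#' Read a disease DAG from a parent-child edge list
#'
#' Two-column TSV/CSV (parent, child). The ancestor closure (every node's
#' set of ancestors, including itself) is computed over the graph; a cycle
#' is an error naming one offending edge.
#'
#' @param path edge-list file.
#' @return list with \code{ancestors} (named list over all nodes),
#'   \code{universe}, and \code{edges}.
#' @export
readDagEdges <- function(path) {
    sep <- .detectSep(path)
    df <- read.csv(path, sep = sep, header = FALSE,
                   colClasses = "character")
    if (ncol(df) != 2L) stop("DAG edge list must have exactly 2 columns")
    names(df) <- c("parent", "child")
    dagFromEdges(df)
}

#' Build the ancestor closure from a parent-child edge data.frame
#'
#' @param edges data.frame with columns \code{parent}, \code{child}.
#' @return list with \code{ancestors}, \code{universe}, \code{edges}.
#' @export
dagFromEdges <- function(edges) {
    g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) {
        comp <- igraph::components(g, mode = "strong")
        bad <- which(comp$csize > 1)[1]
        nodes <- names(comp$membership)[comp$membership == bad]
        sub <- igraph::induced_subgraph(g, nodes)
        e <- igraph::as_edgelist(sub)[1, ]
        stop(sprintf("cycle in DAG edges; offending edge: %s -> %s",
                     e[1], e[2]))
    }
    nodes <- igraph::V(g)$name
    anc <- lapply(nodes, function(v)
        names(igraph::subcomponent(g, v, mode = "in")))
    names(anc) <- nodes
    list(ancestors = anc, universe = nodes,
         edges = as.data.frame(edges, stringsAsFactors = FALSE))
}

#' Write / read a labelled dense matrix as CSV
#'
#' Values are written with 17 significant digits so that
#' \code{readMatrixCsv(writeMatrixCsv(m))} is bit-exact at full double
#' precision.
#'
#' @param m labelled numeric matrix.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeMatrixCsv <- function(m, path) {
    m <- as.matrix(m)
    stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
    header <- paste(c("", colnames(m)), collapse = ",")
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = ","),
        character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' @rdname writeMatrixCsv
#' @export
readMatrixCsv <- function(path) {
    as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
}

#' Assemble a CircDiseaseData object from its parts
#'
#' Reindexes every input to the association-table coordinate order:
#' sequences are aligned by name, gene rows by circRNA label, and DAG
#' ancestor sets restricted to the diseases present.
#'
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param sequences named character vector (any subset of the circRNAs).
#' @param geneAssoc binary circRNA x gene matrix (row subset allowed;
#'   missing rows become all-zero).
#' @param dag DAG list from \code{\link{readDagEdges}} /
#'   \code{\link{dagFromEdges}}, or \code{NULL}.
#' @return a \linkS4class{CircDiseaseData}.
#' @export
circDiseaseData <- function(assoc, sequences = NULL, geneAssoc = NULL,
                            dag = NULL) {
    circ <- rownames(assoc); dis <- colnames(assoc)
    seqs <- setNames(rep(NA_character_, length(circ)), circ)
    if (!is.null(sequences)) {
        unknown <- setdiff(names(sequences), circ)
        if (length(unknown))
            warning(sprintf("%d sequence id(s) not in association table (dropped)",
                            length(unknown)))
        keep <- intersect(names(sequences), circ)
        seqs[keep] <- sequences[keep]
    }
    if (is.null(geneAssoc)) {
        Acg <- matrix(0, length(circ), 0, dimnames = list(circ, NULL))
    } else {
        geneAssoc <- as.matrix(geneAssoc)
        Acg <- matrix(0, length(circ), ncol(geneAssoc),
                      dimnames = list(circ, colnames(geneAssoc)))
        keep <- intersect(rownames(geneAssoc), circ)
        Acg[keep, ] <- geneAssoc[keep, , drop = FALSE]
    }
    if (is.null(dag)) {
        dagList <- list(ancestors = list(), universe = character(0),
                        edges = data.frame(parent = character(0),
                                           child = character(0)))
    } else {
        anc <- dag$ancestors[intersect(names(dag$ancestors), dis)]
        dagList <- list(ancestors = anc, universe = dag$universe,
                        edges = dag$edges)
    }
    new("CircDiseaseData", assoc = assoc, sequences = seqs, geneAssoc = Acg,
        dag = dagList, clusters = list())
}

#' Write the four raw inputs of a dataset to a directory
#'
#' Emits \code{associations.csv} (pair list), \code{sequences.fasta},
#' \code{gene_associations.csv} (pair list) and \code{dag_edges.tsv} in
#' the formats the readers consume.
#'
#' @param data a \linkS4class{CircDiseaseData}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDatasetFiles <- function(data, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    A <- as.matrix(associations(data))
    idx <- which(A == 1, arr.ind = TRUE)
    writeLines(paste(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]], sep = ","),
               file.path(dir, "associations.csv"))
    seqs <- circSequences(data)
    has <- !is.na(seqs)
    writeLines(as.vector(rbind(paste0(">", names(seqs)[has]), seqs[has])),
               file.path(dir, "sequences.fasta"))
    Acg <- geneAssociations(data)
    if (ncol(Acg) > 0) {
        gi <- which(Acg == 1, arr.ind = TRUE)
        writeLines(paste(rownames(Acg)[gi[, 1]], colnames(Acg)[gi[, 2]],
                         sep = ","),
                   file.path(dir, "gene_associations.csv"))
    }
    edges <- diseaseDag(data)$edges
    if (!is.null(edges) && nrow(edges))
        writeLines(paste(edges$parent, edges$child, sep = "\t"),
                   file.path(dir, "dag_edges.tsv"))
    invisible(dir)
}
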