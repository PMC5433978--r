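#' Read a phased haplotype alignment
#'
#' Reads a FASTA alignment of phased, gap-free haplotype sequences and an
#' optional population map keyed by sequence name. Sequences must be equal
#' length over \{A, C, G, T\}; sites with gaps or ambiguity codes must be
#' removed upstream (this stage rejects rather than imputes).
#'
#' @param fasta path to the FASTA alignment.
#' @param populationMap optional named character vector (see [readPopMap()]);
#'   sequence names absent from the map get population \code{"unknown"}.
#' @return list with \code{sequences} (a
#'   \link[Biostrings]{DNAStringSet}) and \code{population} (character
#'   vector parallel to the sequences).
#' @export
readHaplotypeAlignment <- function(fasta, populationMap = NULL) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    pop <- if (is.null(populationMap)) rep("unknown", length(seqs))
           else {
               p <- populationMap[names(seqs)]
               p[is.na(p)] <- "unknown"
               unname(p)
           }
    list(sequences = seqs, population = pop)
}

#' Collapse identical haplotypes
#'
#' Merges identical sequences into unique-haplotype nodes, recording each
#' node's multiplicity and per-population composition. Node order follows
#' first appearance in the input; the collapse itself is order-independent
#' as a set. Errors (naming the offending alignment column) on unequal
#' lengths or non-ACGT characters.
#'
#' @param sequences a \link[Biostrings]{DNAStringSet} or character vector of
#'   aligned sequences.
#' @param population character vector of population labels, one per
#'   sequence (default all \code{"unknown"}).
#' @return list with \code{nodes} (data.frame: \code{hap_id},
#'   \code{sequence}, \code{multiplicity}), \code{popCounts} (haplotypes x
#'   populations integer matrix) and \code{L} (alignment length).
#' @export
collapseHaplotypes <- function(sequences,
                               population = rep("unknown",
                                                length(sequences))) {
    seqs <- toupper(as.character(sequences))
    if (!length(seqs)) stop("no sequences")
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
        stop("sequences are not aligned: lengths ",
             paste(sort(L), collapse = ", "))
    chars <- strsplit(seqs, "", fixed = TRUE)
    badCol <- NA_integer_
    for (s in chars) {
        bad <- which(!s %in% c("A", "C", "G", "T"))
        if (length(bad)) { badCol <- bad[1]; break }
    }
    if (!is.na(badCol))
        stop("non-ACGT character at alignment column ", badCol,
             "; remove gaps/missing data upstream")
    uniq <- unique(seqs)
    idx <- match(seqs, uniq)
    pops <- sort(unique(population))
    popCounts <- vapply(pops, function(p)
        vapply(seq_along(uniq), function(i)
            sum(population[idx == i] == p), integer(1)),
        integer(length(uniq)))
    popCounts <- matrix(popCounts, nrow = length(uniq),
                        dimnames = list(NULL, pops))
    nodes <- data.frame(hap_id = sprintf("H%02d", seq_along(uniq)),
                        sequence = uniq,
                        multiplicity = as.integer(tabulate(idx,
                                                           length(uniq))),
                        stringsAsFactors = FALSE)
    rownames(popCounts) <- nodes$hap_id
    list(nodes = nodes, popCounts = popCounts, L = L)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j at which two haplotypes from an
#' alignment of length L can be connected with parsimony probability at
#' least \code{alpha}, in the statistical-parsimony (TCS) framework of
#' Templeton, Crandall & Sing (1992). The cumulative probability that a
#' j-step connection is non-homoplasious is evaluated as
#' \deqn{P_j = \prod_{i=1}^{j} \frac{2(L - i)}{2L - i}}
#' (each successive observed difference must hit a previously unhit site,
#' out of the remaining opportunities for change along two lineages of L
#' sites); \eqn{P_0 = 1} and \eqn{P_j} decreases in j, so the limit is the
#' largest j with \eqn{P_j \ge \alpha}. At the conventional 95% level and
#' L around 600 bp this yields the familiar limit of about 11 steps.
#'
#' @param L alignment length in bp (>= 1).
#' @param alpha parsimony confidence in (0, 1); default 0.90.
#' @return integer step limit (possibly 0 for tiny L / large alpha).
#' @export
parsimonyConnectionLimit <- function(L, alpha = 0.90) {
    stopifnot(length(L) == 1L, L >= 1, alpha > 0, alpha < 1)
    j <- 0L
    p <- 1
    while (j < L - 1L) {
        pNext <- p * 2 * (L - (j + 1L)) / (2 * L - (j + 1L))
        if (pNext < alpha) break
        p <- pNext
        j <- j + 1L
    }
    j
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects unique haplotypes agglomeratively: pairwise Hamming distances
#' are processed in nondecreasing order and, at each distance d <= jMax,
#' every pair of haplotypes lying in different connected components (as the
#' components stood before any edge at distance d was added) gains an edge.
#' Processing whole distance ties against the pre-tie components retains all
#' equal-distance alternative connections (TCS-style reticulation) and makes
#' the edge set invariant to input order. Components that cannot be joined
#' within \code{jMax} steps remain separate subnetworks. Each edge is
#' annotated with \code{steps - 1} unobserved intermediate haplotypes.
#'
#' @param haps collapsed haplotypes from [collapseHaplotypes()].
#' @param jMax connection limit in steps; default
#'   \code{parsimonyConnectionLimit(L, alpha)}.
#' @param alpha confidence level used when \code{jMax} is derived
#'   (default 0.90).
#' @return a [ParsimonyNetwork-class].
#' @export
buildNetwork <- function(haps, jMax = NULL, alpha = 0.90) {
    nodes <- haps$nodes
    L <- haps$L
    if (is.null(jMax)) jMax <- parsimonyConnectionLimit(L, alpha)
    else alpha <- NA_real_
    jMax <- as.integer(jMax)
    n <- nrow(nodes)
    edges <- data.frame(from = character(), to = character(),
                        steps = integer(), intermediates = integer(),
                        stringsAsFactors = FALSE)
    if (n > 1L) {
        dm <- .hammingMatrix(nodes$sequence)
        comp <- seq_len(n)
        pairs <- which(upper.tri(dm), arr.ind = TRUE)
        pd <- dm[pairs]
        keep <- pd <= jMax
        pairs <- pairs[keep, , drop = FALSE]
        pd <- pd[keep]
        for (d in sort(unique(pd))) {
            at <- which(pd == d)
            cross <- at[comp[pairs[at, 1]] != comp[pairs[at, 2]]]
            if (length(cross)) {
                edges <- rbind(edges, data.frame(
                    from = nodes$hap_id[pairs[cross, 1]],
                    to = nodes$hap_id[pairs[cross, 2]],
                    steps = as.integer(d),
                    intermediates = as.integer(d) - 1L,
                    stringsAsFactors = FALSE))
                for (i in cross) {
                    c1 <- comp[pairs[i, 1]]; c2 <- comp[pairs[i, 2]]
                    if (c1 != c2) comp[comp == c2] <- c1
                }
            }
        }
        rownames(edges) <- NULL
    }
    methods::new("ParsimonyNetwork", nodes = nodes,
                 popCounts = haps$popCounts, edges = edges,
                 jMax = jMax, alpha = alpha, L = as.integer(L))
}

.hammingMatrix <- function(seqs) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    n <- nrow(m)
    dm <- matrix(0L, n, n)
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            dm[i, j] <- dm[j, i] <- sum(m[i, ] != m[j, ])
    dm
}

#' Connected components of a network
#'
#' @param net a [ParsimonyNetwork-class].
#' @return integer component label per haplotype, named by \code{hap_id}.
#' @export
networkComponents <- function(net) {
    g <- asIgraph(net)
    comp <- igraph::components(g)$membership
    comp[net@nodes$hap_id]
}

#' Convert a ParsimonyNetwork to an igraph graph
#'
#' Nodes carry \code{multiplicity} and per-population count attributes;
#' edges carry \code{steps} and \code{intermediates} (with \code{steps} also
#' set as edge weight).
#'
#' @param net a [ParsimonyNetwork-class].
#' @return an \link[igraph]{igraph} object.
#' @export
asIgraph <- function(net) {
    verts <- cbind(net@nodes[, c("hap_id", "multiplicity")],
                   as.data.frame(net@popCounts))
    g <- igraph::graph_from_data_frame(
        if (nrow(net@edges)) net@edges else
            data.frame(from = character(), to = character()),
        directed = FALSE, vertices = verts)
    if (nrow(net@edges))
        igraph::E(g)$weight <- net@edges$steps
    g
}

#' Write network tables and GraphML
#'
#' \code{writeNetworkTables} writes a nodes TSV (haplotype, multiplicity,
#' per-population counts) and an edges TSV (h1, h2, steps, intermediates);
#' \code{writeNetworkGraphML} writes GraphML for plotting tools.
#'
#' @param net a [ParsimonyNetwork-class].
#' @param nodesPath,edgesPath,path output paths.
#' @return the path(s), invisibly.
#' @export
writeNetworkTables <- function(net, nodesPath, edgesPath) {
    nodes <- cbind(net@nodes[, c("hap_id", "multiplicity")],
                   as.data.frame(net@popCounts))
    utils::write.table(nodes, nodesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    edges <- net@edges
    colnames(edges)[1:2] <- c("h1", "h2")
    utils::write.table(edges, edgesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(nodesPath, edgesPath))
}

#' @rdname writeNetworkTables
#' @export
writeNetworkGraphML <- function(net, path) {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}
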