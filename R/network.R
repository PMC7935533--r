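#' Induced subnetwork of up-regulated proteins
#'
#' Builds the subgraph of the interactome induced by a gene list (typically
#' the up-regulated accessions of one patient): it keeps exactly the
#' interactome edges with both endpoints in the list. Listed proteins with no
#' within-list interaction partner are removed and counted, so every retained
#' vertex has degree >= 1 inside the subnetwork. Listed proteins absent from
#' the interactome are likewise counted.
#'
#' @param upregulated character vector of accessions.
#' @param interactome an [interactome()].
#' @return A `subnetwork` (same accessors as an interactome) with attributes
#'   `n_isolated` (listed, in the interactome, but without within-list
#'   neighbours) and `n_absent` (listed but not in the interactome).
#' @export
build_subnetwork <- function(upregulated, interactome) {
  stopifnot(inherits(interactome, c("interactome", "subnetwork")))
  upregulated <- unique(upregulated)
  present <- intersect(upregulated, interactome_vertices(interactome))
  g <- igraph::induced_subgraph(graph_of(interactome), present)
  isolated <- igraph::degree(g) == 0
  g <- igraph::delete_vertices(g, which(isolated))
  out <- structure(list(graph = g, parent = interactome),
                   class = "subnetwork")
  attr(out, "n_isolated") <- sum(isolated)
  attr(out, "n_absent") <- length(upregulated) - length(present)
  out
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d proteins, %d interactions\n",
              n_vertices(x), n_edges(x)))
  invisible(x)
}

#' Degree distribution of a subnetwork
#'
#' Counts, for each connectivity value k, the number of vertices with exactly
#' k neighbours within the subnetwork (not in the parent interactome).
#'
#' @param sub a `subnetwork` (or `interactome`).
#' @return A `degree_distribution`: list with `counts` (named integer vector,
#'   names are the degrees k) and `n_vertices`. An empty graph yields an
#'   empty-distribution sentinel with `n_vertices = 0`.
#' @export
degree_counts <- function(sub) {
  d <- interactome_degree(sub)
  if (length(d) == 0L) {
    return(structure(list(counts = stats::setNames(integer(0), character(0)),
                          n_vertices = 0L),
                     class = "degree_distribution"))
  }
  tab <- table(d)
  structure(list(counts = stats::setNames(as.integer(tab), names(tab)),
                 n_vertices = length(d)),
            class = "degree_distribution")
}

#' Shannon entropy of a degree distribution
#'
#' \eqn{H = -\sum_k p(k) \log_2 p(k)} where \eqn{p(k)} is the probability
#' that a vertex of the subnetwork has connectivity \eqn{k}. H is measured in
#' bits; it is 0 exactly when all vertices share one degree, and grows with
#' the diversity of connectivity values — the complexity measure used to
#' score up-regulated subnetworks.
#'
#' @param dist a `degree_distribution` (or a graph-bearing object, in which
#'   case [degree_counts()] is applied first).
#' @return Entropy in bits, or `NA_real_` (with a warning) for an empty
#'   distribution — never a silent 0.
#' @export
shannon_entropy <- function(dist) {
  if (!inherits(dist, "degree_distribution")) dist <- degree_counts(dist)
  if (dist$n_vertices == 0L) {
    warning("entropy of an empty subnetwork is undefined")
    return(NA_real_)
  }
  p <- dist$counts / dist$n_vertices
  -sum(p * log2(p))
}

#' Rank hub targets by interactome connectivity
#'
#' Sorts up-regulated proteins by their degree in the FULL interactome
#' (connections to any protein, not just up-regulated ones) in decreasing
#' order and returns the top n — the candidate therapeutic targets. Ties are
#' broken by accession ascending for determinism. Up-regulated accessions
#' absent from the interactome are excluded and counted.
#'
#' @param upregulated character vector of accessions.
#' @param interactome an [interactome()].
#' @param n number of targets to keep; default 20.
#' @return Data frame with columns `accession` and `degree`, at most `n`
#'   rows, with attribute `n_absent`.
#' @export
rank_hubs <- function(upregulated, interactome, n = 20) {
  stopifnot(inherits(interactome, "interactome"), n >= 1)
  upregulated <- unique(upregulated)
  deg <- interactome_degree(interactome)
  present <- intersect(upregulated, names(deg))
  d <- deg[present]
  ord <- order(-d, names(d))
  out <- data.frame(accession = names(d)[ord],
                    degree = as.integer(d[ord]))[seq_len(min(n, length(d))), ,
                                                 drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_absent") <- length(upregulated) - length(present)
  out
}

#' Cohort-level target recurrence
#'
#' Tabulates, across a cohort of patients, how often each protein appears in
#' the per-patient up-regulated lists, and retains the proteins up-regulated
#' in at least a threshold fraction of patients (default 70%).
#'
#' @param per_patient_upregulated list of character vectors, one per patient.
#' @param threshold minimum fraction of patients (inclusive); default 0.70.
#' @return Data frame with columns `accession`, `count`, `cohort_size`,
#'   `fraction`, sorted by fraction descending then accession, containing
#'   only the retained proteins.
#' @export
target_recurrence <- function(per_patient_upregulated, threshold = 0.70) {
  stopifnot(is.list(per_patient_upregulated),
            length(per_patient_upregulated) >= 1L,
            threshold >= 0, threshold <= 1)
  cohort <- length(per_patient_upregulated)
  counts <- table(unlist(lapply(per_patient_upregulated, unique)))
  frac <- as.numeric(counts) / cohort
  keep <- frac >= threshold
  out <- data.frame(accession = names(counts)[keep],
                    count = as.integer(counts[keep]),
                    cohort_size = rep.int(cohort, sum(keep)),
                    fraction = frac[keep])
  out <- out[order(-out$fraction, out$accession), ]
  rownames(out) <- NULL
  out
}
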