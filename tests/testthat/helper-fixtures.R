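# shared builders for tiny in-code fixtures

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# interactome from a character vector of "A B" edges
toy_interactome <- function(edges) {
  interactome(do.call(rbind, strsplit(edges, " ", fixed = TRUE)))
}

star_interactome <- function(hub = "H", leaves = paste0("P", 1:5)) {
  toy_interactome(paste(hub, leaves))
}

ev <- function(..., sample_id = "s", id_space = "uniprot",
               norm_state = "raw_counts") {
  expression_vector(c(...), sample_id, id_space, norm_state)
}

# brute-force degree/entropy oracle working directly on an edge matrix,
# independent of igraph and of the package's graph code
oracle_degrees <- function(edge_mat) {
  verts <- unique(as.vector(edge_mat))
  vapply(verts, function(v)
    sum(edge_mat[, 1] == v) + sum(edge_mat[, 2] == v), numeric(1))
}

oracle_entropy <- function(degrees) {
  p <- as.vector(table(degrees)) / length(degrees)
  -sum(p * log2(p))
}

# random simple undirected graph as an edge matrix, for oracle comparisons
random_edge_matrix <- function(n_vertices, n_edges) {
  verts <- sprintf("V%02d", seq_len(n_vertices))
  all_pairs <- t(combn(verts, 2))
  all_pairs[sample(nrow(all_pairs), min(n_edges, nrow(all_pairs))), ,
            drop = FALSE]
}
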