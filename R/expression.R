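#' Per-sample expression vector
#'
#' Holds one sample's gene/protein expression values together with the
#' identifier space of its keys and a tag recording how far along the
#' normalization chain the values are. Raw counts must be non-negative
#' integers; all values must be finite.
#'
#' @param values named numeric vector (identifier -> value).
#' @param sample_id sample label.
#' @param id_space one of `"gene_symbol"`, `"ensembl"`, `"uniprot"`.
#' @param norm_state one of `"raw_counts"`, `"rpkm"`, `"rpkm_upper"`, `"uq"`,
#'   `"lognorm"`, `"log2"`, `"external"`.
#' @return An object of class `expression_vector`.
#' @export
expression_vector <- function(values, sample_id = "sample",
                              id_space = c("uniprot", "gene_symbol", "ensembl"),
                              norm_state = c("raw_counts", "rpkm", "rpkm_upper",
                                             "uq", "lognorm", "log2", "external")) {
  id_space <- match.arg(id_space)
  norm_state <- match.arg(norm_state)
  values <- unlist(values)
  if (length(values) > 0L) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      stop("expression values must be named by gene/protein identifier")
    if (any(!is.finite(values))) stop("expression values must be finite")
    if (norm_state == "raw_counts" && any(values < 0 | values != round(values)))
      stop("raw counts must be non-negative integers")
  } else {
    values <- stats::setNames(numeric(0), character(0))
  }
  structure(list(sample_id = sample_id, values = values,
                 id_space = id_space, norm_state = norm_state),
            class = "expression_vector")
}

#' @export
print.expression_vector <- function(x, ...) {
  cat(sprintf("expression_vector '%s': %d genes, id space %s, state %s\n",
              x$sample_id, length(x$values), x$id_space, x$norm_state))
  invisible(x)
}

#' Translate expression identifiers to UniProtKB accessions
#'
#' Applies a source-id to accession map (e.g. GeneSymbol->UniProtKB or
#' Ensembl->UniProtKB). Identifiers absent from the map are dropped and
#' counted; when several source ids map to the same accession their values
#' are summed, pooling transcript-level signal per protein.
#'
#' @param expr an [expression_vector()].
#' @param map named character vector, source id -> accession.
#' @return An `expression_vector` in the `uniprot` id space, with attribute
#'   `n_unmapped` giving the number of dropped identifiers.
#' @export
map_ids <- function(expr, map) {
  stopifnot(inherits(expr, "expression_vector"))
  if (length(map) == 0L) stop("empty identifier map")
  if (is.null(names(map)) || any(!nzchar(names(map))) || any(!nzchar(map)))
    stop("identifier map must have non-empty source ids and accessions")
  acc <- map[names(expr$values)]
  mapped <- !is.na(acc)
  merged <- tapply(expr$values[mapped], acc[mapped], sum)
  vals <- stats::setNames(as.numeric(merged), names(merged))
  out <- expression_vector(vals, sample_id = expr$sample_id,
                           id_space = "uniprot", norm_state = expr$norm_state)
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}
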