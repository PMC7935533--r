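#' Read an interactome from a tab-separated pair list
#'
#' Accepts plain two-column accession pair files as well as PSI-MITAB-like
#' files: only the first two tab-separated fields of each line are used and a
#' leading `uniprotkb:` prefix is stripped. Lines starting with `#` are
#' comments. Duplicate pairs (in either order) are collapsed, self-pairs are
#' dropped, and lines with fewer than two fields are skipped with a warning.
#'
#' @param path path to the pair-list file.
#' @return An [interactome()] with attribute `n_skipped` (malformed lines).
#' @export
read_interactome <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    out <- interactome(matrix(character(0), ncol = 2))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok))
    warning(sprintf("skipped %d line(s) with fewer than 2 fields in %s",
                    sum(!ok), path))
  pairs <- t(vapply(fields[ok], function(f) f[1:2], character(2)))
  pairs[] <- sub("^uniprotkb:", "", pairs)
  out <- interactome(pairs)
  if (out$n_self_dropped > 0L)
    message(sprintf("dropped %d self-interaction(s)", out$n_self_dropped))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Read a two-column expression file
#'
#' Expects `id<TAB>value` lines; lines starting with `#` are skipped.
#' Values must parse as finite non-negative reals, otherwise the offending
#' line is reported and reading aborts. Duplicate identifiers are aggregated
#' by summation and the number of merges is reported via `n_duplicates`.
#'
#' @param path path to the TSV file.
#' @param id_space identifier space of column 1 (see [expression_vector()]).
#' @param sample_id sample label; defaults to the file name without extension.
#' @param norm_state normalization state tag of the stored values.
#' @return An [expression_vector()] with attribute `n_duplicates`.
#' @export
read_expression <- function(path, id_space = "uniprot", sample_id = NULL,
                            norm_state = "raw_counts") {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- read_lines_checked(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(expression_vector(numeric(0), sample_id, id_space, norm_state))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad))
    stop(sprintf("%s line %d: expected 'id<TAB>value'", path, lineno[which(bad)[1]]))
  ids <- vapply(fields, `[[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  bad <- !is.finite(vals) | vals < 0
  if (any(bad))
    stop(sprintf("%s line %d: value is not a finite non-negative number",
                 path, lineno[which(bad)[1]]))
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0L) {
    merged <- tapply(vals, ids, sum)
    ids <- names(merged); vals <- as.numeric(merged)
    message(sprintf("%s: %d duplicated id(s) aggregated by sum", path, n_dup))
  }
  out <- expression_vector(stats::setNames(vals, ids), sample_id,
                           id_space, norm_state)
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Write an expression vector as a two-column TSV
#'
#' @param expr an [expression_vector()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_vector"))
  utils::write.table(
    data.frame(id = names(expr$values), value = unname(expr$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an identifier map (source id -> UniProtKB accession)
#'
#' TSV with two columns `source_id<TAB>accession`; `#` comments allowed.
#' If a source id occurs more than once the first mapping wins.
#'
#' @param path path to the map file.
#' @return Named character vector suitable for [map_ids()].
#' @export
read_id_map <- function(path) {
  tab <- read_two_columns(path)
  if (any(!nzchar(tab[[1]]) | !nzchar(tab[[2]])))
    stop(sprintf("%s: empty source id or accession", path))
  first <- !duplicated(tab[[1]])
  stats::setNames(tab[[2]][first], tab[[1]][first])
}

#' Read coding-sequence lengths
#'
#' TSV with columns `accession<TAB>length_bp`; lengths must be positive
#' integers (base pairs).
#'
#' @param path path to the annotation file.
#' @return Named integer vector of coding-sequence lengths.
#' @export
read_gene_lengths <- function(path) {
  tab <- read_two_columns(path)
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(!is.finite(len) | len <= 0 | len != round(len)))
    stop(sprintf("%s: coding-sequence lengths must be positive integers", path))
  stats::setNames(as.integer(len), tab[[1]])
}

#' Derive read counts per protein from BLASTx tabular output
#'
#' Parses the standard 12-column tabular format (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Each read
#' contributes one count to its single best-scoring subject by bit score;
#' ties go to the hit seen first in file order. Malformed lines are skipped
#' with a warning.
#'
#' @param path path to the BLASTx tabular file.
#' @param sample_id sample label; defaults to the file name without extension.
#' @return An [expression_vector()] of raw counts in the `uniprot` id space.
#' @export
counts_from_blastx <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(expression_vector(numeric(0), sample_id, "uniprot", "raw_counts"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  score <- suppressWarnings(
    as.numeric(vapply(fields, function(f) if (length(f) >= 12L) f[12L] else NA_character_,
                      character(1))))
  ok <- lengths(fields) >= 12L & is.finite(score)
  if (any(!ok))
    warning(sprintf("skipped %d malformed BLASTx line(s) in %s", sum(!ok), path))
  if (!any(ok))
    return(expression_vector(numeric(0), sample_id, "uniprot", "raw_counts"))
  read_id <- vapply(fields[ok], `[[`, character(1), 1L)
  subject <- vapply(fields[ok], `[[`, character(1), 2L)
  score <- score[ok]
  # best hit per read; stable order of ties = first occurrence in the file
  ord <- order(read_id, -score)
  best <- !duplicated(read_id[ord])
  counts <- table(subject[ord][best])
  expression_vector(stats::setNames(as.numeric(counts), names(counts)),
                    sample_id, "uniprot", "raw_counts")
}

#' Target report: write and read
#'
#' A target report bundles one patient's results: the critical value used for
#' up-regulation, the degree entropy of the up-regulated subnetwork (bits),
#' the ranked hub targets with their interactome degrees, and the run
#' parameters. `write_report()` serializes it as JSON; `read_report()` is its
#' inverse, so the pair round-trips losslessly.
#'
#' @param report a `target_report` as produced by [target_report()].
#' @param path JSON file path.
#' @return `read_report()` returns a `target_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "target_report"))
  doc <- list(patient_id = report$patient_id,
              critical_value = report$critical_value,
              entropy_bits = report$entropy_bits,
              targets = if (nrow(report$targets) == 0L) list() else
                lapply(seq_len(nrow(report$targets)), function(i)
                  list(accession = report$targets$accession[i],
                       degree = report$targets$degree[i])),
              parameters = report$parameters)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  targets <- if (length(doc$targets) == 0L)
    data.frame(accession = character(0), degree = integer(0))
  else
    data.frame(accession = vapply(doc$targets, `[[`, character(1), "accession"),
               degree = vapply(doc$targets, function(t) as.integer(t$degree),
                               integer(1)))
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  target_report(patient_id = doc$patient_id,
                critical_value = num_or_na(doc$critical_value),
                entropy_bits = num_or_na(doc$entropy_bits),
                targets = targets,
                parameters = doc$parameters)
}

#' Construct a target report
#'
#' @param patient_id patient label.
#' @param critical_value up-regulation threshold used.
#' @param entropy_bits degree entropy of the up-regulated subnetwork, in bits
#'   (`NA` when the subnetwork is empty).
#' @param targets data frame with columns `accession` and `degree`, sorted by
#'   degree descending, ties by accession ascending.
#' @param parameters named list echoing the run configuration.
#' @return An object of class `target_report`.
#' @export
target_report <- function(patient_id, critical_value, entropy_bits, targets,
                          parameters = list()) {
  stopifnot(is.data.frame(targets),
            all(c("accession", "degree") %in% names(targets)))
  if (nrow(targets) > 1L) {
    ord <- order(-targets$degree, targets$accession)
    if (!identical(ord, seq_len(nrow(targets)))) targets <- targets[ord, ]
  }
  rownames(targets) <- NULL
  structure(list(patient_id = patient_id,
                 critical_value = critical_value,
                 entropy_bits = entropy_bits,
                 targets = targets,
                 parameters = parameters),
            class = "target_report")
}

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

read_two_columns <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(V1 = character(0), V2 = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop(sprintf("%s: expected two tab-separated columns", path))
  data.frame(V1 = vapply(fields, `[[`, character(1), 1L),
             V2 = vapply(fields, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
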