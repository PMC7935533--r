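#' Read a patient manifest
#'
#' TSV with a header line and columns `patient_id`, `tumor_path`,
#' `control_path`; `#` comments allowed. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest file path.
#' @return Data frame with the three columns, paths resolved.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("patient_id", "tumor_path", "control_path")
  if (!all(need %in% names(tab)))
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  base <- dirname(normalizePath(path))
  for (col in c("tumor_path", "control_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", tab[[col]])
    tab[[col]][rel] <- file.path(base, tab[[col]][rel])
  }
  tab[, need]
}

#' Run the hub-diagnosis pipeline on a patient cohort
#'
#' Chains the full analysis for every patient in a manifest: read the paired
#' tumor/control expression files, optionally translate identifiers to
#' UniProtKB, normalize (default: `rpkm_upper` with delta = 0.05 followed by
#' `log2norm` — the recommended compromise), subtract control from tumor,
#' fit the Gaussian null and derive the critical value at probability `p`,
#' select up-regulated genes, build their induced interactome subnetwork,
#' score its degree entropy, and rank the top-n hub targets by full
#' interactome degree. One JSON target report per patient and a cohort
#' summary TSV are written when `out_dir` is given.
#'
#' A patient whose processing fails is skipped with a warning; the run
#' errors only if every patient fails.
#'
#' @param manifest data frame from [read_manifest()] (or a path to one).
#' @param interactome an [interactome()] (or a path readable by
#'   [read_interactome()]).
#' @param lengths named coding-sequence lengths, required for count
#'   normalization (or a path readable by [read_gene_lengths()]).
#' @param id_map optional named map to UniProtKB (or a path readable by
#'   [read_id_map()]).
#' @param method normalization method (see [normalize_counts()]) or
#'   `"none"` for inputs that are already normalized.
#' @param id_space identifier space of the expression files.
#' @param norm_state_in normalization state tag of the input files
#'   (`"raw_counts"` for counts; `"external"` with `method = "none"` for
#'   pre-normalized data).
#' @param p one-tail cumulative probability of the critical value.
#' @param fit_range differential interval for the Gaussian fit.
#' @param top_n number of hub targets to report.
#' @param delta,C,b_lognorm,b_log2 normalization constants (see [rpkm()]).
#' @param out_dir optional output directory for per-patient JSON reports and
#'   `cohort_summary.tsv`.
#' @return Invisibly, a list with `reports` (per-patient `target_report`s),
#'   `upregulated` (per-patient accession lists), `summary` (data frame:
#'   patient_id, critical_value, n_vertices, entropy_bits) and `failed`
#'   (named character vector of skip reasons).
#' @export
run_pipeline <- function(manifest, interactome, lengths = NULL, id_map = NULL,
                         method = "chain", id_space = "uniprot",
                         norm_state_in = "raw_counts",
                         p = 0.975, fit_range = c(-20000, 20000), top_n = 20,
                         delta = 0.05, C = 20, b_lognorm = 1.1, b_log2 = 2,
                         out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(interactome)) interactome <- read_interactome(interactome)
  if (is.character(lengths)) lengths <- read_gene_lengths(lengths)
  if (is.character(id_map)) id_map <- read_id_map(id_map)
  if (nrow(manifest) < 1L) stop("manifest lists no patients")
  if (method != "none" && is.null(lengths))
    stop("count normalization requires coding-sequence lengths")
  params <- list(method = method, delta = delta, C = C, b_lognorm = b_lognorm,
                 b_log2 = b_log2, p = p, fit_range = fit_range, top_n = top_n)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  reports <- list(); upregulated <- list(); failed <- character(0)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    res <- tryCatch({
      prep <- function(path, tag) {
        ev <- read_expression(path, id_space = id_space,
                              sample_id = paste0(pid, "_", tag),
                              norm_state = norm_state_in)
        if (!is.null(id_map)) ev <- map_ids(ev, id_map)
        if (method != "none")
          ev <- normalize_counts(ev, lengths, method, delta, C, b_lognorm, b_log2)
        ev
      }
      tumor <- prep(manifest$tumor_path[i], "tumor")
      control <- prep(manifest$control_path[i], "control")
      prof <- differential_expression(tumor, control, patient_id = pid,
                                      fit_range = fit_range, p = p)
      prof <- critical_value(fit_null(prof))
      up <- select_upregulated(prof)
      sub <- build_subnetwork(up, interactome)
      h <- if (n_vertices(sub) > 0L) shannon_entropy(degree_counts(sub)) else NA_real_
      targets <- rank_hubs(up, interactome, n = top_n)
      report <- target_report(pid, prof$critical_value, h, targets, params)
      list(report = report, up = up,
           row = data.frame(patient_id = pid,
                            critical_value = prof$critical_value,
                            n_vertices = n_vertices(sub),
                            entropy_bits = h))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("patient '%s' skipped: %s", pid, conditionMessage(res)))
      failed[pid] <- conditionMessage(res)
      next
    }
    reports[[pid]] <- res$report
    upregulated[[pid]] <- res$up
    rows[[pid]] <- res$row
    if (!is.null(out_dir))
      write_report(res$report, file.path(out_dir, paste0(pid, "_report.json")))
  }
  if (length(reports) == 0L)
    stop("all patients failed; nothing to report")
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    utils::write.table(summary, file.path(out_dir, "cohort_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reports = reports, upregulated = upregulated,
                 summary = summary, failed = failed))
}
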