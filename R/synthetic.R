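#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The generator
#' emulates the statistical structure the pipeline assumes: a scale-free
#' interactome, paired tumor/control profiles whose non-differential bulk is
#' Gaussian on the tumor-minus-control axis, heavy-tailed expression
#' magnitudes, and cohorts in which hub up-regulation is inversely tied to
#' survival.
#'
#' @param seed integer RNG seed; all generator functions derive their streams
#'   from it, so outputs are fully reproducible.
#' @param n_proteins number of proteins in the interactome.
#' @param attachment_edges edges added per vertex during preferential
#'   attachment (scale-free growth parameter m).
#' @param n_patients patients per cohort (per cancer type in
#'   [generate_cohort()]).
#' @param null_sigma SD of the Gaussian differential noise, in expression
#'   units.
#' @param n_injected number of truly up-regulated genes injected per patient.
#' @param effect_size injected differential shift, in units of `null_sigma`.
#' @param hub_bias exponent >= 0 biasing injection toward high-degree
#'   vertices (probability proportional to degree^hub_bias; 0 = uniform).
#' @param os_coupling strength (>= 0) of the negative link between cohort
#'   subnetwork complexity and 5-year overall survival; 0 decouples them.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 42L, n_proteins = 2000L,
                              attachment_edges = 2L, n_patients = 10L,
                              null_sigma = 1000, n_injected = 100L,
                              effect_size = 10, hub_bias = 1,
                              os_coupling = 1) {
  stopifnot(n_proteins >= attachment_edges + 1L,
            n_injected < n_proteins,
            null_sigma > 0, effect_size >= 0, hub_bias >= 0, os_coupling >= 0,
            n_patients >= 1L)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 attachment_edges = as.integer(attachment_edges),
                 n_patients = as.integer(n_patients),
                 null_sigma = null_sigma, n_injected = as.integer(n_injected),
                 effect_size = effect_size, hub_bias = hub_bias,
                 os_coupling = os_coupling),
            class = "simulation_config")
}

#' Generate a scale-free interactome
#'
#' Simple connected undirected graph grown by preferential attachment
#' (Barabási–Albert), so few proteins have high connectivity and many have
#' low connectivity. Vertices are named `P0001`-style accessions.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return An [interactome()].
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- igraph::sample_pa(config$n_proteins, power = 1,
                         m = config$attachment_edges, directed = FALSE)
  g <- igraph::simplify(g)
  width <- max(4L, nchar(as.character(config$n_proteins)))
  igraph::V(g)$name <- sprintf(paste0("P%0", width, "d"),
                               seq_len(config$n_proteins))
  structure(list(graph = g, n_self_dropped = 0L, n_dup_dropped = 0L),
            class = "interactome")
}

#' Generate one paired tumor/control profile with known truth
#'
#' Control expression is drawn from a baseline-offset log-normal law
#' (positive, heavy right tail). The tumor profile adds Gaussian differential
#' noise `N(0, null_sigma^2)` to every gene, plus a shift of
#' `effect_size * null_sigma` for `n_injected` truth genes chosen with
#' probability proportional to interactome degree raised to `hub_bias`.
#' The tumor-minus-control profile is therefore exactly Gaussian for null
#' genes, matching the model the critical-value fit assumes.
#'
#' @param config a [simulation_config()].
#' @param interactome the [interactome()] the patient's proteins live on.
#' @param patient_index 1-based index decorrelating patients generated from
#'   one config; patient `i` is reproducible in isolation.
#' @return List with `tumor` and `control` [expression_vector()]s (norm
#'   state `external`), `truth` (character vector of injected accessions)
#'   and `patient_id`.
#' @export
generate_patient <- function(config, interactome, patient_index = 1L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(interactome, "interactome"))
  set.seed(config$seed + 7919L * as.integer(patient_index))
  acc <- interactome_vertices(interactome)
  n <- length(acc)
  control <- 10 * config$null_sigma +
    stats::rlnorm(n, meanlog = log(5 * config$null_sigma), sdlog = 1)
  deg <- interactome_degree(interactome)
  truth <- sample(acc, config$n_injected, prob = deg[acc]^config$hub_bias)
  noise <- stats::rnorm(n, 0, config$null_sigma)
  shift <- ifelse(acc %in% truth, config$effect_size * config$null_sigma, 0)
  tumor <- control + noise + shift
  pid <- sprintf("patient%03d", as.integer(patient_index))
  list(tumor = expression_vector(stats::setNames(tumor, acc),
                                 paste0(pid, "_tumor"), "uniprot", "external"),
       control = expression_vector(stats::setNames(control, acc),
                                   paste0(pid, "_control"), "uniprot", "external"),
       truth = sort(truth),
       patient_id = pid)
}

#' Generate a multi-cancer-type cohort with entropy-coupled survival
#'
#' Creates one shared interactome and, for each cancer type, a set of paired
#' patients whose injected up-regulation grows with the type's configured
#' complexity: type complexity scales `n_injected`, and 5-year overall
#' survival decreases linearly with complexity at strength `os_coupling`
#' (with `os_coupling = 0` survival is shuffled independently of
#' complexity). The returned truth table records the intended design so
#' pipeline estimates can be validated against it.
#'
#' @param config a [simulation_config()].
#' @param cancer_types character vector of type labels (>= 3).
#' @return List with `interactome`, `patients` (named list per type, each a
#'   list of [generate_patient()] outputs) and `cohort_table` (data frame:
#'   `cancer_type`, `five_year_os`, `n_injected`).
#' @export
generate_cohort <- function(config,
                            cancer_types = paste0("CT", 1:6)) {
  stopifnot(inherits(config, "simulation_config"), length(cancer_types) >= 3L)
  interactome <- generate_interactome(config)
  k <- length(cancer_types)
  complexity <- (seq_len(k) - 1) / (k - 1)
  n_inj <- pmin(as.integer(round(config$n_injected * (0.5 + 1.5 * complexity))),
                config$n_proteins - 1L)
  os <- 85 - 60 * complexity
  set.seed(config$seed + 104729L)
  if (config$os_coupling == 0) {
    os <- sample(os)
  } else {
    os <- pmin(100, pmax(0, 85 - config$os_coupling * 60 * complexity))
  }
  patients <- vector("list", k)
  names(patients) <- cancer_types
  for (t in seq_len(k)) {
    cfg_t <- config
    cfg_t$n_injected <- n_inj[t]
    cfg_t$seed <- config$seed + 1009L * t
    patients[[t]] <- lapply(seq_len(config$n_patients), function(i)
      generate_patient(cfg_t, interactome, i))
  }
  list(interactome = interactome,
       patients = patients,
       cohort_table = data.frame(cancer_type = cancer_types,
                                 five_year_os = os,
                                 n_injected = n_inj))
}
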