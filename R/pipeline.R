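#' Pipeline run configuration
#'
#' Exactly one cohort source and one network source must be given: a
#' synthetic cohort specification or a cohort CSV; the packaged hepatocyte
#' network or a network file (SBML or table dialect). All seeds are recorded
#' in the run manifest.
#'
#' @param cohort_spec a [cohort_spec()] (synthetic cohort source).
#' @param cohort_csv path to a cohort CSV (alternative source).
#' @param network \code{"toy"} or a path to a network file.
#' @param mode solve mode, \code{"min_sum"} or \code{"sampled_mean"}.
#' @param seed base RNG seed for solving/sampling.
#' @param n_samples samples per subject in sampling mode.
#' @param metabolome \code{"synthetic"}, a metabolite CSV path, or
#'   \code{NULL} to skip the metabolomics stage.
#' @param out_dir output directory for [run_pipeline()].
#' @param const physiology constants.
#' @param profiles amino-acid profile table.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(cohort_spec = NULL, cohort_csv = NULL,
                       network = "toy", mode = c("min_sum", "sampled_mean"),
                       seed = 1, n_samples = 100, metabolome = "synthetic",
                       out_dir = tempfile("steatoflux_run_"),
                       const = physiology_constants(),
                       profiles = aa_profiles()) {
  mode <- match.arg(mode)
  if (is.null(cohort_spec) == is.null(cohort_csv))
    stop("exactly one of cohort_spec / cohort_csv must be given")
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("cohort CSV not found: ", cohort_csv)
  if (!identical(network, "toy") && !file.exists(network))
    stop("network file not found: ", network)
  structure(list(cohort_spec = cohort_spec, cohort_csv = cohort_csv,
                 network = network, mode = mode, seed = as.integer(seed),
                 n_samples = n_samples, metabolome = metabolome,
                 out_dir = out_dir, const = const, profiles = profiles),
            class = "run_config")
}

#' The packaged demonstration configuration
#'
#' One-call profile running the full synthetic pipeline: 86-subject cohort,
#' packaged hepatocyte network, parsimonious solves, synthetic metabolome.
#'
#' @param seed RNG seed (cohort, solving and metabolome all derive from it).
#' @param out_dir output directory.
#' @param ... overrides forwarded to [run_config()].
#' @return a \code{run_config}.
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("steatoflux_demo_"), ...) {
  run_config(cohort_spec = cohort_spec(n_subjects = 86, seed = seed),
             seed = seed, out_dir = out_dir, ...)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - cohort, personalized constraints, network
#' solves, flux-phenotype associations, plasma-metabolomics statistics (when
#' a metabolome source is configured) - and writes every output plus a run
#' manifest (configuration echo, seeds, package version, config checksum) to
#' the output directory. Any stage failure halts the run with an error naming
#' the stage.
#'
#' Outputs: \code{cohort.csv}, \code{bounds/<id>.csv},
#' \code{flux_matrix.csv} (with solve status), \code{associations.csv}
#' (reaction, subsystem, r/p versus liver fat and versus net fat influx),
#' \code{nfi.csv}, \code{metabolites_welch.csv},
#' \code{metabolites_hs_corr.csv}, \code{manifest.json}.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; the manifest list as
#'   attribute \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_spec)) generate_cohort(config$cohort_spec)
    else read_cohort_csv(config$cohort_csv)
  })
  write_cohort_csv(cohort, out("cohort.csv"))

  network <- stage("network", {
    if (identical(config$network, "toy"))
      build_toy_hepatocyte_network(config$profiles, config$const)
    else load_network(config$network)
  })

  stage("constraints", {
    dir.create(out("bounds"), showWarnings = FALSE)
    for (i in seq_len(nrow(cohort))) {
      eb <- assemble_subject_bounds(cohort[i, ], config$profiles, config$const)
      write_exchange_bounds(eb, out("bounds", paste0(cohort$id[i], ".csv")))
    }
  })

  fm <- stage("solve", {
    solve_cohort(cohort, network, config$mode, seed = config$seed,
                 n_samples = config$n_samples,
                 profiles = config$profiles, const = config$const)
  })
  utils::write.csv(data.frame(id = fm$ids, status = fm$status,
                              fm$fluxes, check.names = FALSE),
                   out("flux_matrix.csv"), row.names = FALSE)

  stage("associations", {
    nfi <- net_fat_influx(fm, network, config$const)
    utils::write.csv(data.frame(id = fm$ids, nfi = nfi), out("nfi.csv"),
                     row.names = FALSE)
    hs_tab <- correlate_fluxes(fm, cohort$liver_fat_pct, "HS")
    nfi_tab <- correlate_fluxes(fm, nfi, "NFI")
    assoc <- data.frame(
      reaction = hs_tab$reaction,
      subsystem = network$reactions$subsystem[
        match(hs_tab$reaction, network$reactions$id)],
      r_HS = hs_tab$r, p_HS = hs_tab$p,
      r_NFI = nfi_tab$r[match(hs_tab$reaction, nfi_tab$reaction)],
      p_NFI = nfi_tab$p[match(hs_tab$reaction, nfi_tab$reaction)],
      n = hs_tab$n, stringsAsFactors = FALSE)
    utils::write.csv(assoc, out("associations.csv"), row.names = FALSE)
  })

  if (!is.null(config$metabolome)) {
    stage("metabostats", {
      mat <- if (identical(config$metabolome, "synthetic"))
        generate_metabolome(cohort, seed = config$seed + 1000L)
      else read_metabolite_csv(config$metabolome)
      write_metabolite_csv(mat, out("metabolome.csv"))
      lm <- log_transform(mat)
      groups <- ifelse(cohort$liver_fat_pct >= 5.5, "high", "low")
      utils::write.csv(welch_tests(lm, groups), out("metabolites_welch.csv"),
                       row.names = FALSE)
      utils::write.csv(hs_correlations(lm, cohort$liver_fat_pct,
                                       min_detected = min(30, nrow(mat))),
                       out("metabolites_hs_corr.csv"), row.names = FALSE)
    })
  }

  cfg_echo <- list(
    cohort_source = if (!is.null(config$cohort_spec)) "synthetic" else
      config$cohort_csv,
    n_subjects = nrow(cohort),
    network = if (identical(config$network, "toy")) "toy" else config$network,
    mode = config$mode,
    seeds = list(solve = config$seed,
                 cohort = if (!is.null(config$cohort_spec))
                   config$cohort_spec$seed,
                 metabolome = if (identical(config$metabolome, "synthetic"))
                   config$seed + 1000L),
    n_samples = config$n_samples)
  manifest <- list(
    package = "steatoflux",
    version = tryCatch(as.character(utils::packageVersion("steatoflux")),
                       error = function(e) "dev"),
    config = cfg_echo,
    config_checksum = unname(tools::md5sum(out("cohort.csv"))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  structure(invisible(config$out_dir), manifest = manifest)
}
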