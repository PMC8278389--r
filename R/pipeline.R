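#' Default pipeline configuration
#'
#' Flat list of every tunable the pipeline uses, with the method's
#' standard operating points: 2 percent mean neighbor fraction for the
#' density cutoff, 300 K, 72 profile bins (5 degrees), 36 fingerprint
#' bins (10 degrees), Euclidean metric with rounded barrier weights.
#'
#' @param ... overrides as `name = value` pairs.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(temperature = 300,
              profile_bins = 72,
              fingerprint_bins = 36,
              neighbor_fraction = 0.02,
              metric_form = "euclidean",
              use_rounded_weights = TRUE,
              center_mode = "auto",
              rho_min = NULL, delta_min = NULL, k = NULL, centers = NULL,
              halo = "center-cutoff",
              support_min_count = 1,
              tie_break = "product",
              seed = 1L,
              barriers = NULL,
              bias_column = NULL,
              energy_columns = NULL,
              reference_cluster = NULL,
              n_boot = 200)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full conformational-analysis pipeline
#'
#' Chains every stage on a reference trajectory (and optionally a second,
#' possibly biased, trajectory to classify): barrier weights, distance
#' matrix, density-peaks clustering, fingerprints, classification, and —
#' when bias/energy columns are present — reweighted populations and the
#' free-energy decomposition. All artifacts are written to `out_dir` in
#' stable text/binary formats, together with a machine-readable run log
#' of every parameter used. Reruns with identical inputs and config are
#' byte-identical.
#'
#' @param reference a [dihedral_trajectory()] (or path readable by
#'   [read_colvar()]) used to define the conformers.
#' @param out_dir output directory (created if needed).
#' @param target optional trajectory (or path) to classify and analyze
#'   thermodynamically; defaults to the reference itself.
#' @param config list from [default_config()].
#' @return invisibly, a list with the fit, classification and (if
#'   computed) the thermodynamic report.
#' @export
run_pipeline <- function(reference, out_dir, target = NULL,
                         config = default_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.character(reference))
    reference <- stage("read", read_colvar(reference,
                                           bias_column = config$bias_column))
  if (is.character(target))
    target <- stage("read", read_colvar(target,
                                        bias_column = config$bias_column))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  weights <- stage("weights", {
    if (!is.null(config$barriers)) compute_weights(config$barriers)
    else NULL
  })
  fit <- stage("cluster", conformer_clust(
    reference, weights = weights,
    neighbor_fraction = config$neighbor_fraction,
    form = config$metric_form, use_rounded = config$use_rounded_weights,
    mode = config$center_mode, rho_min = config$rho_min,
    delta_min = config$delta_min, k = config$k, centers = config$centers,
    halo = config$halo, fingerprint_bins = config$fingerprint_bins,
    support_min_count = config$support_min_count,
    profile_bins = config$profile_bins, keep_distance = TRUE))

  stage("write", {
    jsonlite::write_json(
      list(raw = fit$weights$raw, normalized = fit$weights$normalized,
           rounded = fit$weights$rounded),
      file.path(out_dir, "weights.json"), digits = I(17), auto_unbox = FALSE)
    write_distance_matrix(fit$distance, file.path(out_dir, "dist.bin"))
    utils::write.table(decision_graph(fit$clustering),
                       file.path(out_dir, "decision_graph.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_cluster_model(fit$clustering, file.path(out_dir, "clusters.json"))
    write_fingerprints(fit$fingerprints,
                       file.path(out_dir, "fingerprints.json"))
  })

  if (is.null(target)) target <- reference
  cls <- stage("classify", predict(fit, newdata = target,
                                   tie_break = config$tie_break))
  stage("write", utils::write.csv(
    data.frame(frame = seq_along(cls$labels),
               time = target$time %||% (seq_along(cls$labels) - 1),
               label = cls$labels,
               score = apply(cls$scores, 1, max)),
    file.path(out_dir, "labels.csv"), row.names = FALSE))

  thermo <- NULL
  if (!is.null(target$bias) || !is.null(target$energy_solute)) {
    thermo <- stage("thermo", {
      fw <- if (!is.null(target$bias))
        reweight(target$bias, config$temperature) else NULL
      if (!is.null(target$energy_solute)) {
        ids <- sort(unique(cls$labels[cls$labels > 0]))
        ref_cl <- config$reference_cluster %||%
          ids[which.max(vapply(ids, function(c) sum(cls$labels == c),
                               numeric(1)))]
        thermo_report(target, cls, fw, reference = ref_cl,
                      temperature = config$temperature,
                      n_boot = config$n_boot, seed = config$seed)
      } else {
        pops <- cluster_populations(cls, fw)
        structure(list(table = data.frame(
          cluster = as.integer(sub("^C", "", names(pops$P))),
          P = unname(pops$P)),
          reference = NA, unclassified = pops$unclassified,
          temperature = config$temperature), class = "thermo_report")
      }
    })
    stage("write", utils::write.csv(thermo$table,
                                    file.path(out_dir, "thermo.csv"),
                                    row.names = FALSE))
  }

  stage("log", {
    log <- list(package = "torsmap",
                version = as.character(utils::packageVersion("torsmap")),
                r_version = paste(R.version$major, R.version$minor, sep = "."),
                config = config[!vapply(config, is.function, logical(1))],
                n_frames_reference = n_frames(reference),
                n_frames_target = n_frames(target),
                n_clusters = length(fit$centers),
                d_c = fit$clustering$d_c,
                fraction_classified = cls$fraction_classified)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         digits = I(17), auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  })
  invisible(list(fit = fit, classified = cls, thermo = thermo))
}
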