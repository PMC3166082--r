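#' Default pipeline configuration
#'
#' Returns the full end-to-end run configuration with the canonical
#' analysis settings: activity threshold 50.0\%, 200 bootstrap folds,
#' 1000 response permutations, 0.85 Tanimoto cutoff, the default
#' \code{\link{forestSpec}}, and the default synthetic-data generator.
#' Every entry can be overridden through \code{...}.
#'
#' @param seed master seed.
#' @param ... named overrides of the defaults.
#' @return named list (class \code{RunConfig}).
#' @export
runConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    threshold = 50.0,
    replicate_sd = 16,
    n_bootstrap = 200L,
    n_permutations = 1000L,
    similarity_cutoff = 0.85,
    beam_width = 10L,
    max_combination_size = 5L,
    score_resamples = 30L,
    candidate_q = 30L,
    forest = forestSpec(),
    generator = generatorConfig(seed = as.integer(seed)),
    stages = c("synth", "descriptors", "activity", "train", "yscramble",
               "diversity", "screen"),
    screen_kind = "natural_like")
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on a synthetic or user-supplied
#' compound set: descriptor matrix construction, activity thresholding and
#' bimodality analysis, beam-search descriptor selection with bootstrap
#' validation, Y-scrambling, structural diversity, and virtual screening
#' with group enrichment. Each enabled stage appends its outputs to the
#' run report; when \code{outdir} is given, stage outputs are written as
#' CSV/JSON next to a manifest (seed, parameters, package version) from
#' which every value is recomputable.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param data optional list(compounds, structures) to use instead of the
#'   synthetic stage.
#' @param outdir optional output directory.
#' @return named list with one element per executed stage.
#' @export
runPipeline <- function(config = runConfig(), data = NULL, outdir = NULL) {
  report <- list(manifest = list(
    seed = config$seed, threshold = config$threshold,
    n_bootstrap = config$n_bootstrap,
    n_permutations = config$n_permutations,
    similarity_cutoff = config$similarity_cutoff,
    package_version = as.character(utils::packageVersion("lysoSPAR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  stage <- function(name) name %in% config$stages
  if (is.null(data)) {
    if (!stage("synth"))
      stop("no input data and synth stage disabled", call. = FALSE)
    data <- generateExperimentalSet(config$generator)
    report$synth <- list(n = nCompounds(data$compounds),
                         class_counts = unname(table(data$truth$class)))
  }
  compounds <- data$compounds
  structures <- data$structures
  X <- buildDescriptorMatrix(compounds, structures,
    extra_columns = grep("^noise", names(compoundData(compounds)),
                         value = TRUE))
  report$descriptors <- list(n_descriptors = ncol(X),
                             names = colnames(X))
  d <- compoundData(compounds)
  calls <- classifyActivity(d$residual_activity, sd = config$replicate_sd,
                            ids = d$id, threshold = config$threshold)
  y <- calls$class
  report$activity <- list(
    n_active = sum(y == 1L), n_inactive = sum(y == 0L),
    zero_rule = zeroRule(y),
    bimodality = bimodalityAnalysis(d$residual_activity,
                                    split = config$threshold))
  if (stage("train")) {
    Xc <- X[, complete.cases(t(X)), drop = FALSE]
    candidates <- selectCandidates(Xc, y, q = config$candidate_q)
    beam <- beamSearch(Xc, y, candidates, beam_width = config$beam_width,
                       max_size = config$max_combination_size,
                       spec = config$forest,
                       n_resamples = config$n_bootstrap,
                       score_resamples = config$score_resamples,
                       seed = fanSeed(config$seed, 21L))
    combo <- beam[[length(beam)]]$descriptors
    # per-size table in the shape of a descriptor-combination report
    report$train <- list(
      candidates = candidates,
      combinations = data.frame(
        size = seq_along(beam),
        descriptors = vapply(beam, function(b)
          paste(b$descriptors, collapse = "+"), ""),
        youden_mean = vapply(beam, function(b) meanYouden(b$report), 0),
        youden_sd = vapply(beam, function(b) sdYouden(b$report), 0),
        accuracy_mean = vapply(beam, function(b) meanAccuracy(b$report), 0),
        accuracy_sd = vapply(beam, function(b) sdAccuracy(b$report), 0)),
      final = beam[[length(beam)]])
    model <- fitForest(Xc[, combo, drop = FALSE], y, config$forest)
    report$model <- model
    if (stage("yscramble")) {
      ys <- yScramble(Xc, y, combo, spec = config$forest,
                      n_permutations = config$n_permutations,
                      n_resamples = config$n_bootstrap,
                      seed = fanSeed(config$seed, 22L))
      report$yscramble <- list(
        n_permutations = config$n_permutations,
        scaled_down = config$n_permutations < 1000L,
        null_youden_mean = ys$null_youden_mean,
        null_youden_sd = ys$null_youden_sd,
        null_accuracy_mean = ys$null_accuracy_mean,
        null_accuracy_sd = ys$null_accuracy_sd,
        z_youden = ys$z_youden)
    }
  }
  if (stage("diversity") && length(structures)) {
    div_all <- structuralDiversity(structures,
                                   cutoff = config$similarity_cutoff)
    act <- intersect(names(structures), calls$id[calls$class == 1L])
    div_act <- if (length(act) >= 2L)
      structuralDiversity(structures[act],
                          cutoff = config$similarity_cutoff) else NULL
    report$diversity <- list(
      whole_set = div_all[c("div_rel", "n_clusters", "n")],
      actives = if (!is.null(div_act))
        div_act[c("div_rel", "n_clusters", "n")])
  }
  if (stage("screen") && !is.null(report$model)) {
    lib <- generateLibrary(config$generator, kind = config$screen_kind)
    scr <- virtualScreen(lib$compounds, report$model, lib$structures)
    enr <- tryCatch(
      groupEnrichment(predictions(scr),
                      data.frame(id = compoundIds(lib$compounds),
                                 group = compoundData(lib$compounds)$atc_codes),
                      mc_seed = fanSeed(config$seed, 23L)),
      error = function(e) NULL)
    report$screen <- list(result = scr, enrichment = enr)
  }
  if (!is.null(outdir)) .writeRunOutputs(report, outdir)
  report
}

.writeRunOutputs <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(report$train))
    write.csv(report$train$combinations,
              file.path(outdir, "descriptor_combinations.csv"),
              row.names = FALSE)
  summary_ <- list(
    activity = report$activity[c("n_active", "n_inactive", "zero_rule")],
    bimodality = report$activity$bimodality[
      c("ks_p_overall", "means", "sds", "weights")],
    yscramble = report$yscramble,
    diversity = report$diversity)
  if (!is.null(report$screen)) {
    scr <- report$screen$result
    summary_$screen <- list(
      library = scr@library_tag, n_input = scr@n_input,
      n_excluded_incalculable = scr@n_excluded_incalculable,
      n_excluded_quaternary = scr@n_excluded_quaternary,
      n_excluded_duplicates = scr@n_excluded_duplicates,
      n_screened = nScreened(scr),
      n_predicted_active = sum(predictions(scr)$predicted_class == 1L))
    if (!is.null(report$screen$enrichment))
      write.csv(report$screen$enrichment$table,
                file.path(outdir, "enrichment.csv"), row.names = FALSE)
  }
  jsonlite::write_json(summary_, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}
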