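#' Assemble a full-study run configuration
#'
#' Collects every threshold of the analysis in one place. The defaults are
#' the conventional values used throughout: genome-wide significance 5e-8
#' for instruments, LD clumping at r-squared < 0.001 within 10,000 kb,
#' weak-instrument rule mean F < 10, confounder-association threshold
#' 1e-5, and screening alpha 0.05.
#'
#' @param simulate A [sim_config()] describing the synthetic triple, or
#'   \code{NULL} when \code{paths} supplies real tables.
#' @param paths Named list of TSV paths (\code{exposure, mediator,
#'   outcome}) read with [read_sumstats()]; ignored when \code{simulate}
#'   is given.
#' @param p_exposure,clump_r2,clump_kb,f_min,confounder_p,alpha Thresholds.
#' @param confounder_traits Traits screened by [confounder_filter()];
#'   defaults to the usual pancreatic-cancer risk factors.
#' @param effects,n_boot,phi Estimator options (see [mr_fit()]).
#' @param seed Global seed; per-stage streams are derived from it.
#' @param out_dir Output directory for [run_full_study()].
#' @return A validated list of class \code{"run_config"}.
#' @export
run_config <- function(simulate = NULL, paths = NULL,
                       p_exposure = 5e-8, clump_r2 = 0.001,
                       clump_kb = 10000, f_min = 10, confounder_p = 1e-5,
                       alpha = 0.05,
                       confounder_traits = c("BMI", "smoking", "drinking",
                                             "diabetes", "pancreatitis"),
                       effects = "random", n_boot = 1000, phi = 1,
                       seed = 42L, out_dir = NULL) {
  for (nm in c("p_exposure", "clump_r2", "clump_kb", "f_min",
               "confounder_p", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop_config(nm, " must be a positive number")
  }
  if (is.null(simulate) && is.null(paths))
    stop_config("either a simulation block or input paths are required")
  structure(list(simulate = simulate, paths = paths,
                 p_exposure = p_exposure, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 confounder_p = confounder_p, alpha = alpha,
                 confounder_traits = confounder_traits,
                 effects = effects, n_boot = n_boot, phi = phi,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()] arguments; a \code{simulate:} block is
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

#' Run the full MR + mediation study
#'
#' Orchestrates simulate (or load) -> harmonize -> instrument selection ->
#' five-method estimation -> sensitivity diagnostics -> exposure screening
#' (including reverse MR) -> two-step mediation, from one configuration.
#' With an output directory set, writes the estimates table, sensitivity
#' report, screening report, mediation table and a JSON run manifest;
#' identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class \code{"mr_study"}: \code{fit} (forward
#'   [mr_fit()]), \code{sensitivity}, \code{screen}, \code{reverse},
#'   \code{mediation}, \code{instruments}, and \code{manifest}.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    simcfg <- config$simulate
    simcfg$seed <- derive_seed(config$seed, "simulate")
    trip <- stage("simulate", simulate_triple(simcfg))
    exposure <- trip$exposure; mediator <- trip$mediator
    outcome <- trip$outcome
    ld <- ld_matrix(simcfg)
  } else {
    exposure <- stage("load", read_sumstats(config$paths$exposure))
    mediator <- if (!is.null(config$paths$mediator))
      stage("load", read_sumstats(config$paths$mediator)) else NULL
    outcome <- stage("load", read_sumstats(config$paths$outcome))
    ld <- if (!is.null(config$paths$ld))
      stage("load", read_ld_table(config$paths$ld)) else NULL
    trip <- NULL
  }
  annotations <- if (!is.null(config$paths$annotations))
    utils::read.delim(config$paths$annotations, stringsAsFactors = FALSE)
  else NULL

  sel <- stage("select_instruments",
               select_instruments(exposure, ld = ld,
                                  annotations = annotations,
                                  p_threshold = config$p_exposure,
                                  r2_max = config$clump_r2,
                                  window_kb = config$clump_kb,
                                  confounder_p = config$confounder_p,
                                  confounder_traits = config$confounder_traits,
                                  f_min = config$f_min))
  pairs <- stage("harmonize", harmonize(sel$instruments, outcome))
  fit <- stage("mr_fit",
               mr_fit(pairs, effects = config$effects,
                      n_boot = config$n_boot, phi = config$phi,
                      seed = derive_seed(config$seed, "mr_fit")))
  sens <- stage("sensitivity",
                mr_sensitivity(pairs, alpha = config$alpha,
                               effects = config$effects))
  rev <- stage("reverse_mr",
               reverse_mr(outcome, exposure, ld = ld,
                          annotations = annotations, alpha = config$alpha,
                          p_threshold = config$p_exposure,
                          r2_max = config$clump_r2,
                          window_kb = config$clump_kb,
                          confounder_p = config$confounder_p,
                          confounder_traits = config$confounder_traits,
                          f_min = config$f_min))
  screen <- stage("screen", screen_exposures(
    stats::setNames(list(list(fit = fit,
                              intercept_pval = sens$egger$pval,
                              reverse = rev)),
                    attr(exposure, "trait_label") %||% "exposure"),
    alpha = config$alpha))

  mediation <- if (!is.null(mediator)) stage("mediation", tryCatch(
    mr_mediation(exposure, mediator, outcome, ld = ld,
                 annotations = annotations,
                 p_threshold = config$p_exposure,
                 r2_max = config$clump_r2, window_kb = config$clump_kb,
                 confounder_p = config$confounder_p, f_min = config$f_min,
                 effects = config$effects),
    mrmediate_no_instruments_error = function(e) {
      warning("mediation not computable: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })) else NULL

  manifest <- list(
    seed = config$seed,
    thresholds = config[c("p_exposure", "clump_r2", "clump_kb", "f_min",
                          "confounder_p", "alpha")],
    estimator = config[c("effects", "n_boot", "phi")],
    n_instruments = nrow(sel$instruments),
    mean_f = sel$f$mean_f,
    stage_counts = as.list(attr(screen, "stage_counts")),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("mrmediate"))
  )

  res <- structure(list(fit = fit, sensitivity = sens, screen = screen,
                        reverse = rev, mediation = mediation,
                        instruments = sel, triple = trip,
                        manifest = manifest, config = config),
                   class = "mr_study")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_mr_estimates(fit, p("estimates.tsv"))
    write_sensitivity(sens, p("sensitivity_loo.tsv"),
                      p("sensitivity.json"))
    utils::write.table(as.data.frame(screen), p("screening.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mediation))
      write_mediation_table(mediation, p("mediation.tsv"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  res
}

#' @export
print.mr_study <- function(x, ...) {
  cat("== Full MR study ==\n")
  print(x$fit)
  cat("\n")
  print(x$sensitivity)
  cat("\n")
  print(x$screen)
  if (!is.null(x$mediation)) {
    cat("\n")
    print(x$mediation)
  }
  invisible(x)
}
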