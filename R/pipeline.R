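# End-to-end pipeline: read -> transform -> scale -> design -> fit ->
# effect matrices -> PCA -> (optional) bootstrap, with tables, figures,
# and a machine-readable summary. The `rmasca` script in exec/ is a thin
# command-line front end over run_pipeline() and the simulation presets.

#' Assemble a run configuration
#'
#' @param input path to a long-format delimited file, or a
#'   `longitudinal_dataset`.
#' @param schema named list with `subject`, `time`, `group` column names
#'   and optionally `responses`, `covariates` (used when `input` is a
#'   path).
#' @param transform per-variable transform tags or single tag.
#' @param scale_baseline divide each variable by its baseline SD.
#' @param model a [model_spec()].
#' @param effects list of effect-family combinations to decompose, e.g.
#'   `list("time", c("time", "time:group"))`.
#' @param A components per decomposition.
#' @param n_boot bootstrap replicates (0 disables the bootstrap).
#' @param alpha bootstrap interval level.
#' @param seed seed for the bootstrap and any subsampling.
#' @param output_dir directory for tables, figures, and the summary.
#' @param figures write PNG figures (tables are always written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, schema = NULL, transform = "none",
                       scale_baseline = TRUE, model = model_spec(),
                       effects = list(c("time", "time:group")),
                       A = 2, n_boot = 0, alpha = 0.05, seed = 1,
                       output_dir = tempfile("rmasca_run_"),
                       figures = TRUE) {
  structure(list(input = input, schema = schema, transform = transform,
                 scale_baseline = scale_baseline, model = model,
                 effects = effects, A = A, n_boot = n_boot, alpha = alpha,
                 seed = seed, output_dir = output_dir, figures = figures),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror [run_config()]; the model block has keys `family`,
#' `group_coding` (`reference`/`sum`), `reference_level`,
#' `include_group_main`, `covariates`, `baseline_center`,
#' `random_intercept`. Effect combinations are given as a list of
#' character vectors (e.g. `[time, "time:group"]`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$model %||% list()
  if (identical(m$group_coding %||% "sum", "reference") &&
      is.null(m$reference_level)) {
    stop("reference coding for group requires an explicit reference_level")
  }
  spec <- model_spec(
    family = m$family %||% "rm_unconstrained",
    group_coding = coding_scheme(m$group_coding %||% "sum",
                                 m$reference_level),
    include_group_main = m$include_group_main,
    covariates = as.character(m$covariates %||% character()),
    baseline_center_ancova = isTRUE(m$baseline_center),
    random_intercept = m$random_intercept %||% TRUE
  )
  transform <- y$transform %||% "none"
  if (is.list(transform)) transform <- unlist(transform)
  run_config(
    input = y$input, schema = y$schema,
    transform = transform,
    scale_baseline = y$scale_baseline %||% TRUE,
    model = spec,
    effects = lapply(y$effects %||% list(c("time", "time:group")),
                     as.character),
    A = y$A %||% 2, n_boot = y$n_boot %||% 0,
    alpha = y$alpha %||% 0.05, seed = y$seed %||% 1,
    output_dir = y$output_dir %||% "rmasca_output",
    figures = y$figures %||% TRUE
  )
}

validate_run_config <- function(cfg) {
  if (cfg$model$family == "rm_constrained") {
    bad <- vapply(cfg$effects, function(f) "group" %in% f, logical(1))
    if (any(bad)) {
      stop("the constrained family has no group main effect; ",
           "remove 'group' from the requested effect combinations")
    }
  }
  if (cfg$A < 1) stop("A must be at least 1")
  invisible(cfg)
}

stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[rmasca] ", fmt), ...))
}

#' Run the full RM-ASCA+ pipeline
#'
#' Executes read, transform, baseline-SD scaling, design and column-wise
#' mixed-model fitting, effect-matrix construction, PCA, and (optionally)
#' the stratified Procrustes bootstrap, writing per-combination scree /
#' score / loading tables and figures, an augmented-score spaghetti
#' figure, the univariate coefficient table, and a JSON summary with the
#' settings hash.
#'
#' @param cfg a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with `fit`, `decompositions`, `bootstraps`,
#'   `summary`, and `output_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage(quiet, "reading input")
  ds <- if (inherits(cfg$input, "longitudinal_dataset")) cfg$input else {
    sch <- cfg$schema %||% stop("a schema is required for file input")
    read_long_table(cfg$input, subject = sch$subject, time = sch$time,
                    group = sch$group, responses = sch$responses,
                    covariates = sch$covariates)
  }
  raw <- ds
  s <- summary(ds)
  stage(quiet, "N = %d records, I = %d, K = %d, H = %d, J = %d",
        s$N, s$I, s$K, s$H, s$J)

  stage(quiet, "transforming and scaling")
  if (!identical(cfg$transform, "none")) {
    ds <- apply_transform(ds, cfg$transform)
  }
  scaling <- NULL
  if (cfg$scale_baseline) {
    sc <- scale_to_baseline_sd(ds)
    ds <- sc$dataset
    scaling <- sc$state
    write_scaling_state(scaling, file.path(cfg$output_dir, "scaling_state.tsv"))
  }

  stage(quiet, "fitting %s mixed models per variable", cfg$model$family)
  fm <- fit_multivariate(ds, cfg$model)
  utils::write.csv(coefficient_table(fm),
                   file.path(cfg$output_dir, "coefficients.csv"),
                   row.names = FALSE)

  decs <- list()
  boots <- list()
  expl <- list()
  for (fams in cfg$effects) {
    tag <- gsub("[^a-z]+", "_", paste(fams, collapse = "_"))
    stage(quiet, "effect matrix [%s]: PCA", paste(fams, collapse = " + "))
    m <- construct_effect_matrix(fm, fams)
    dec <- center_and_pca(m, A = min(cfg$A, min(dim(m$M))))
    decs[[tag]] <- dec
    expl[[tag]] <- as.list(dec$explained_fraction)

    utils::write.csv(
      tibble::tibble(component = names(dec$explained_fraction),
                     explained_fraction = unname(dec$explained_fraction)),
      file.path(cfg$output_dir, paste0("scree_", tag, ".csv")),
      row.names = FALSE)
    boot <- NULL
    if (cfg$n_boot > 0) {
      stage(quiet, "bootstrap (%d replicates)", cfg$n_boot)
      boot <- bootstrap_rm_asca(
        raw, cfg$model, fams, A = ncol(dec$loadings), n_boot = cfg$n_boot,
        seed = cfg$seed, alpha = cfg$alpha,
        transform = if (identical(cfg$transform, "none")) NULL else cfg$transform,
        scale_baseline = cfg$scale_baseline)
      boots[[tag]] <- boot
      utils::write.csv(boot$score_ci,
                       file.path(cfg$output_dir, paste0("scores_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(boot$loading_ci,
                       file.path(cfg$output_dir, paste0("loadings_", tag, ".csv")),
                       row.names = FALSE)
    } else {
      utils::write.csv(scores_by_cell(dec),
                       file.path(cfg$output_dir, paste0("scores_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(loadings_table(dec),
                       file.path(cfg$output_dir, paste0("loadings_", tag, ".csv")),
                       row.names = FALSE)
    }
    if (cfg$figures) {
      save_fig <- function(name, plot) {
        tryCatch(
          suppressMessages(ggplot2::ggsave(
            file.path(cfg$output_dir, name), plot,
            width = 8, height = 5, dpi = 150)),
          error = function(e) warning("figure ", name, " not written: ",
                                      conditionMessage(e), call. = FALSE))
      }
      save_fig(paste0("scree_", tag, ".png"), plot_scree(dec))
      save_fig(paste0("scores_", tag, ".png"), plot_scores(dec, boot))
      save_fig(paste0("loadings_", tag, ".png"), plot_loadings(dec, boot))
      save_fig(paste0("augmented_", tag, ".png"),
               plot_augmented_scores(dec, fm, seed = cfg$seed))
    }
  }

  cfg_for_hash <- cfg
  cfg_for_hash$output_dir <- NULL
  summary_out <- list(
    package_version = as.character(utils::packageVersion("rmasca")),
    config_hash = rlang::hash(cfg_for_hash),
    seed = cfg$seed,
    fit_method = fm$fit_method,
    family = cfg$model$family,
    n_records = s$N, n_subjects = s$I, n_timepoints = s$K,
    n_groups = s$H, n_variables = s$J,
    missing_by_time = as.list(s$missing_by_time),
    n_used = as.list(fm$n_used),
    explained_fraction = expl,
    bootstrap = list(n_boot = cfg$n_boot,
                     skipped = if (length(boots) > 0)
                       vapply(boots, `[[`, numeric(1), "skipped") else NULL)
  )
  jsonlite::write_json(summary_out,
                       file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage(quiet, "done; outputs in %s", cfg$output_dir)
  invisible(list(fit = fm, decompositions = decs, bootstraps = boots,
                 summary = summary_out, output_dir = cfg$output_dir))
}
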