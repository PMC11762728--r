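#' Build a pipeline run configuration
#'
#' Collects inputs and analysis settings for [run_pipeline()]. Inputs are
#' either file paths (`tree`, `genus_table`, `records`, `climate_points`,
#' `synonyms`) or a [synth_config()] under `synth`, in which case the
#' whole dataset is generated in memory.
#'
#' @param tree,genus_table,records,climate_points,synonyms Input file
#'   paths (Newick / CSV), ignored when `synth` is given.
#' @param synth Optional [synth_config()]; generates all inputs.
#' @param eps Relative extinction fraction for the rate estimator.
#' @param classes Dataset classes to aggregate band statistics for.
#' @param formulas Character vector of model specifications, e.g.
#'   `"div_elev ~ bio1 + bio1^2"`. Responses `div_elev` go through beta
#'   regression, `age_elev` through the identity-link Poisson-variance
#'   GLM.
#' @param r2_threshold Adjusted-R2 acceptance cutoff for precipitation
#'   calibrations.
#' @param exclude_gradients Gradient ids removed before analysis (island
#'   sensitivity reruns).
#' @param reduced Reduce the records to one per genus per band before
#'   aggregation.
#' @param trait_variables Bioclim variables used as thermal preference for
#'   the comparative stage.
#' @param outdir Optional output directory; when set, every result table
#'   is written as CSV (plus annotated Newick for the reconstruction).
#' @param seed Seed recorded in the config (generation is driven by the
#'   `synth` config's own seed).
#' @return A `run_config` list.
#' @export
run_config <- function(tree = NULL, genus_table = NULL, records = NULL,
                       climate_points = NULL, synonyms = NULL,
                       synth = NULL, eps = 0,
                       classes = c("all", "epiphyte", "non_epiphyte"),
                       formulas = c("div_elev ~ bio1",
                                    "div_elev ~ bio1 + bio1^2",
                                    "age_elev ~ bio1 + bio1^2"),
                       r2_threshold = 0.5,
                       exclude_gradients = character(0),
                       reduced = TRUE,
                       trait_variables = c("bio1", "bio6"),
                       outdir = NULL, seed = 1L) {
  if (is.null(synth)) {
    paths <- c(tree = tree, genus_table = genus_table, records = records,
               climate_points = climate_points, synonyms = synonyms)
    missing <- paths[!vapply(paths, file.exists, TRUE)]
    if (length(missing))
      stop("input path(s) do not exist: ",
           paste(missing, collapse = ", "))
    if (is.null(tree) || is.null(genus_table) || is.null(records) ||
        is.null(climate_points))
      stop("either 'synth' or all of tree/genus_table/records/",
           "climate_points must be supplied")
  }
  lapply(formulas, parse_model_spec)  # fail fast on unparsable formulas
  cfg <- as.list(environment())
  cfg$paths <- NULL; cfg$missing <- NULL
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `synth` mapping
#' is passed to [synth_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  do.call(run_config, y)
}

#' Run the full elevational diversification pipeline
#'
#' Executes the stages in order -- phylogeny pruning, per-genus rates, band
#' statistics, climate calibration and attachment, regressions, group
#' comparison, phylogenetic signal and ancestral reconstruction -- and
#' returns (optionally writes) the result bundle. The pipeline is a pure
#' function of its inputs and configuration: re-running reproduces every
#' output exactly.
#'
#' @param config A `run_config` (see [run_config()]).
#' @return A `result_bundle` list: `taxon_report`, `rate_table`,
#'   `rate_summary`, `band_stats` (climate attached), `climate_models`,
#'   `models` (per-formula fit objects), `model_report` (coefficient
#'   table), `group_comparison` (DivElev and AgeElev across classes),
#'   `trait` (per variable), `lambda` (per variable), `asr` (primary
#'   variable), `dropped` (structured drop log), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # ---- inputs ----
  if (!is.null(config$synth)) {
    dat <- stage("synth", synth_dataset(config$synth))
    tree <- dat$tree; genus_table <- dat$genus_table
    records <- dat$records; climate_points <- dat$climate_points
    synonyms <- NULL
  } else {
    tree <- stage("phylo", read_chronogram(config$tree))
    genus_table <- stage("input", read_genus_table(config$genus_table))
    records <- stage("input", read_band_records(config$records))
    climate_points <- stage("input", read_climate_points(config$climate_points))
    synonyms <- if (!is.null(config$synonyms))
      stage("input", read_synonym_map(config$synonyms)) else NULL
  }
  if (length(config$exclude_gradients)) {
    records <- records[!records$gradient_id %in% config$exclude_gradients, ,
                       drop = FALSE]
    climate_points <- climate_points[
      !climate_points$gradient_id %in% config$exclude_gradients, ,
      drop = FALSE]
  }
  if (config$reduced) records <- dedupe(records)

  # ---- phylo + rates ----
  pr <- stage("phylo", prune_to_taxa(tree, genus_table$genus, synonyms))
  matched <- pr$report$status != "unmatched"
  gt <- genus_table[matched, , drop = FALSE]
  gt$genus <- pr$report$matched_tip[matched]
  profiles <- stage("rates", rate_table(pr$tree, gt, eps = config$eps))
  rate_summary <- rate_distribution_summary(profiles)

  # ---- band statistics + climate ----
  classes <- intersect(config$classes, unique(records$class))
  if (length(classes) == 0L)
    stop("pipeline stage 'gradients' failed: no records in the configured ",
         "classes (", paste(config$classes, collapse = ", "), ")")
  bs <- stage("gradients",
              band_stats(records, profiles, class_filter = classes))
  direct <- if ("source" %in% names(climate_points))
    climate_points[!is.na(climate_points$source) &
                   climate_points$source == "direct", , drop = FALSE]
  else NULL
  models_clim <- stage("climate",
                       fit_climate_models(climate_points,
                                          threshold = config$r2_threshold))
  bs <- stage("climate", attach_climate(bs, models_clim, direct = direct))

  # ---- regressions ----
  fits <- list()
  for (f in config$formulas) {
    fml <- parse_model_spec(f)
    response <- all.vars(fml)[1L]
    sub <- bs[bs$class == "all", , drop = FALSE]
    if (!nrow(sub)) sub <- bs
    vars <- all.vars(fml)
    sub <- sub[stats::complete.cases(sub[, vars, drop = FALSE]), ,
               drop = FALSE]
    fits[[f]] <- stage("regress", switch(
      response,
      div_elev = beta_fit(fml, sub),
      age_elev = glm_fit(fml, sub),
      stop("formula response must be div_elev or age_elev, got ", response)
    ))
  }
  model_report <- .model_report(fits)

  # ---- group comparison ----
  comp <- list()
  for (resp in c("div_elev", "age_elev")) {
    groups <- split(bs[[resp]], bs$class)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) >= 2L)
      comp[[resp]] <- stage("gradients", group_comparison(groups))
  }

  # ---- comparative ----
  trait <- list(); lam <- list(); asr <- NULL
  for (v in config$trait_variables) {
    tv <- stage("comparative", genus_temp_pref(records, bs, v))
    trait[[v]] <- tv
    if (sum(is.finite(tv)) >= 4L)
      lam[[v]] <- stage("comparative", pagel_lambda(pr$tree, tv))
  }
  primary <- config$trait_variables[1L]
  if (!is.null(trait[[primary]]) && sum(is.finite(trait[[primary]])) >= 3L)
    asr <- stage("comparative", asr_bm(pr$tree, trait[[primary]]))

  dropped <- list(
    unmatched_genera = pr$report$name[pr$report$status == "unmatched"],
    records_without_profile = attr(bs, "dropped"),
    genera_without_climate = lapply(trait, attr, "dropped")
  )
  bundle <- list(
    taxon_report = pr$report, rate_table = profiles,
    rate_summary = rate_summary, band_stats = bs,
    climate_models = models_clim, models = fits,
    model_report = model_report, group_comparison = comp,
    trait = trait, lambda = lam, asr = asr,
    dropped = dropped, config = config
  )
  class(bundle) <- "result_bundle"
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

.model_report <- function(fits) {
  rows <- lapply(names(fits), function(f) {
    fit <- fits[[f]]
    k <- length(fit$coefficients)
    data.frame(
      model = f,
      family = fit$family,
      term = fit$terms,
      estimate = unname(fit$coefficients),
      se = unname(fit$se[seq_len(k)]),
      fit_index = if (inherits(fit, "beta_fit")) fit$pseudo_r2 else fit$kl_r2,
      logLik = fit$logLik,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a result bundle to disk
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  w(bundle$taxon_report, "taxon_report.csv")
  w(bundle$rate_table, "rate_table.csv")
  w(bundle$band_stats, "band_stats.csv")
  if (!is.null(bundle$model_report)) w(bundle$model_report, "model_report.csv")
  if (!is.null(bundle$asr)) {
    w(as.data.frame(bundle$asr), "asr.csv")
    write_asr_newick(bundle$asr, file.path(outdir, "asr_annotated.nwk"))
  }
  if (length(bundle$lambda)) {
    lam <- do.call(rbind, lapply(names(bundle$lambda), function(v) {
      l <- bundle$lambda[[v]]
      data.frame(variable = v, lambda = l$lambda, logLik = l$logLik,
                 lr_statistic = l$lr_statistic, p = l$p,
                 sigma2 = l$sigma2, root = l$root, n = l$n)
    }))
    w(lam, "lambda_fit.csv")
  }
  drops <- bundle$dropped$records_without_profile
  if (!is.null(drops) && nrow(drops)) w(drops, "dropped_records.csv")
  invisible(outdir)
}

#' Plain-text report of a result bundle
#'
#' Prints the rate-distribution summary, per-model coefficient tables with
#' stationary-point temperatures wherever a quadratic temperature term was
#' fitted, the group comparisons, and the phylogenetic signal / ancestral
#' root estimates.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @return `bundle`, invisibly.
#' @export
report_bundle <- function(bundle) {
  rs <- bundle$rate_summary
  cat("== Diversification rates ==\n")
  cat(sprintf("%d genera | rates %.3f-%.3f | mean %.3f | median %.3f | %d zero\n",
              rs$n, rs$min, rs$max, rs$mean, rs$median, rs$n_zero))
  if (rs$n_zero == rs$n) cat("note: all rates zero (monospecific genera only)\n")
  cat("bins:", paste(sprintf("%s=%d", names(rs$bins), rs$bins),
                     collapse = "  "), "\n\n")
  if (length(bundle$models)) {
    cat("== Regression models ==\n")
    for (f in names(bundle$models)) {
      fit <- bundle$models[[f]]
      cat("--", f, "--\n")
      print(fit)
      sq <- grep("^I\\(.+\\^2\\)$", fit$terms, value = TRUE)
      for (s in sq) {
        term <- sub("^I\\((.+)\\^2\\)$", "\\1", s)
        if (term %in% fit$terms && fit$coefficients[[s]] != 0) {
          v <- quadratic_vertex(fit, term = term)
          cat(sprintf("   stationary point: %s at %s = %.2f\n",
                      v$type, term, v$x))
        }
      }
    }
    cat("\n")
  } else cat("== Regression models ==\n(none configured)\n\n")
  for (resp in names(bundle$group_comparison)) {
    gc <- bundle$group_comparison[[resp]]
    cat(sprintf("== Group comparison: %s == F(%d,%d) = %.3f, p = %.3g\n",
                resp, gc$anova$df1, gc$anova$df2, gc$anova$F, gc$anova$p))
    if (!is.null(gc$tukey)) print(gc$tukey)
  }
  for (v in names(bundle$lambda)) {
    cat(sprintf("\n== Phylogenetic signal (%s) ==\n", v))
    print(bundle$lambda[[v]])
  }
  if (!is.null(bundle$asr))
    cat(sprintf("\nAncestral root estimate: %.2f deg C (sigma2 %.4g)\n",
                attr(bundle$asr, "root_estimate"), attr(bundle$asr, "sigma2")))
  invisible(bundle)
}
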