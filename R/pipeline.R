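eco_variables <- c("habitat_class", "light_class", "diet_class",
                   "prey_mobility", "foraging_mode")

#' Pipeline configuration
#'
#' Collects the inputs and tunable constants of the end-to-end analysis.
#' `tree` and `traits` may be in-memory objects (a `phylo`, a data.frame)
#' or file paths (Newick, CSV).
#'
#' @param tree phylogeny: a `phylo` object or path to a Newick file.
#' @param traits species trait table: data.frame or path to a CSV with one
#'   row per species record (see [run_pipeline()] for the column schema).
#' @param output_dir optional directory for [write_report()].
#' @param log_base base of the log transform applied to acuity, eye size
#'   and body mass (default natural log).
#' @param habitat_threshold_pct threshold of the habitat 70% rule.
#' @param diet_threshold_pct threshold of the dominant-diet 50% rule.
#' @param corr_threshold collinearity flagging threshold (default 0.7).
#' @param cooks_rule outlier rule: `"4/n"` (exclude Cook's D > 4/n) or
#'   `"topk:K"` (exclude the K most influential species).
#' @param n_sims Brownian simulations for the phylogenetic ANOVA null
#'   (default 1000, minimum 100).
#' @param seed integer seed (required).
#' @param lambda_boundary_mixture use the 50:50 boundary mixture for the
#'   lambda LRT p-value (default FALSE: plain chi-squared(1) tail).
#' @param subset `"all"`, `"rgc_only"` or `"behavior_only"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree, traits, output_dir = NULL,
                            log_base = exp(1),
                            habitat_threshold_pct = 70,
                            diet_threshold_pct = 50,
                            corr_threshold = 0.7,
                            cooks_rule = "4/n",
                            n_sims = 1000, seed,
                            lambda_boundary_mixture = FALSE,
                            subset = c("all", "rgc_only", "behavior_only")) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  subset <- match.arg(subset)
  stopifnot(habitat_threshold_pct > 0, habitat_threshold_pct < 100,
            diet_threshold_pct > 0, diet_threshold_pct < 100,
            corr_threshold > 0, corr_threshold < 1, n_sims >= 100)
  structure(list(tree = tree, traits = traits, output_dir = output_dir,
                 log_base = log_base,
                 habitat_threshold_pct = habitat_threshold_pct,
                 diet_threshold_pct = diet_threshold_pct,
                 corr_threshold = corr_threshold,
                 cooks_rule = cooks_rule, n_sims = n_sims,
                 seed = as.integer(seed),
                 lambda_boundary_mixture = lambda_boundary_mixture,
                 subset = subset),
            class = "pipeline_config")
}

load_tree_input <- function(tree) {
  if (inherits(tree, "phylo")) return(validate_tree(tree))
  if (is.character(tree) && length(tree) == 1L) {
    return(parse_newick(paste(readLines(tree, warn = FALSE), collapse = "")))
  }
  stop("tree must be a 'phylo' object or a Newick file path")
}

load_trait_input <- function(traits) {
  if (is.data.frame(traits)) return(traits)
  if (is.character(traits) && length(traits) == 1L) {
    return(utils::read.csv(traits, stringsAsFactors = FALSE))
  }
  stop("traits must be a data.frame or a CSV file path")
}

split_list_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1L]])
}

# Derive the five categorical classifications for each row, from either
# pre-supplied *_class columns or raw trait fields.
derive_classes <- function(df, config) {
  n <- nrow(df)
  strata <- unlist(habitat_strata, use.names = FALSE)
  for (v in eco_variables) {
    if (!is.null(df[[v]])) next
    df[[v]] <- vapply(seq_len(n), function(i) {
      row <- df[i, , drop = FALSE]
      switch(v,
        habitat_class = {
          cols <- paste0("habitat_", strata)
          have <- intersect(cols, names(df))
          if (!length(have)) stop("missing habitat percentage columns")
          pct <- stats::setNames(as.numeric(row[have]),
                                 sub("^habitat_", "", have))
          classify_habitat(pct, config$habitat_threshold_pct)
        },
        light_class = classify_light(
          split_list_field(row$habitat_keywords),
          isTRUE(as.logical(row$nocturnal))),
        diet_class = ,
        prey_mobility = {
          cols <- setdiff(grep("^diet_", names(df), value = TRUE),
                          "diet_class")
          if (!length(cols)) stop("missing diet score columns")
          raw <- stats::setNames(as.numeric(row[cols]),
                                 sub("^diet_", "", cols))
          if (v == "diet_class") classify_diet(raw, config$diet_threshold_pct)
          else classify_prey_mobility(raw)
        },
        foraging_mode = classify_foraging(split_list_field(row$maneuvers))
      )
    }, character(1))
  }
  df
}

#' Exclude influential species from a GLS fit
#'
#' @param fit a `gls_fit` with Cook's distances.
#' @param rule `"4/n"` (exclude D > 4/n) or `"topk:K"` (exclude the K
#'   largest D).
#' @return list with `kept` (species names) and `excluded` (data.frame of
#'   species and Cook's D, sorted descending).
#' @export
exclude_outliers <- function(fit, rule = "4/n") {
  stopifnot(inherits(fit, "gls_fit"))
  d <- fit$cooks_d
  if (is.null(names(d))) names(d) <- seq_along(d)
  if (identical(rule, "4/n")) {
    out <- names(d)[d > 4 / fit$n_obs]
  } else if (grepl("^topk:[0-9]+$", rule)) {
    k <- as.integer(sub("^topk:", "", rule))
    out <- names(sort(d, decreasing = TRUE))[seq_len(min(k, length(d)))]
  } else {
    stop("unknown outlier rule: '", rule, "' (use \"4/n\" or \"topk:K\")")
  }
  excl <- data.frame(species = out, cooks_d = unname(d[out]),
                     stringsAsFactors = FALSE)
  excl <- excl[order(-excl$cooks_d), , drop = FALSE]
  rownames(excl) <- NULL
  list(kept = setdiff(names(d), out), excluded = excl)
}

config_hash <- function(config) {
  flat <- unclass(config)
  flat$tree <- if (is.character(flat$tree)) flat$tree else "<in-memory tree>"
  flat$traits <- if (is.character(flat$traits)) flat$traits
                 else "<in-memory table>"
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(flat), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full comparative analysis pipeline
#'
#' End-to-end orchestration: record selection and unit conversion,
#' ecological classification, missing-data drops, tree pruning, log
#' transforms, Pagel's lambda, the acuity-eye size PGLS with Cook's
#' distance outlier exclusion and refit, the collinearity screen, the
#' all-subsets AIC model tables (with and without eye size), the residual
#' cascade, and phylogenetic ANOVAs with post hoc contrasts and marginal
#' means for every ecological variable crossed with the three responses
#' (log acuity, relative eye size, residual acuity).
#'
#' The trait table needs columns `species`, `eye_axial_length_mm`,
#' `body_mass_g`, and either `acuity_cpd` or `acuity_value` +
#' `acuity_unit`; `method` and `source_year` drive record selection when a
#' species has several rows. Ecological categories are taken from
#' `habitat_class`, `light_class`, `diet_class`, `prey_mobility`,
#' `foraging_mode` columns when present, and are otherwise derived from raw
#' fields (`habitat_<stratum>` percentages, `habitat_keywords`,
#' `nocturnal`, `diet_<category>` scores, `maneuvers`; list fields are
#' semicolon-separated).
#'
#' @param config a [pipeline_config()].
#' @return object of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  tree <- stage("load_tree", load_tree_input(config$tree))
  df <- stage("load_traits", load_trait_input(config$traits))
  if (is.null(df$species)) stop("pipeline stage 'load_traits' failed: no species column")

  # (1) unit conversion + record selection
  df <- stage("unit_conversion", {
    if (is.null(df$acuity_cpd)) {
      if (is.null(df$acuity_value) || is.null(df$acuity_unit)) {
        stop("need acuity_cpd or acuity_value + acuity_unit columns")
      }
      df$acuity_cpd <- mapply(function(v, u) to_cpd(v, u),
                              df$acuity_value, as.character(df$acuity_unit))
    }
    df
  })
  df <- stage("record_selection", {
    if (is.null(df$method)) df$method <- "RGC"
    if (is.null(df$source_year)) df$source_year <- NA_integer_
    sp <- normalize_label(df$species)
    if (anyDuplicated(sp)) {
      picked <- lapply(split(df, sp), select_record)
      df <- do.call(rbind, picked)
    }
    rownames(df) <- NULL
    df
  })

  # (2) ecological classification
  df <- stage("classification", derive_classes(df, config))

  # method subset
  df <- stage("subset", switch(config$subset,
    all = df,
    rgc_only = df[df$method == "RGC", , drop = FALSE],
    behavior_only = df[df$method == "behavioral", , drop = FALSE]))
  n_input <- nrow(df)

  # (3) drop species missing eye size or body mass
  has_data <- !is.na(df$eye_axial_length_mm) & !is.na(df$body_mass_g) &
    !is.na(df$acuity_cpd)
  dropped_missing <- df$species[!has_data]
  df <- df[has_data, , drop = FALSE]

  # (4) prune tree to remaining species
  tree0 <- stage("prune", {
    missing <- setdiff(normalize_label(df$species),
                       normalize_label(tree$tip.label))
    if (length(missing)) {
      stop("species absent from tree: ", paste(missing, collapse = ", "))
    }
    prune_tree(tree, df$species)
  })
  ord <- match(normalize_label(tree0$tip.label), normalize_label(df$species))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- df$species <- tree0$tip.label

  # (5) log transforms
  lb <- log(config$log_base)
  df$log_acuity <- log(df$acuity_cpd) / lb
  df$log_eye_size <- log(df$eye_axial_length_mm) / lb
  df$log_body_mass <- log(df$body_mass_g) / lb

  C0 <- phylo_vcv(tree0)
  y0 <- stats::setNames(df$log_acuity, df$species)

  # (6) phylogenetic signal in acuity
  lambda <- stage("pagels_lambda",
                  pagels_lambda(y0, C0,
                                mixture = config$lambda_boundary_mixture))

  # (7) acuity ~ eye size, outlier exclusion, refit
  X0 <- cbind(`(Intercept)` = 1, log_eye_size = df$log_eye_size)
  rownames(X0) <- df$species
  fit_initial <- stage("initial_fit", fit_gls(X0, y0, C0))
  excl <- stage("outlier_exclusion", exclude_outliers(fit_initial,
                                                      config$cooks_rule))
  df <- df[df$species %in% excl$kept, , drop = FALSE]
  tree1 <- if (length(excl$excluded$species)) prune_tree(tree0, df$species)
           else tree0
  ord <- match(tree1$tip.label, df$species)
  df <- df[ord, , drop = FALSE]
  C1 <- phylo_vcv(tree1)
  y <- stats::setNames(df$log_acuity, df$species)
  X1 <- cbind(`(Intercept)` = 1, log_eye_size = df$log_eye_size)
  rownames(X1) <- df$species
  fit_final <- stage("refit", fit_gls(X1, y, C1))

  for (v in eco_variables) df[[v]] <- droplevels(factor(df[[v]]))

  # (8) collinearity screen over eye size + ecological variables
  pred_df <- df[, c("log_eye_size", eco_variables)]
  screen <- stage("collinearity_screen",
                  collinearity_screen(pred_df, config$corr_threshold))

  # (9) all-subsets model tables (64 models; 32 with eye size forced absent)
  model_table_full <- stage("model_selection", {
    fits <- fit_subsets(y, pred_df, C1)
    rank_models(fits)
  })
  model_table_eco <- stage("model_selection_no_eyesize", {
    eco_df <- df[, eco_variables]
    rank_models(fit_subsets(y, eco_df, C1))
  })

  # (10) residual cascade
  cascade <- stage("residual_cascade", residual_cascade(
    y, stats::setNames(df$log_eye_size, df$species),
    stats::setNames(df$log_body_mass, df$species), C1))
  df$relative_eye_size <- unname(cascade$relative_eye_size)
  df$residual_acuity <- unname(cascade$residual_acuity)

  # (11) phylogenetic ANOVA + post hocs + marginal means
  responses <- list(log_acuity = y,
                    relative_eye_size = cascade$relative_eye_size,
                    residual_acuity = cascade$residual_acuity)
  anova_results <- list()
  seed_offset <- 0L
  for (v in eco_variables) {
    anova_results[[v]] <- list()
    for (rname in names(responses)) {
      seed_offset <- seed_offset + 1L
      anova_results[[v]][[rname]] <- stage(
        paste0("phyl_anova:", v, ":", rname), {
          res <- phyl_anova(responses[[rname]], df[[v]], tree1,
                            n_sims = config$n_sims,
                            seed = config$seed + seed_offset)
          res$marginal_means <- marginal_means(responses[[rname]],
                                               df[[v]], C1)
          res
        })
    }
  }

  report <- structure(list(
    sample_sizes = list(n_input = n_input,
                        n_dropped_missing = length(dropped_missing),
                        n_excluded_outliers = nrow(excl$excluded),
                        n_analyzed = nrow(df)),
    dropped_missing = dropped_missing,
    lambda = lambda,
    fit_acuity_eye_initial = fit_initial,
    fit_acuity_eye_final = fit_final,
    exclusions = excl$excluded,
    collinearity = screen,
    model_table_full = model_table_full,
    model_table_no_eyesize = model_table_eco,
    cascade = cascade,
    anova = anova_results,
    tree = tree1,
    data = df,
    subset = config$subset,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      n_sims = config$n_sims,
                      cooks_rule = config$cooks_rule,
                      log_base = config$log_base,
                      version = as.character(utils::packageVersion("birdacuity")))
  ), class = "analysis_report")
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$sample_sizes
  cat("Phylogenetic acuity analysis report\n")
  cat(sprintf("  species: %d analyzed (%d in, %d missing data, %d outliers excluded)\n",
              s$n_analyzed, s$n_input, s$n_dropped_missing,
              s$n_excluded_outliers))
  cat(sprintf("  Pagel's lambda(acuity) = %.3f (LRT P = %.3g)\n",
              x$lambda$lambda_hat, x$lambda$p_value))
  b <- x$fit_acuity_eye_final
  cat(sprintf("  acuity ~ eye size: slope = %.3f +/- %.3f, R2 = %.2f\n",
              b$beta["log_eye_size"], b$se["log_eye_size"], b$r_squared))
  cat(sprintf("  best model: %s (weight %.2f)\n",
              x$model_table_full$model[1L], x$model_table_full$weight[1L]))
  invisible(x)
}

# tidy contrast table mirroring the report layout
contrast_table <- function(report) {
  rows <- list()
  for (v in names(report$anova)) {
    for (rname in names(report$anova[[v]])) {
      res <- report$anova[[v]][[rname]]
      pairs <- strsplit(names(res$pairwise_p_raw), " vs ", fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        response = rname, category = v,
        level_a = vapply(pairs, `[`, character(1), 1L),
        level_b = vapply(pairs, `[`, character(1), 2L),
        t = unname(res$pairwise_t_signed),
        p_raw = unname(res$pairwise_p_raw),
        p_holm = unname(res$pairwise_p_holm),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

gls_fit_summary <- function(fit) {
  list(coefficients = as.list(fit$beta), se = as.list(fit$se),
       t = as.list(fit$t_stats), p = as.list(fit$p_values),
       df_residual = fit$df_residual, sigma2 = fit$sigma2,
       loglik = fit$loglik, aic = fit$aic, r_squared = fit$r_squared,
       n_obs = fit$n_obs)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable JSON report, tidy CSVs (model tables, contrast
#' table, species table with classifications and residuals), the pruned
#' Newick tree, and a plain-text log. Outputs are byte-stable for a fixed
#' configuration and seed.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param dir output directory (created if necessary).
#' @return invisibly, the vector of file paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (is.null(report$model_table_full) || nrow(report$model_table_full) == 0L) {
    stop("incomplete report: empty model table")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  wr <- function(name) { p <- file.path(dir, name); paths <<- c(paths, p); p }

  utils::write.csv(as.data.frame(report$model_table_full),
                   wr("model_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$model_table_no_eyesize),
                   wr("model_table_no_eyesize.csv"), row.names = FALSE)
  utils::write.csv(contrast_table(report), wr("contrasts.csv"),
                   row.names = FALSE)
  species_cols <- intersect(c("species", "acuity_cpd", "method",
                              "source_year", "eye_axial_length_mm",
                              "body_mass_g", eco_variables, "log_acuity",
                              "log_eye_size", "log_body_mass",
                              "relative_eye_size", "residual_acuity"),
                            names(report$data))
  utils::write.csv(report$data[, species_cols], wr("species.csv"),
                   row.names = FALSE)
  ape::write.tree(report$tree, wr("tree.nwk"))

  json <- list(
    sample_sizes = report$sample_sizes,
    lambda = report$lambda[c("lambda_hat", "lrt_stat", "p_value")],
    fit_acuity_eye = gls_fit_summary(report$fit_acuity_eye_final),
    residual_cascade = list(
      stage1 = gls_fit_summary(report$cascade$stage1),
      stage2 = gls_fit_summary(report$cascade$stage2)),
    excluded_species = report$exclusions,
    collinearity = report$collinearity,
    anova = lapply(report$anova, function(by_resp) {
      lapply(by_resp, function(res) {
        list(f_stat = res$f_stat, p_classical = res$p_classical,
             p_phylogenetic = res$p_phylogenetic,
             group_means = as.list(res$group_means),
             pairwise_p_holm = as.list(res$pairwise_p_holm),
             marginal_means = res$marginal_means)
      })
    }),
    provenance = report$provenance)
  jsonlite::write_json(json, wr("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("birdacuity %s analysis log", report$provenance$version),
    sprintf("config hash: %s", report$provenance$config_hash),
    sprintf("seed: %d, n_sims: %d", report$provenance$seed,
            report$provenance$n_sims),
    sprintf("subset: %s", report$subset),
    sprintf("species in: %d; missing data: %d; outliers excluded: %d; analyzed: %d",
            report$sample_sizes$n_input,
            report$sample_sizes$n_dropped_missing,
            report$sample_sizes$n_excluded_outliers,
            report$sample_sizes$n_analyzed),
    sprintf("excluded: %s",
            if (nrow(report$exclusions)) paste(report$exclusions$species,
                                               collapse = ", ") else "none"),
    sprintf("lambda(acuity) = %.6f (LRT P = %.6g)", report$lambda$lambda_hat,
            report$lambda$p_value),
    sprintf("acuity ~ eye size slope = %.6f +/- %.6f (R2 = %.4f)",
            report$fit_acuity_eye_final$beta["log_eye_size"],
            report$fit_acuity_eye_final$se["log_eye_size"],
            report$fit_acuity_eye_final$r_squared))
  writeLines(log_lines, wr("log.txt"))
  invisible(paths)
}
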