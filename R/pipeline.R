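#' Read a flat key=value pipeline configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are parsed as numbers where possible, and as logicals
#' for `true`/`false`.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("config file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  config <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop_validation(sprintf("config line is not 'key = value': '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  config
}

default_config <- function() {
  list(curves_format = "csv", flip_y = FALSE, resample_n = 250,
       window = 50, overlap = 0.5, taper = "hann",
       n_sim = 1000, n_perm = 999, seed = 1,
       lambda_pref_threshold = 0.5)
}

validate_traits <- function(traits) {
  required <- c("species", "locomotor", "facial_tilt", "body_mass",
                "centroid_size", "burrowing")
  missing_cols <- setdiff(required, names(traits))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("trait table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  traits$species <- trimws(as.character(traits$species))
  if (anyDuplicated(traits$species)) {
    stop_validation("trait table has duplicated species")
  }
  allowed <- c("generalised", "saltatorial", "cursorial")
  bad <- which(!traits$locomotor %in% allowed)
  if (length(bad) > 0L) {
    stop_validation(sprintf("unknown locomotor label '%s' in trait row %d (species '%s'); allowed: %s",
                            traits$locomotor[bad[1]], bad[1],
                            traits$species[bad[1]],
                            paste(allowed, collapse = ", ")))
  }
  if (!all(traits$burrowing %in% c(0, 1))) {
    stop_validation("`burrowing` must be coded 0/1")
  }
  num_cols <- c("facial_tilt", "body_mass", "centroid_size")
  for (col in num_cols) {
    if (!is.numeric(traits[[col]]) || anyNA(traits[[col]])) {
      stop_validation(sprintf("trait column '%s' must be numeric with no missing values", col))
    }
  }
  traits
}

table1_row <- function(model, response, fit, lambda_hat, preferred) {
  pw <- fit$pairwise
  if (is.null(pw)) pw <- fit$pairwise_sim
  cell <- function(a, b) {
    hit <- (pw$group_i == a & pw$group_j == b) | (pw$group_i == b & pw$group_j == a)
    if (!any(hit)) return(NA_real_)
    pw$p_adjusted[hit][1]
  }
  data.frame(response = response, model = model,
             F = fit$F,
             p = if (!is.null(fit$p_sim)) fit$p_sim else fit$p,
             eta2G = if (!is.null(fit$eta2g)) fit$eta2g else NA_real_,
             lambda = lambda_hat,
             C_v_G = cell("cursorial", "generalised"),
             C_v_S = cell("cursorial", "saltatorial"),
             G_v_S = cell("generalised", "saltatorial"),
             preferred = preferred,
             stringsAsFactors = FALSE)
}

#' Run the full suture-complexity analysis pipeline
#'
#' Orchestrates resampling, digitisation-direction normalisation, generalised
#' Procrustes alignment, complexity scoring (SI and PSD on the superimposed
#' semi-landmarks) and the comparative statistics stage:
#' * one-way ANOVA and simulation-based phylogenetic ANOVA of each metric
#'   versus locomotor mode, with Pagel's lambda of the model residuals and a
#'   preferred-model flag (standard ANOVA when residual lambda is low);
#' * PGLS of each metric against facial tilt, body mass and centroid size;
#' * ANOVA of each metric versus burrowing habit;
#' * optionally, Procrustes PGLS of 3D cranial shape (or the aligned suture
#'   shapes) on each metric;
#' * Shapiro-Wilk normality checks of the continuous covariates.
#'
#' All outputs are written as CSV plus a flat `manifest.txt` (sufficient to
#' re-run the pipeline identically) and a `run.log`. A second run with the
#' same config is byte-identical.
#'
#' @param config Named list (see [read_run_config()]) with entries `curves`,
#'   `tree`, `traits` (paths), optional `landmarks3d`, and the parameters
#'   `curves_format`, `flip_y`, `resample_n`, `window`, `overlap`, `taper`,
#'   `n_sim`, `n_perm`, `seed`, `out_dir`.
#' @return Invisibly, a list with the computed tables and model objects.
#' @export
run_pipeline <- function(config) {
  config <- utils::modifyList(default_config(), as.list(config))
  for (key in c("curves", "tree", "traits", "out_dir")) {
    if (is.null(config[[key]])) {
      stop_validation(sprintf("config entry '%s' is required", key))
    }
  }
  for (key in c("curves", "tree", "traits")) {
    if (!file.exists(config[[key]])) {
      stop_validation(sprintf("config entry '%s': file not found '%s'",
                              key, config[[key]]))
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  log_msg("stage curve_io: reading curves from %s", config$curves)
  curves <- read_curves(config$curves, format = config$curves_format,
                        flip_y = isTRUE(config$flip_y))
  log_msg("stage curve_io: %d curves read", length(curves))

  tree <- read_newick(config$tree)
  chk <- tree_check(tree)
  log_msg("stage phylo: %d tips, ultrametric deviation %.3g",
          chk$n_tips, chk$ultrametric_deviation)

  traits <- validate_traits(utils::read.csv(config$traits,
                                            stringsAsFactors = FALSE))
  curve_ids <- vapply(curves, function(cv) cv$specimen_id, character(1))
  missing_curves <- setdiff(traits$species, curve_ids)
  if (length(missing_curves) > 0L) {
    stop_validation(sprintf("species present in traits but absent from curves: %s",
                            paste(missing_curves, collapse = ", ")))
  }

  log_msg("stage procrustes: resampling to %d semi-landmarks and aligning",
          config$resample_n)
  alignment <- align_curves(curves, n = config$resample_n)
  aligned_curves <- aligned_to_curves(alignment$aligned)
  log_msg("stage procrustes: GPA %s after %d iterations",
          if (alignment$aligned$converged) "converged" else "did NOT converge",
          alignment$aligned$iterations)

  log_msg("stage complexity: scoring SI and PSD (window %d, overlap %.2f, %s taper)",
          as.integer(config$window), config$overlap, config$taper)
  cx <- complexity_scores(aligned_curves, window = as.integer(config$window),
                          overlap_fraction = config$overlap,
                          taper = config$taper)
  traits <- merge(traits, cx, by.x = "species", by.y = "specimen_id",
                  sort = TRUE)

  named <- function(col) stats::setNames(traits[[col]], traits$species)
  seed <- as.integer(config$seed)
  n_sim <- as.integer(config$n_sim)
  n_perm <- as.integer(config$n_perm)

  normality <- do.call(rbind, lapply(c("facial_tilt", "body_mass"), function(v) {
    sw <- shapiro_wilk(traits[[v]])
    data.frame(variable = v, W = sw$W, p = sw$p)
  }))

  log_msg("stage stats: ANOVA / phylogenetic ANOVA vs locomotor mode")
  loco_rows <- list()
  models <- list()
  for (metric in c("SI", "PSD")) {
    y <- named(metric)
    g <- named("locomotor")
    av <- anova_oneway(y, g)
    pav <- phyl_anova(y, g, tree, n_sim = n_sim, seed = seed)
    resid_lambda <- fit_pagel_lambda(
      stats::setNames(stats::resid(stats::lm(y ~ g)), names(y)), tree)
    pref <- if (resid_lambda$lambda_hat < config$lambda_pref_threshold)
      "ANOVA" else "PANOVA"
    loco_rows[[paste0(metric, "_anova")]] <-
      table1_row("ANOVA", metric, av, NA_real_,
                 ifelse(pref == "ANOVA", "*", ""))
    loco_rows[[paste0(metric, "_panova")]] <-
      table1_row("PANOVA", metric, pav, resid_lambda$lambda_hat,
                 ifelse(pref == "PANOVA", "*", ""))
    models[[paste0(metric, "_locomotor_anova")]] <- av
    models[[paste0(metric, "_locomotor_panova")]] <- pav
  }
  locomotor_table <- do.call(rbind, loco_rows)
  rownames(locomotor_table) <- NULL

  log_msg("stage stats: PGLS of complexity vs continuous covariates")
  pgls_rows <- list()
  for (metric in c("SI", "PSD")) {
    for (pred in c("facial_tilt", "body_mass", "centroid_size")) {
      fit <- pgls_fit(named(metric), named(pred), tree)
      models[[paste0(metric, "_", pred, "_pgls")]] <- fit
      pgls_rows[[paste0(metric, "_", pred)]] <- data.frame(
        response = metric, predictor = pred,
        slope = fit$coefficients[["predictor"]],
        SE = fit$standard_errors[["predictor"]],
        t = fit$t_values[["predictor"]],
        p = fit$p_values[["predictor"]],
        lambda = fit$lambda_used, n = fit$n,
        stringsAsFactors = FALSE)
    }
  }
  pgls_table <- do.call(rbind, pgls_rows)
  rownames(pgls_table) <- NULL

  log_msg("stage stats: ANOVA of complexity vs burrowing habit")
  burrow_rows <- lapply(c("SI", "PSD"), function(metric) {
    av <- anova_oneway(named(metric), factor(named("burrowing"),
                                             levels = c(0, 1),
                                             labels = c("non_burrowing",
                                                        "burrowing")))
    data.frame(response = metric, F = av$F, p = av$p, eta2G = av$eta2g,
               stringsAsFactors = FALSE)
  })
  burrowing_table <- do.call(rbind, burrow_rows)

  shape_table <- NULL
  if (!is.null(config$landmarks3d)) {
    log_msg("stage shape: 3D cranial GPA and Procrustes PGLS on complexity")
    configs3d <- read_landmarks(config$landmarks3d)
    shape_aligned <- gpa_align(configs3d)
  } else {
    log_msg("stage shape: no 3D landmarks supplied; using aligned suture shapes")
    shape_aligned <- alignment$aligned
  }
  shape_rows <- lapply(c("SI", "PSD"), function(metric) {
    fit <- procrustes_pgls(shape_aligned, named(metric), tree,
                           n_perm = n_perm, seed = seed)
    models[[paste0("shape_", metric, "_pgls")]] <<- fit
    fcv <- fit$fitted_component_variances
    data.frame(predictor = metric, r_squared = fit$r_squared,
               p_perm = fit$p_perm, n_perm = fit$n_perm,
               PC1_fitted_variance = if (length(fcv) >= 1) fcv[1] else NA_real_,
               PC2_fitted_variance = if (length(fcv) >= 2) fcv[2] else NA_real_,
               stringsAsFactors = FALSE)
  })
  shape_table <- do.call(rbind, shape_rows)

  write_out <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
    log_msg("wrote %s", path)
    path
  }
  write_out(cx, "complexity.csv")
  write_out(locomotor_table, "anova_locomotor.csv")
  write_out(pgls_table, "pgls_continuous.csv")
  write_out(burrowing_table, "anova_burrowing.csv")
  write_out(shape_table, "shape_pgls.csv")
  write_out(normality, "normality.csv")

  manifest <- c(
    sprintf("suturemorph_version = %s",
            as.character(utils::packageVersion("suturemorph"))),
    sprintf("curves = %s", config$curves),
    sprintf("curves_format = %s", config$curves_format),
    if (!is.null(config$landmarks3d)) sprintf("landmarks3d = %s", config$landmarks3d),
    sprintf("tree = %s", config$tree),
    sprintf("traits = %s", config$traits),
    sprintf("flip_y = %s", tolower(as.character(isTRUE(config$flip_y)))),
    sprintf("resample_n = %d", as.integer(config$resample_n)),
    sprintf("window = %d", as.integer(config$window)),
    sprintf("overlap = %g", config$overlap),
    sprintf("taper = %s", config$taper),
    sprintf("n_sim = %d", n_sim),
    sprintf("n_perm = %d", n_perm),
    sprintf("seed = %d", seed),
    sprintf("out_dir = %s", out_dir))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(complexity = cx, locomotor = locomotor_table,
                 pgls = pgls_table, burrowing = burrowing_table,
                 shape = shape_table, normality = normality,
                 traits = traits, alignment = alignment, models = models))
}
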