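# End-to-end orchestration: a single configuration (R list, YAML or JSON)
# selects which stages run — limiting-dilution analysis, differential
# expression, motif activity inference, gene-set enrichment, IHC
# quantification — on packaged fixtures, user files or freshly simulated
# data, and collects a machine-readable run report.

#' Validate a pipeline configuration
#'
#' Checks the configuration before any computation: each enabled stage must
#' have exactly one input source (real file paths or `simulate: true`), a
#' seed is mandatory whenever any stochastic stage is enabled, and
#' stage-specific required fields (e.g. `gene_sets` for GSEA on real data)
#' must be present. Errors name the offending field.
#'
#' @param config named list, or a path to a YAML/JSON file.
#' @return the normalized configuration (invisibly usable by
#'   [run_pipeline()]).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config field 'stages' is missing or empty")
  known <- c("lda", "de", "mara", "gsea", "ihc")
  bad <- setdiff(names(stages), known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  simulated <- vapply(stages, function(s) isTRUE(s$simulate), logical(1))
  stochastic <- any(simulated) || "gsea" %in% names(stages)
  if (stochastic && is.null(config$seed)) {
    stop("config field 'seed' is required when a stochastic stage is enabled")
  }

  for (nm in names(stages)) {
    s <- stages[[nm]]
    path_fields <- switch(nm,
      lda = "input_csv", de = c("expression_tsv", "samples_csv"),
      mara = c("expression_tsv", "sites_tsv"),
      gsea = c("expression_tsv", "samples_csv", "gene_sets"),
      ihc = c("image_png", "training_csv"))
    has_paths <- any(path_fields %in% names(s))
    if (nm == "lda" && !has_paths && !isTRUE(s$simulate)) {
      # LDA defaults to the packaged transplantation fixture
      next
    }
    if (isTRUE(s$simulate) && has_paths) {
      stop("stage '", nm, "': give either 'simulate: true' or input paths, not both")
    }
    if (!isTRUE(s$simulate)) {
      missing <- setdiff(path_fields, names(s))
      if (length(missing)) {
        stop("stage '", nm, "': missing required field(s): ",
             paste(missing, collapse = ", "))
      }
      for (f in path_fields) {
        if (!file.exists(s[[f]])) stop("stage '", nm, "': file not found for '",
                                       f, "': ", s[[f]])
      }
    }
  }
  invisible(config)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order, writes every
#' intermediate to `output_dir`, and returns (and writes) a run report
#' containing per-stage status, the key outputs, the package version and a
#' hash of the configuration. Reports are byte-identical across runs with
#' the same configuration and seed.
#'
#' @param config named list or YAML/JSON path (see
#'   [validate_pipeline_config()] for the schema).
#' @param output_dir directory for intermediates and the report (created if
#'   needed); default a fresh temporary directory.
#' @return a `run_report` list.
#' @examples
#' report <- run_pipeline(list(stages = list(lda = list())))
#' names(report$stages$lda$estimates)
#' @export
run_pipeline <- function(config, output_dir = tempfile("paritykit_run_")) {
  config <- validate_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 0L
  sim_cfg <- do.call(simulation_config,
                     c(list(seed = seed), config$simulation %||% list()))
  report <- list(package = "paritykit",
                 version = as.character(utils::packageVersion("paritykit")),
                 config_hash = config_hash(config),
                 seed = seed,
                 stages = list())

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      stop("stage '", name, "' failed: ", conditionMessage(res), call. = FALSE)
    }
    report$stages[[name]] <<- c(list(status = "ok"), res)
  }

  stages <- config$stages

  if ("lda" %in% names(stages)) run_stage("lda", function() {
    s <- stages$lda
    assays <- if (isTRUE(s$simulate)) {
      list(simulated = simulate_dilution_assay(
        s$frequency %||% 1 / 500,
        s$doses %||% c(1000, 500, 250, 100, 50),
        s$n_per_dose %||% c(9, 11, 6, 6, 7), seed = seed))
    } else if (!is.null(s$input_csv)) {
      read_dilution_csv(s$input_csv)
    } else {
      parity_transplant_tables()
    }
    fits <- lapply(assays, fit_single_hit)
    est <- lapply(fits, function(f) list(
      denominator = f$denominator, f_hat = f$f_hat,
      ci_denominator = f$ci_denominator, boundary = f$boundary))
    comparisons <- s$comparisons %||% (if (is.null(s$input_csv) && !isTRUE(s$simulate))
      list(c("virgin_c", "parous_c"), c("virgin_d", "parous_d"),
           c("virgin_d", "parous_e")) else list())
    comp <- lapply(comparisons, function(pair) {
      cm <- compare_frequencies(assays[[pair[1]]], assays[[pair[2]]])
      list(groups = pair, chi2 = cm$chi2, p_value = cm$p_value)
    })
    tab <- do.call(rbind, lapply(names(fits), function(g) {
      f <- fits[[g]]
      data.frame(group = g, denominator = f$denominator,
                 ci_low_denominator = f$ci_denominator[1],
                 ci_high_denominator = f$ci_denominator[2],
                 log_likelihood = f$log_likelihood)
    }))
    utils::write.table(tab, file.path(output_dir, "lda_estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(estimates = est, comparisons = comp)
  })

  de_dataset <- NULL
  if ("de" %in% names(stages)) run_stage("de", function() {
    s <- stages$de
    dataset <- if (isTRUE(s$simulate)) {
      simulate_expression_dataset(sim_cfg)$dataset
    } else {
      m <- read_expression_tsv(s$expression_tsv)
      sheet <- utils::read.csv(s$samples_csv, stringsAsFactors = FALSE)
      expression_dataset(m[, sheet$sample, drop = FALSE],
                         factor(sheet$condition,
                                levels = unique(sheet$condition)))
    }
    de_dataset <<- dataset
    crit <- do.call(filter_criteria, s$filters %||% list())
    de <- moderated_t(dataset)
    kept <- apply_filters(de, crit)
    utils::write.table(de, file.path(output_dir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_genes = nrow(de), n_retained = nrow(kept),
         criteria = unclass(crit),
         top = top_genes(de)[c("up", "down")] |>
           lapply(function(d) d$gene))
  })

  if ("mara" %in% names(stages)) run_stage("mara", function() {
    s <- stages$mara
    if (isTRUE(s$simulate)) {
      sim <- simulate_motif_dataset(sim_cfg, s$planted_activity_changes)
      dataset <- sim$dataset; sites <- sim$sites
    } else {
      m <- read_expression_tsv(s$expression_tsv)
      sites <- read_sites_tsv(s$sites_tsv)
      cond <- factor(rep(c("virgin", "parous"), length.out = ncol(m)))
      if (!is.null(s$samples_csv)) {
        sheet <- utils::read.csv(s$samples_csv, stringsAsFactors = FALSE)
        m <- m[, sheet$sample, drop = FALSE]
        cond <- factor(sheet$condition, levels = unique(sheet$condition))
      }
      dataset <- expression_dataset(m, cond)
    }
    fit <- fit_activities(dataset, sites, lambda = s$lambda %||% "cv")
    chg <- motif_change_z(fit)
    write_expression_tsv(fit$activities,
                         file.path(output_dir, "motif_activities.tsv"),
                         id_col = "motif")
    utils::write.table(chg, file.path(output_dir, "motif_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(lambda = fit$lambda, n_motifs = nrow(fit$activities),
         top_motifs = utils::head(chg$motif, 5),
         top_z = utils::head(chg$z, 5))
  })

  if ("gsea" %in% names(stages)) run_stage("gsea", function() {
    s <- stages$gsea
    if (isTRUE(s$simulate)) {
      sim <- simulate_expression_dataset(sim_cfg)
      dataset <- sim$dataset
      collection <- list(
        planted_down = sim$truth$gene[sim$truth$sign < 0],
        planted_up = sim$truth$gene[sim$truth$sign > 0])
      collection <- collection[lengths(collection) > 0]
    } else {
      m <- read_expression_tsv(s$expression_tsv)
      sheet <- utils::read.csv(s$samples_csv, stringsAsFactors = FALSE)
      dataset <- expression_dataset(m[, sheet$sample, drop = FALSE],
                                    factor(sheet$condition,
                                           levels = unique(sheet$condition)))
      collection <- read_gmt(s$gene_sets)
    }
    cond <- dataset$condition
    ranked <- rank_by_difference(
      dataset$expr[, cond == levels(cond)[2], drop = FALSE],
      dataset$expr[, cond == levels(cond)[1], drop = FALSE])
    res <- permute_and_score(ranked, collection,
                             n_perm = s$n_perm %||% 1000L, seed = seed)
    utils::write.table(res, file.path(output_dir, "gsea_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_sets = nrow(res), n_perm = attr(res, "n_perm"),
         table = res[, c("set", "size", "es", "nes", "p_nominal", "fdr_q", "fwer")])
  })

  if ("ihc" %in% names(stages)) run_stage("ihc", function() {
    s <- stages$ihc
    if (isTRUE(s$simulate)) {
      pos_mu <- s$positive_color_mean %||% c(120, 70, 30)
      sim <- simulate_ihc_image(sim_cfg, positive_color_mean = pos_mu)
      image <- sim$image
      train <- with_seed(stream_seed(seed, "ihc-training"),
                         rmvnorm_chol(500, pos_mu, diag(25, 3)))
    } else {
      image <- read_rgb_png(s$image_png)
      train <- as.matrix(utils::read.csv(s$training_csv))
    }
    ref <- fit_color_reference(train)
    seg <- segment_by_mahalanobis(image, ref, quantile = s$quantile %||% 0.99)
    write_rgb_png(array(rep(seg$mask * 255, 3), c(dim(seg$mask), 3)),
                  file.path(output_dir, "ihc_mask.png"))
    list(positive_fraction = seg$positive_fraction,
         quantile = seg$quantile, n_analyzed = seg$n_analyzed)
  })

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("paritykit run (version ", x$version, ", config ", x$config_hash, ")\n",
      sep = "")
  for (nm in names(x$stages)) {
    cat("  stage ", nm, ": ", x$stages[[nm]]$status, "\n", sep = "")
  }
  invisible(x)
}
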