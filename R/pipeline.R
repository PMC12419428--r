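# End-to-end orchestration: Step 1 (instrument selection, harmonization,
# MR estimation and sensitivity per exposure-outcome pair), Step 2
# (meta-analysis of IVW estimates within disease groups), Step 3
# (colocalization of pairs with positive meta findings, optional ROC on an
# expression matrix). Driven by a single config (list or YAML file) with a
# mandatory seed so reports are reproducible.

default_thresholds <- function() {
  list(p_instrument = 5e-6, ld_r2 = 0.001, ld_window_kb = 10000,
       alpha = 0.05, fdr_alpha = 0.1, pp_h4 = 0.7, auc_flag = 0.6)
}

#' Assemble and validate a pipeline configuration
#'
#' @param exposures named character vector/list of exposure sumstats paths
#'   (names are exposure ids).
#' @param outcomes data.frame (or list coercible to one) with columns `id`,
#'   `path`, `disease`.
#' @param out_dir output directory (created if absent).
#' @param seed global RNG seed (mandatory).
#' @param ld_matrix optional path to an LD r^2 matrix TSV for clumping.
#' @param exclusion_list optional path to a confounder rsid list.
#' @param thresholds named list overriding any of `p_instrument` (5e-6),
#'   `ld_r2` (0.001), `ld_window_kb` (10000), `alpha` (0.05), `fdr_alpha`
#'   (0.1), `pp_h4` (0.7), `auc_flag` (0.6).
#' @param priors coloc priors, default `list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)`.
#' @param expression optional list with `matrix` and `labels` paths (TSV)
#'   and a `genes` character vector for ROC evaluation.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(exposures, outcomes, out_dir, seed,
                            ld_matrix = NULL, exclusion_list = NULL,
                            thresholds = list(), priors = list(),
                            expression = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop_tsmr("seed is mandatory", class = "tsmr_config_error")
  }
  if (!length(exposures)) {
    stop_tsmr("at least one exposure is required", class = "tsmr_config_error")
  }
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  if (!nrow(outcomes) || !all(c("id", "path", "disease") %in% names(outcomes))) {
    stop_tsmr("outcomes need columns id, path, disease",
              class = "tsmr_config_error")
  }
  th <- utils::modifyList(default_thresholds(), thresholds)
  stopifnot(th$p_instrument > 0, th$p_instrument < 1,
            th$ld_r2 >= 0, th$ld_r2 <= 1, th$ld_window_kb > 0,
            th$alpha > 0, th$alpha < 1, th$fdr_alpha > 0, th$fdr_alpha <= 1,
            th$pp_h4 > 0, th$pp_h4 < 1)
  pr <- utils::modifyList(list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5), priors)
  structure(list(exposures = exposures, outcomes = outcomes,
                 out_dir = out_dir, seed = as.integer(seed),
                 ld_matrix = ld_matrix, exclusion_list = exclusion_list,
                 thresholds = th, priors = pr, expression = expression),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    exposures = unlist(y$exposures),
    outcomes = do.call(rbind, lapply(y$outcomes, as.data.frame)),
    out_dir = y$out_dir, seed = y$seed,
    ld_matrix = y$ld_matrix, exclusion_list = y$exclusion_list,
    thresholds = y$thresholds %||% list(), priors = y$priors %||% list(),
    expression = y$expression)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg)), f)
  unname(tools::md5sum(f))
}

#' Run the three-step analysis pipeline
#'
#' Step 1: for every exposure x outcome pair, select instruments (p-value
#' threshold + exclusion list), clump by LD when a matrix is supplied,
#' harmonize, fit all MR estimators and the sensitivity battery; IVW
#' p-values are FDR-adjusted within each outcome dataset. Step 2: pool the
#' per-study IVW estimates within disease groups. Step 3: pairs whose
#' pooled fixed-effect FDR-adjusted p-value falls below `fdr_alpha` are
#' colocalized over the harmonized SNP set, and an expression matrix, when
#' provided, is evaluated by ROC. Reports (`table1.tsv`,
#' `sensitivity.tsv`, `table2.tsv`, `table3_<pair>.tsv`, `roc.tsv`) are
#' written under `out_dir` together with a `MANIFEST.tsv` listing each
#' file's MD5 content hash; every report carries the config hash and seed
#' in a comment-free sidecar column of the manifest.
#'
#' @param cfg a `pipeline_config` (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with `table1`, `sensitivity`, `table2`,
#'   `coloc`, `roc`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  th <- cfg$thresholds
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  manifest <- data.frame(file = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  emit <- function(df, name, layout = NULL) {
    path <- file.path(cfg$out_dir, name)
    if (is.null(layout)) {
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      write_report(df, path, layout)
    }
    manifest <<- rbind(manifest,
                       data.frame(file = name, md5 = unname(tools::md5sum(path)),
                                  stringsAsFactors = FALSE))
  }

  excl <- cfg$exclusion_list %||% character()
  ld <- if (!is.null(cfg$ld_matrix)) read_ld_matrix(cfg$ld_matrix) else NULL

  stage <- "step1"
  table1 <- NULL
  sens_rows <- NULL
  hsets <- list()
  step_guard <- function(expr, pair) {
    tryCatch(expr, error = function(e) {
      # preserve partial outputs with a manifest marking completion state
      utils::write.table(manifest, file.path(cfg$out_dir, "MANIFEST.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stop_tsmr("pipeline aborted at %s for pair %s: %s", stage, pair,
                conditionMessage(e), class = "tsmr_pipeline_error")
    })
  }

  for (ei in seq_along(cfg$exposures)) {
    exp_id <- names(cfg$exposures)[ei] %||% paste0("exposure", ei)
    exposure <- read_sumstats(cfg$exposures[[ei]], trait_id = exp_id)
    inst <- step_guard({
      x <- select_instruments(exposure, th$p_instrument, excl)
      if (!is.null(ld)) x <- ld_clump(x, ld, th$ld_r2, th$ld_window_kb)
      x
    }, exp_id)
    for (oi in seq_len(nrow(cfg$outcomes))) {
      out_id <- cfg$outcomes$id[oi]
      pair <- paste(exp_id, out_id, sep = ";")
      outcome <- read_sumstats(cfg$outcomes$path[oi], trait_id = out_id)
      res <- step_guard({
        h <- harmonize(inst, outcome)
        fit <- mr_fit(h, alpha = th$alpha, seed = cfg$seed)
        sens <- mr_sensitivity(h, alpha = th$alpha)
        list(h = h, fit = fit, sens = sens)
      }, pair)
      hsets[[pair]] <- list(exposure = exposure, outcome = outcome)
      tab <- mr_fit_table(res$fit)
      tab <- cbind(data.frame(disease = cfg$outcomes$disease[oi],
                              outcome_id = out_id, exposure_id = exp_id,
                              stringsAsFactors = FALSE), tab)
      table1 <- rbind(table1, tab)
      sens_rows <- rbind(sens_rows, data.frame(
        outcome_id = out_id, exposure_id = exp_id, nsnp = nrow(res$h$pairs),
        q_stat = res$sens$q_stat, q_pval = res$sens$q_pval, i2 = res$sens$i2,
        egger_intercept = res$sens$egger_intercept %||% NA_real_,
        egger_intercept_p = res$sens$egger_intercept_p %||% NA_real_,
        steiger_direction = res$sens$steiger_direction %||% NA,
        steiger_pval = res$sens$steiger_pval %||% NA_real_,
        influential = paste(res$sens$influential, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }

  # FDR within each outcome dataset, over the exposure x method family.
  table1$fdr_p <- bh_adjust(table1$pval, table1$outcome_id)
  emit(table1, "table1.tsv", layout = "mr")
  emit(sens_rows, "sensitivity.tsv")

  stage <- "step2"
  ivw <- table1[grepl("^IVW", table1$method) | table1$method == "WaldRatio", ]
  grouping <- split(cfg$outcomes$id, cfg$outcomes$disease)
  table2 <- step_guard(meta_group(ivw, grouping), "meta")
  table2$fdr_p <- bh_adjust(table2$fixed_p)
  emit(table2, "table2.tsv", layout = "meta")

  stage <- "step3"
  positive <- table2[table2$fdr_p < th$fdr_alpha, , drop = FALSE]
  coloc_fits <- list()
  for (i in seq_len(nrow(positive))) {
    exp_id <- positive$exposure_id[i]
    for (out_id in grouping[[positive$disease[i]]]) {
      pair <- paste(exp_id, out_id, sep = ";")
      hs <- hsets[[pair]]
      if (is.null(hs)) next
      shared <- intersect(hs$outcome$rsid, hs$exposure$rsid)
      if (length(shared) < 1) next
      fit <- step_guard(
        coloc_abf(hs$outcome[match(shared, hs$outcome$rsid), ],
                  hs$exposure[match(shared, hs$exposure$rsid), ],
                  p1 = cfg$priors$p1, p2 = cfg$priors$p2,
                  p12 = cfg$priors$p12),
        pair)
      coloc_fits[[pair]] <- fit
      emit(fit$snp, sprintf("table3_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", pair)),
           layout = "coloc")
    }
  }

  roc_tab <- NULL
  if (!is.null(cfg$expression)) {
    mat <- as.matrix(utils::read.delim(cfg$expression$matrix, row.names = 1,
                                       check.names = FALSE))
    labels <- utils::read.delim(cfg$expression$labels)[[1]]
    roc_tab <- step_guard(
      roc_genes(mat, labels, cfg$expression$genes %||% rownames(mat),
                seed = cfg$seed, auc_flag_threshold = th$auc_flag),
      "roc")
    emit(roc_tab, "roc.tsv")
  }

  manifest$config_md5 <- hash
  manifest$seed <- cfg$seed
  utils::write.table(manifest, file.path(cfg$out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(table1 = table1, sensitivity = sens_rows, table2 = table2,
                 coloc = coloc_fits, roc = roc_tab, manifest = manifest))
}
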