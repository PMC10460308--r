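# ---- Pipeline orchestration -----------------------------------------------

#' Stable hash of a configuration object
#'
#' @param config Any R object.
#' @return Character SHA-1 hash.
#' @export
config_hash <- function(config) {
  digest::digest(config, algo = "sha1")
}

stage_seed <- function(seed, stage) {
  h <- digest::digest(paste(seed, stage, sep = "/"), algo = "sha1")
  as.integer(strtoi(substr(h, 1, 7), 16L))
}

#' Pipeline run configuration
#'
#' @param input `NULL` to generate a synthetic cohort from `preset`, or the
#'   path of a cohort CSV.
#' @param preset Generator preset name (currently `"paper_like"`) or a
#'   `generator_config`.
#' @param seed Root seed; per-stage seeds are derived from it so disabling
#'   a stage leaves the others unchanged.
#' @param n Cohort size for generated input.
#' @param stages Stages to run, a subset of `"descriptives"`,
#'   `"zero_order"`, `"ggm"`, `"centrality"`, `"regression"` (scoring and
#'   grouping always run).
#' @param edge_alpha Fisher display threshold of the zero-order network.
#' @param gamma,gamma_path EBIC hyperparameters of the GGM stage.
#' @param m,mice_maxit Imputation count and chained-equation iterations.
#' @param missing_rate Missingness injected by the generator.
#' @param include_q7 Count the failed-cut-down harm among the zero-order
#'   network indicators?
#' @param out_dir Output directory (`NULL` = no files written).
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = "paper_like", seed = 1L,
                       n = 1107, stages = c("descriptives", "zero_order",
                                            "ggm", "centrality",
                                            "regression"),
                       edge_alpha = 0.05, gamma = 0, gamma_path = 0.5,
                       m = 20, mice_maxit = 10, missing_rate = 0.05,
                       include_q7 = FALSE, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(edge_alpha > 0, edge_alpha < 1, m >= 2)
  structure(list(input = input, preset = preset, seed = as.integer(seed),
                 n = n, stages = stages, edge_alpha = edge_alpha,
                 gamma = gamma, gamma_path = gamma_path, m = m,
                 mice_maxit = mice_maxit, missing_rate = missing_rate,
                 include_q7 = include_q7, out_dir = out_dir),
            class = "run_config")
}

zero_order_indicators <- function(ind, substances = assist_substances(),
                                  include_q7 = FALSE) {
  harms <- c("urge", "problems", "failed_expect", "concerns")
  if (include_q7) harms <- c(harms, "cutdown_fail")
  keep <- unlist(lapply(substances, function(s)
    paste0(s, "_", c("used", harms))))
  keep <- setdiff(keep, "tobacco_failed_expect")  # item never administered
  ind[, intersect(keep, names(ind)), drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort input (generate or read), involvement scoring,
#' dichotomisation and grouping, descriptive tables, zero-order tetrachoric
#' network with MDS layout, partial-correlation GGM, centrality ranking,
#' and MI-pooled multinomial regression of group membership. Each stage
#' draws its own seed from the root seed, so toggling one stage never
#' changes another's output. When `out_dir` is set, tables are written as
#' CSV, networks additionally as GraphML, and a manifest records the seed
#' and configuration hash.
#'
#' @param config `run_config`.
#' @return List of class `report_bundle` with elements `cohort`, `scores`,
#'   `indicators`, `groups`, `descriptives`, `zero_order` (network +
#'   layout), `ggm`, `centrality` (profile + ranking), `regression`
#'   (pooled effects per outcome contrast), `qc`, `meta`, and `errors`
#'   (per-stage error messages, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # hash the scientific configuration only: stage toggles and output paths
  # must not change the content of the stages that do run
  hash <- config_hash(config[setdiff(names(config),
                                     c("out_dir", "stages"))])
  bundle <- list(meta = list(seed = config$seed, config_hash = hash,
                             stages = config$stages))
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  # cohort
  cohort <- run_stage("input", {
    if (!is.null(config$input)) {
      read_cohort(config$input)
    } else {
      gc_ <- if (inherits(config$preset, "generator_config")) {
        config$preset
      } else if (identical(config$preset, "paper_like")) {
        paper_like_config(n = config$n,
                          seed = stage_seed(config$seed, "generate"),
                          missing_rate = config$missing_rate)
      } else {
        stop("unknown preset '", config$preset, "'")
      }
      generate_cohort(gc_)
    }
  })
  if (is.null(cohort)) {
    bundle$errors <- errors
    class(bundle) <- "report_bundle"
    return(bundle)
  }
  bundle$cohort <- cohort
  scores <- run_stage("scoring", involvement_scores(cohort))
  ind <- run_stage("indicators", dichotomize_items(cohort))
  bundle$scores <- scores
  bundle$indicators <- ind
  groups <- run_stage("grouping", assign_group(ind))
  bundle$groups <- groups
  miss_frac <- vapply(cohort, function(x) mean(is.na(x)), numeric(1))
  bundle$qc <- list(missing_per_variable = miss_frac,
                    harm_without_use = attr(ind, "qc_harm_without_use"),
                    group_counts = table(groups, useNA = "ifany"))

  if ("descriptives" %in% config$stages && !is.null(ind)) {
    bundle$descriptives <- run_stage("descriptives", {
      dat <- cbind(cohort, ind,
                   poly_incl = classify_polysubstance(ind, TRUE),
                   poly_excl = classify_polysubstance(ind, FALSE),
                   group = groups)
      dat$n_substances <- rowSums(
        as.matrix(ind[, paste0(assist_substances(), "_used")]), na.rm = FALSE)
      use_groups <- droplevels(factor(
        dat$group, levels = c("alcohol_tobacco_other", "cannabis_no_ats",
                              "ats")))
      dat$use_group <- factor(dat$group,
                              levels = c("alcohol_tobacco_other",
                                         "cannabis_no_ats", "ats"))
      vars <- c(paste0(assist_substances(), "_used"), "n_substances",
                "any_urge", "any_problems", "any_failed_expect",
                "any_concerns")
      describe_by_group(dat, vars, "use_group")
    })
  }
  if ("zero_order" %in% config$stages && !is.null(ind)) {
    bundle$zero_order <- run_stage("zero_order", {
      nodes <- zero_order_indicators(ind, include_q7 = config$include_q7)
      net <- build_zero_order_network(nodes, alpha = config$edge_alpha)
      layout <- tryCatch(
        mds_layout(net, seed = stage_seed(config$seed, "mds")),
        error = function(e) NULL)
      list(network = net, layout = layout)
    })
  }
  ggm_res <- NULL
  if ("ggm" %in% config$stages && !is.null(scores)) {
    ggm_res <- run_stage("ggm", {
      logscores <- scores[, paste0(assist_substances(), "_logscore")]
      colnames(logscores) <- assist_substances()
      fit_ggm(logscores, gamma = config$gamma,
              gamma_path = config$gamma_path)
    })
    bundle$ggm <- ggm_res
  }
  if ("centrality" %in% config$stages && !is.null(ggm_res)) {
    bundle$centrality <- run_stage("centrality", {
      prof <- centrality_indices(ggm_res$network)
      list(profile = prof, ranking = rank_substances(prof))
    })
  }
  if ("regression" %in% config$stages && !is.null(groups)) {
    bundle$regression <- run_stage("regression", {
      regress_groups(cohort, groups, m = config$m,
                     maxit = config$mice_maxit,
                     seed = stage_seed(config$seed, "regression"))
    })
  }
  bundle$errors <- errors
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' MI-pooled multinomial regression of substance-use group
#'
#' Drops participants whose group cannot be resolved (the group is the
#' analysis stratum, not imputed), imputes missing covariates by chained
#' equations, z-scores the six clinical scale totals within each completed
#' dataset, fits the package's Newton multinomial logit (reference group:
#' no recent use) per imputation and pools by Rubin's rules.
#'
#' @param cohort Cohort data frame with demographic/clinical columns.
#' @param groups Factor from [assign_group()].
#' @param m,maxit,seed Imputation controls.
#' @return List with `pooled` (data frame of pooled effects with `outcome`
#'   and `term` columns), `m`, `n`, `fits` (per-imputation fits).
#' @export
regress_groups <- function(cohort, groups, m = 20, maxit = 10, seed = 1L) {
  covars <- c("age", "sex_at_birth", "lgbtiqa", "region", "edu_employment",
              "primary_diagnosis", "phq9", "gad7", "rrs10", "psqi", "cas",
              "pq16")
  keep <- !is.na(groups)
  dat <- cohort[keep, covars, drop = FALSE]
  dat$group <- factor(as.character(groups[keep]),
                      levels = c("none", "alcohol_tobacco_other",
                                 "cannabis_no_ats", "ats"))
  for (v in c("sex_at_birth", "lgbtiqa", "region", "edu_employment",
              "primary_diagnosis")) {
    ref <- c(sex_at_birth = "female", lgbtiqa = "no", region = "metro",
             edu_employment = "studying_only",
             primary_diagnosis = "depression")[[v]]
    dat[[v]] <- stats::relevel(factor(dat[[v]]), ref = ref)
  }
  imp <- mice_impute(dat, m = m, maxit = maxit, seed = seed)
  scales <- c("phq9", "gad7", "rrs10", "psqi", "cas", "pq16")
  fits <- lapply(imp$imputations, function(d) {
    for (sc in scales) d[[sc]] <- as.numeric(scale(d[[sc]]))
    fit_multinomial(group ~ age + sex_at_birth + lgbtiqa + region +
                      edu_employment + primary_diagnosis + phq9 + gad7 +
                      rrs10 + psqi + cas + pq16, d)
  })
  pooled <- pool_rubin(fits, n_obs = fits[[1]]$n)
  pooled$outcome <- sub(":.*$", "", pooled$term)
  pooled$term <- sub("^[^:]*:", "", pooled$term)
  list(pooled = pooled, m = m, n = fits[[1]]$n, fits = fits)
}

network_to_igraph <- function(net) {
  W <- net$weights
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(net$mask)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$displayed <- net$mask[el]
  }
  g
}

network_edge_table <- function(net) {
  W <- net$weights
  nodes <- net$nodes
  ut <- which(upper.tri(W), arr.ind = TRUE)
  data.frame(node_i = nodes[ut[, 1]], node_j = nodes[ut[, 2]],
             weight = W[ut],
             p = if (!is.null(net$p)) net$p[ut] else NA_real_,
             displayed = net$mask[ut])
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- bundle$meta
  put <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    df <- as.data.frame(df)
    df$config_hash <- meta$config_hash
    df$seed <- meta$seed
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  put(bundle$descriptives, "descriptives.csv")
  if (!is.null(bundle$zero_order)) {
    put(network_edge_table(bundle$zero_order$network), "zero_order_edges.csv")
    igraph::write_graph(network_to_igraph(bundle$zero_order$network),
                        file.path(out_dir, "zero_order.graphml"),
                        format = "graphml")
    if (!is.null(bundle$zero_order$layout)) {
      lay <- bundle$zero_order$layout
      put(data.frame(node = rownames(lay$points), lay$points,
                     stress = lay$stress), "zero_order_layout.csv")
    }
  }
  if (!is.null(bundle$ggm)) {
    put(network_edge_table(bundle$ggm$network), "ggm_edges.csv")
    igraph::write_graph(network_to_igraph(bundle$ggm$network),
                        file.path(out_dir, "ggm.graphml"), format = "graphml")
    jsonlite::write_json(
      list(config_hash = meta$config_hash, seed = meta$seed,
           gamma = bundle$ggm$model$gamma,
           gamma_path = bundle$ggm$model$gamma_path,
           ebic = bundle$ggm$model$ebic,
           ebic_start = bundle$ggm$model$ebic_start,
           n_used = bundle$ggm$n_used,
           path = bundle$ggm$model$path),
      file.path(out_dir, "ggm_meta.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(bundle$centrality)) {
    put(bundle$centrality$profile, "centrality.csv")
  }
  if (!is.null(bundle$regression)) {
    put(bundle$regression$pooled, "regression.csv")
  }
  jsonlite::write_json(
    list(seed = meta$seed, config_hash = meta$config_hash,
         stages = meta$stages,
         group_counts = as.list(bundle$qc$group_counts),
         missing_per_variable = as.list(bundle$qc$missing_per_variable),
         errors = bundle$errors),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis bundle (seed ", x$meta$seed, ", hash ",
      substr(x$meta$config_hash, 1, 8), ")\n", sep = "")
  if (!is.null(x$cohort)) cat("  cohort: ", nrow(x$cohort), " participants\n", sep = "")
  if (!is.null(x$qc$group_counts)) {
    gc_ <- x$qc$group_counts
    cat("  groups:", paste(names(gc_), as.integer(gc_), sep = "=",
                           collapse = ", "), "\n")
  }
  if (!is.null(x$zero_order)) {
    cat("  zero-order network: mean r_t =",
        format(x$zero_order$network$mean_r, digits = 3), "\n")
  }
  if (!is.null(x$ggm)) {
    cat("  GGM:", length(x$ggm$model$edges), "edges\n")
  }
  if (!is.null(x$centrality)) {
    cat("  top-centrality node(s):",
        paste(x$centrality$ranking$top_nodes, collapse = ", "), "\n")
  }
  if (length(x$errors)) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
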