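#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full analysis run.
#' Either `simulate` is given (a list with entries `topology`,
#' `effect`, `covariate`, `n_per_group` describing a synthetic study)
#' or `paths` must point at an atlas TSV, a directory of per-subject
#' adjacency TSVs and a covariates TSV whose `group` column defines
#' the two cohorts.
#'
#' @param out_dir output directory for stage results and the manifest.
#' @param paths list with `atlas`, `subjects_dir`, `covariates` (may be
#'   `NULL` when simulating).
#' @param simulate `NULL`, or a list describing the synthetic study.
#' @param preprocessing list: `threshold_fraction` (default 0.01),
#'   `rescale` (default TRUE).
#' @param nbs list: `t_thresh` (default 2.1), `n_perm` (default 5000),
#'   `alpha` (default 0.05).
#' @param modularity list: `n_restarts` (default 1000),
#'   `n_restarts_subject` (default 100), `n_perm` (default 1000).
#' @param richclub list: `n_random` (default 1000).
#' @param association list: `confounds` (default `c("age", "gender")`),
#'   `scores` (score columns; default all numeric score columns).
#' @param smallworld list: `n_random` (default 100).
#' @param master_seed integer master seed; every stochastic stage
#'   derives its own seed from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       paths = list(atlas = NULL, subjects_dir = NULL,
                                    covariates = NULL),
                       simulate = NULL,
                       preprocessing = list(),
                       nbs = list(),
                       modularity = list(),
                       richclub = list(),
                       association = list(),
                       smallworld = list(),
                       master_seed = 1L) {
  defaults <- function(given, def) utils::modifyList(def, as.list(given))
  cfg <- list(
    out_dir = out_dir,
    paths = paths,
    simulate = simulate,
    preprocessing = defaults(preprocessing,
                             list(threshold_fraction = 0.01, rescale = TRUE)),
    nbs = defaults(nbs, list(t_thresh = 2.1, n_perm = 5000, alpha = 0.05)),
    modularity = defaults(modularity,
                          list(n_restarts = 1000, n_restarts_subject = 100,
                               n_perm = 1000)),
    richclub = defaults(richclub, list(n_random = 1000)),
    association = defaults(association,
                           list(confounds = c("age", "gender"),
                                scores = NULL)),
    smallworld = defaults(smallworld, list(n_random = 100)),
    master_seed = as.integer(master_seed)
  )
  with(cfg$preprocessing, {
    if (threshold_fraction < 0 || threshold_fraction >= 1)
      stopf("preprocessing$threshold_fraction must be in [0, 1)")
  })
  if (cfg$nbs$t_thresh <= 0) stopf("nbs$t_thresh must be > 0")
  if (cfg$nbs$n_perm < 100) stopf("nbs$n_perm must be >= 100")
  if (cfg$nbs$alpha <= 0 || cfg$nbs$alpha >= 1)
    stopf("nbs$alpha must be in (0, 1)")
  if (cfg$modularity$n_restarts < 1) stopf("modularity$n_restarts must be >= 1")
  if (cfg$richclub$n_random < 1) stopf("richclub$n_random must be >= 1")
  if (is.null(cfg$simulate)) {
    for (p in c("atlas", "subjects_dir", "covariates"))
      if (is.null(cfg$paths[[p]]))
        stopf("paths$%s is required when not simulating", p)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path config file; `.json` is parsed as JSON, anything else
#'   as YAML.
#' @param out_dir optional override of the configured output
#'   directory.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(run_config, raw)
}

load_study <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    tspec <- do.call(topology_spec,
                     utils::modifyList(list(seed = cfg$master_seed),
                                       as.list(sim$topology %||% list())))
    eff <- if (is.null(sim$effect)) NULL else {
      if (inherits(sim$effect, "effect_spec")) sim$effect
      else do.call(effect_spec, as.list(sim$effect))
    }
    cv <- if (is.null(sim$covariate)) NULL else {
      if (inherits(sim$covariate, "covariate_spec")) sim$covariate
      else do.call(covariate_spec, as.list(sim$covariate))
    }
    generate_cohorts(tspec, eff, cv, n_per_group = sim$n_per_group %||% 15)
  } else {
    atlas <- read_atlas(cfg$paths$atlas)
    cov <- read_covariates(cfg$paths$covariates)
    if (!"group" %in% names(cov)) stopf("covariates need a 'group' column")
    groups <- unique(cov$group)
    if (length(groups) != 2) stopf("expected exactly 2 groups, found %d",
                                   length(groups))
    make <- function(g) {
      ids <- cov$subject_id[cov$group == g]
      subs <- lapply(ids, function(id) {
        f <- file.path(cfg$paths$subjects_dir, paste0(id, ".tsv"))
        if (!file.exists(f)) stopf("missing adjacency file for subject '%s'",
                                   id)
        read_connectome(f, atlas, subject_id = id)
      })
      cohort(g, subs, cov[cov$group == g, , drop = FALSE])
    }
    list(A = make(groups[1]), B = make(groups[2]), atlas = atlas)
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full connectome topology pipeline
#'
#' Executes simulate/load, preprocessing, NBS, per-subject graph
#' metrics, community/hub/fingerprint analysis, rich-club analysis and
#' score association as one reproducible run. Every stage writes its
#' outputs (TSV/JSON) under `config$out_dir` and is summarised in a
#' machine-readable `manifest.json` (configuration echo, derived
#' seeds, wall-clock per stage). Rerunning with the same configuration
#' reproduces all outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return The output directory, invisibly; the full result set as the
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(stage) derive_seed(config$master_seed, stage)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   stages = list())
  results <- list()
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    say("[%s] running ...", name)
    val <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[name]] <<- list(seconds = round(dt, 2))
    say("[%s] done (%.1fs)", name, dt)
    val
  }

  study <- stage("load", load_study(config))
  if (!is.null(config$simulate))
    stage("write-input", write_study(study, file.path(out, "input")))

  pp <- config$preprocessing
  study$A <- stage("preprocess-A",
                   preprocess_cohort(study$A, pp$threshold_fraction,
                                     pp$rescale))
  study$B <- stage("preprocess-B",
                   preprocess_cohort(study$B, pp$threshold_fraction,
                                     pp$rescale))

  nbs_res <- stage("nbs", {
    r <- nbs_test(study$A, study$B, t_thresh = config$nbs$t_thresh,
                  n_perm = config$nbs$n_perm, seed = seed_of(101L))
    if (length(r$components) > 0) {
      comp_df <- do.call(rbind, lapply(seq_along(r$components), function(k) {
        df <- r$components[[k]]
        df$component <- k
        df$p_fwer <- r$p_fwer[k]
        df$region_i <- study$atlas$label[df$i]
        df$region_j <- study$atlas$label[df$j]
        df
      }))
      write_tsv(comp_df, file.path(out, "nbs_components.tsv"))
    }
    jsonlite::write_json(
      list(t_thresh = r$primary_threshold, n_perm = r$n_perm,
           n_components = length(r$components),
           extent = r$extent, p_fwer = r$p_fwer,
           significant = sum(r$p_fwer < config$nbs$alpha)),
      file.path(out, "nbs_summary.json"), auto_unbox = TRUE, digits = NA)
    r
  })
  results$nbs <- nbs_res

  metrics <- stage("metrics", {
    per_subject <- function(ch) {
      do.call(rbind, lapply(ch$subjects, function(s) {
        gl <- global_metrics(s, n_random = config$smallworld$n_random,
                             n_restarts = config$modularity$n_restarts_subject,
                             seed = seed_of(104L))
        cbind(subject_id = s$subject_id, group = ch$group_label, gl)
      }))
    }
    gm <- rbind(per_subject(study$A), per_subject(study$B))
    write_tsv(gm, file.path(out, "global_metrics.tsv"))
    gm
  })
  results$global_metrics <- metrics

  modules <- stage("modules", {
    ref <- select_reference_partition(
      study$A, study$B, n_restarts = config$modularity$n_restarts,
      n_restarts_subject = config$modularity$n_restarts_subject,
      seed = seed_of(102L))
    write_tsv(data.frame(node = seq_along(ref$reference$assignment),
                         label = study$atlas$label,
                         module = ref$reference$assignment),
              file.path(out, "reference_partition.tsv"))
    hubsA <- classify_hubs(group_average(study$A), ref$reference)
    hubsB <- classify_hubs(group_average(study$B), ref$reference)
    write_tsv(cbind(group = study$A$group_label, hubsA),
              file.path(out, "hubs_A.tsv"))
    write_tsv(cbind(group = study$B$group_label, hubsB),
              file.path(out, "hubs_B.tsv"))
    fpA <- modular_fingerprint(group_average(study$A), ref$reference, hubsA)
    fpB <- modular_fingerprint(group_average(study$B), ref$reference, hubsB)
    for (g in c("A", "B")) {
      fp <- if (g == "A") fpA else fpB
      write_tsv(as.data.frame(fp$inter),
                file.path(out, sprintf("fingerprint_inter_%s.tsv", g)))
      write_tsv(data.frame(module = seq_along(fp$intra), intra = fp$intra),
                file.path(out, sprintf("fingerprint_intra_%s.tsv", g)))
      write_tsv(as.data.frame(fp$connector_inter),
                file.path(out, sprintf("fingerprint_connector_%s.tsv", g)))
    }
    cmp <- compare_modular_topology(study$A, study$B, ref$reference,
                                    n_perm = config$modularity$n_perm,
                                    seed = seed_of(105L))
    write_tsv(cmp, file.path(out, "modular_comparison.tsv"))
    list(reference = ref, hubsA = hubsA, hubsB = hubsB,
         fingerprintA = fpA, fingerprintB = fpB, comparison = cmp)
  })
  results$modules <- modules

  rc <- stage("richclub", {
    res <- lapply(list(A = study$A, B = study$B), function(ch) {
      curve <- normalized_rich_club(group_average(ch),
                                    n_random = config$richclub$n_random,
                                    seed = seed_of(103L))
      curve
    })
    both <- rbind(cbind(group = study$A$group_label, as.data.frame(res$A)),
                  cbind(group = study$B$group_label, as.data.frame(res$B)))
    write_tsv(both, file.path(out, "richclub_curves.tsv"))
    res
  })
  results$richclub <- rc

  assoc <- stage("associate", {
    scores <- config$association$scores
    covB <- study$B$covariates
    if (is.null(scores)) {
      skip <- c("subject_id", "group", "age", "gender")
      scores <- setdiff(names(covB)[vapply(covB, is.numeric, logical(1))],
                        skip)
    }
    if (length(scores) == 0) {
      NULL
    } else {
      # nodal efficiency per subject (group B), tested node-by-node for a
      # group difference; nodes differing at p < 0.05 (uncorrected) are
      # associated with each score under the configured confounds
      EA <- vapply(study$A$subjects, function(s) nodal_efficiency(s),
                   numeric(nrow(study$atlas)))
      EB <- vapply(study$B$subjects, function(s) nodal_efficiency(s),
                   numeric(nrow(study$atlas)))
      pnode <- vapply(seq_len(nrow(EA)), function(i) {
        stats::t.test(EA[i, ], EB[i, ], var.equal = TRUE)$p.value
      }, numeric(1))
      sel <- which(pnode < 0.05)
      tabs <- lapply(sel, function(i) {
        associate_metric(study$B, EB[i, ], scores,
                         confounds = config$association$confounds,
                         metric_name = sprintf("e_nodal[%s]",
                                               study$atlas$label[i]))
      })
      tab <- if (length(tabs)) do.call(rbind, tabs) else NULL
      if (!is.null(tab)) write_tsv(tab, file.path(out, "associations.tsv"))
      tab
    }
  })
  results$associations <- assoc

  manifest$seeds <- list(master = config$master_seed,
                         nbs = seed_of(101L), modularity = seed_of(102L),
                         richclub = seed_of(103L), smallworld = seed_of(104L),
                         modular_comparison = seed_of(105L))
  manifest$package_version <- as.character(utils::packageVersion("structnet"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(structure(out, results = results))
}
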