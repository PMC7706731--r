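default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "enhancerkit_run",
    scale = "desk",
    stages = c("simulate", "train", "evaluate", "interpret", "architecture",
               "cross_species"),
    cohort = list(n_regions = 100L, region_length = 500L),
    model = list(),
    thresholds = list(class_call = 0.5, topic_binarize = 0.995,
                      bls_presence = 0),
    evolve = list(tree = "((human:0.05,dog:0.07):0.1,(mouse:0.12,fish:0.3):0.05);",
                  motif_loss_rate = 0.15),
    interpret = list(n_regions = 30L, n_refs = 10L, n_steps = 10L),
    fragments = list(depth = 50L)
  )
}

known_config_keys <- function() {
  c("seed", "out_dir", "scale", "stages", "cohort", "model", "thresholds",
    "evolve", "interpret", "fragments")
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, checks it against the known key
#' set and value constraints, and returns the completed configuration.
#' All violations are reported together, not just the first; unknown keys
#' are an error listing them.
#'
#' @param config Path to a YAML/JSON file, or a config list.
#' @return A validated `run_config` list (defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  assert_that(is.list(config), "config must be a list or a YAML/JSON file")
  unknown <- setdiff(names(config), known_config_keys())
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(default_run_config(), config)
  violations <- character(0)
  note <- function(msg) violations <<- c(violations, msg)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0 ||
      cfg$seed != round(cfg$seed)) {
    note("seed must be a single nonnegative integer")
  }
  if (!cfg$scale %in% c("desk", "paper")) {
    note("scale must be 'desk' or 'paper'")
  }
  bad_stage <- setdiff(cfg$stages, default_run_config()$stages)
  if (length(bad_stage) > 0) {
    note(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  if (!is.numeric(cfg$cohort$n_regions) || cfg$cohort$n_regions < 10) {
    note("cohort.n_regions must be >= 10")
  }
  for (nm in names(cfg$thresholds)) {
    v <- cfg$thresholds[[nm]]
    if (!is.numeric(v) || v < 0 || (nm != "bls_presence" && v >= 1)) {
      note(paste0("thresholds.", nm, " out of range"))
    }
  }
  if (cfg$evolve$motif_loss_rate < 0 || cfg$evolve$motif_loss_rate > 1) {
    note("evolve.motif_loss_rate must be in [0,1]")
  }
  if (length(violations) > 0) {
    abort(paste0("invalid configuration:\n  - ",
                 paste(violations, collapse = "\n  - ")))
  }
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> train -> evaluate -> interpret ->
#' architecture -> cross-species on the synthetic cohort, writing all
#' stage outputs, a Markdown report and a manifest (config, file MD5
#' hashes, per-stage runtimes) under `config$out_dir`. Stages can be
#' omitted via `config$stages`; a stage whose inputs are missing fails
#' fast with a dependency error naming the stage.
#'
#' @param config A `run_config` (see [validate_config()]), a config list,
#'   or a path to a YAML file.
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  runtimes <- list()
  report <- c("# enhancerkit synthetic-study report", "")
  t_all <- proc.time()[3]

  need <- function(obj, from_stage, for_stage) {
    if (is.null(obj)) {
      abort(paste0("pipeline stage '", for_stage, "' requires stage '",
                   from_stage, "' in config$stages"))
    }
    obj
  }

  cohort <- NULL
  model <- NULL
  eval_tbl <- NULL

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    specs <- default_class_specs(n_regions = cfg$cohort$n_regions,
                                 region_length = cfg$cohort$region_length)
    cohort <- simulate_regions(specs, seed = derive_seed(cfg$seed, "simulate"))
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    runtimes$simulate <- proc.time()[3] - t0
    report <- c(report,
                paste0("* simulated ", nrow(cohort$regions), " regions in ",
                       length(cohort$classes), " classes, ",
                       nrow(cohort$truth_hits), " implanted motif instances"))
  }

  if ("train" %in% stages) {
    t0 <- proc.time()[3]
    cohort <- need(cohort, "simulate", "train")
    mcfg_args <- utils::modifyList(
      list(n_classes = length(cohort$classes),
           seed = derive_seed(cfg$seed, "train")),
      cfg$model
    )
    mcfg <- if (identical(cfg$scale, "paper")) {
      do.call(model_config, mcfg_args)
    } else {
      do.call(desk_config, mcfg_args)
    }
    model <- build_model(mcfg, class_names = cohort$classes)
    model <- train_model(model, cohort$sequences, cohort$label_matrix)
    write_model(model, file.path(cfg$out_dir, "model.json"))
    runtimes$train <- proc.time()[3] - t0
    report <- c(report, paste0("* trained model (", n_parameters(model),
                               " parameters), final loss ",
                               signif(tail(model$log$loss, 1), 4)))
  }

  if ("evaluate" %in% stages) {
    t0 <- proc.time()[3]
    model <- need(model, "train", "evaluate")
    eval_tbl <- evaluate_model(model, cohort$sequences, cohort$label_matrix,
                               cohort$regions$chrom, "chr2")
    readr::write_tsv(eval_tbl, file.path(cfg$out_dir, "evaluation.tsv"),
                     progress = FALSE)
    runtimes$evaluate <- proc.time()[3] - t0
    test_auc <- eval_tbl$auroc[eval_tbl$split == "test"]
    report <- c(report, paste0("* held-out (chr2) auROC per class: ",
                               paste(signif(test_auc, 3), collapse = ", ")))
  }

  scan_hits <- NULL
  if ("interpret" %in% stages) {
    t0 <- proc.time()[3]
    model <- need(model, "train", "interpret")
    fp <- filters_to_pwms(model, n_random = 50000L,
                          seed = derive_seed(cfg$seed, "filters"))
    fam <- match_filters(fp, cohort$motifs)
    write_pwm_jaspar(
      tibble(name = paste0("filter_", fp$filter), pwm = fp$pwm),
      file.path(cfg$out_dir, "filter_pwms.jaspar")
    )
    n_r <- min(cfg$interpret$n_regions,
               sum(cohort$regions$class == cohort$classes[1]))
    mel_idx <- which(cohort$regions$class == "MEL")[seq_len(n_r)]
    mes_idx <- which(cohort$regions$class == "MES")[seq_len(n_r)]
    refs <- cohort$sequences[cohort$regions$class == "BG"]
    attr_for <- function(idx, class_id) {
      lapply(idx, function(i) {
        attribute(model, cohort$sequences[[i]], class_id, refs,
                  n_refs = cfg$interpret$n_refs,
                  n_steps = cfg$interpret$n_steps,
                  seed = derive_seed(cfg$seed, paste0("attr", i)))
      })
    }
    mel_attr <- attr_for(mel_idx, "MEL")
    mes_attr <- attr_for(mes_idx, "MES")
    cal <- calibrate_motif_thresholds(model,
                                      cohort$sequences[mel_idx], mel_attr,
                                      cohort$sequences[mes_idx], mes_attr)
    scan_hits <- scan_motif_instances(model, cohort$sequences[mel_idx],
                                      mel_attr, cal, filter_pwms = fp,
                                      filter_families = fam)
    scan_hits <- dedupe_hits(scan_hits)
    write_hits_bed(scan_hits, file.path(cfg$out_dir, "motif_hits.bed"))
    mut <- saturation_mutagenesis(model, cohort$sequences[[mel_idx[1]]])
    readr::write_tsv(tidy(mut), file.path(cfg$out_dir, "satmut_example.tsv"),
                     progress = FALSE)
    runtimes$interpret <- proc.time()[3] - t0
    report <- c(report, paste0("* interpreted model: ", nrow(scan_hits),
                               " motif hits located on ", n_r,
                               " melanocytic-like regions"))
  }

  if ("architecture" %in% stages) {
    t0 <- proc.time()[3]
    scan_hits <- need(scan_hits, "interpret", "architecture")
    counts <- count_motif_hits(scan_hits, regions = unique(scan_hits$region))
    comp <- classify_composition(counts)
    readr::write_tsv(comp$assignments,
                     file.path(cfg$out_dir, "composition_classes.tsv"),
                     progress = FALSE)
    frag <- simulate_fragments(cohort$regions, depth = cfg$fragments$depth,
                               seed = derive_seed(cfg$seed, "fragments"))
    prof <- tn5_cut_profile(frag$fragments, cohort$regions, flank_bp = 200L)
    readr::write_tsv(prof, file.path(cfg$out_dir, "tn5_profile.tsv"),
                     progress = FALSE)
    runtimes$architecture <- proc.time()[3] - t0
    report <- c(report, paste0("* composition classes: ",
                               nrow(comp$inventory)))
  }

  if ("cross_species" %in% stages) {
    t0 <- proc.time()[3]
    cohort <- need(cohort, "simulate", "cross_species")
    model <- need(model, "train", "cross_species")
    n_cs <- min(40L, nrow(cohort$regions))
    mel_ids <- cohort$regions$name[cohort$regions$class == "MEL"]
    sub_ids <- head(mel_ids, n_cs)
    sub <- cohort
    sub$sequences <- cohort$sequences[sub_ids]
    sub$truth_hits <- cohort$truth_hits[cohort$truth_hits$region %in% sub_ids, ]
    evolved <- evolve_cohort(sub, cfg$evolve$tree,
                             motif_loss_rate = cfg$evolve$motif_loss_rate,
                             seed = derive_seed(cfg$seed, "evolve"))
    blst <- bls_table(evolved$sequences, cohort$motifs, evolved$tree,
                      presence_threshold = cfg$thresholds$bls_presence,
                      seed = derive_seed(cfg$seed, "bls"))
    readr::write_tsv(as_tibble(blst), file.path(cfg$out_dir, "bls_ranking.tsv"),
                     progress = FALSE)
    sp <- evolved$species[1:2]
    corr <- tibble(region_a = sub_ids, region_b = sub_ids)
    pairs <- build_ortholog_pairs(corr, evolved$sequences[[sp[1]]],
                                  evolved$sequences[[sp[2]]], model,
                                  class_id = "MEL")
    readr::write_tsv(dplyr::select(pairs, -"alignment"),
                     file.path(cfg$out_dir, "ortholog_pairs.tsv"),
                     progress = FALSE)
    runtimes$cross_species <- proc.time()[3] - t0
    report <- c(report,
                paste0("* top conserved motif by normalized BLS: ",
                       blst$motif[1]),
                paste0("* ortholog pairs passing identity filter: ",
                       nrow(pairs), " of ", nrow(corr)))
  }

  report_path <- file.path(cfg$out_dir, "report.md")
  writeLines(report, report_path)
  files <- setdiff(list.files(cfg$out_dir, recursive = TRUE,
                              full.names = TRUE),
                   file.path(cfg$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("enhancerkit")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = digest_file_list(NULL, serialize_config = cfg),
    runtimes = runtimes,
    total_runtime = proc.time()[3] - t_all,
    files = tibble(path = sub(paste0("^", cfg$out_dir, "/?"), "", files),
                   md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(manifest, class = "run_manifest")
}

digest_file_list <- function(files, serialize_config = NULL) {
  if (!is.null(serialize_config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(unclass(serialize_config),
                                auto_unbox = TRUE), tmp)
    return(unname(tools::md5sum(tmp)))
  }
  unname(tools::md5sum(files))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed ", x$seed, ", ", nrow(x$files), " output files, ",
      round(x$total_runtime, 1), "s total\n", sep = "")
  invisible(x)
}
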