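#' Default pipeline configuration
#'
#' All tunables of the end-to-end run: simulation presets and sizes, the
#' classifier thresholds, the DE significance filter (adjusted p < 0.05
#' and |log2 fold change| > 1 by convention), phenotype cohort sizes, and
#' annotation-only metadata (e.g. the drug concentration of the treatment
#' arm). The configuration round-trips losslessly through YAML; unknown
#' keys are rejected at validation.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    presets = c("huh6_invitro", "cam_pure", "tumor_on_cam"),
    n_reads = 20000L,
    reference = list(n_homolog_pairs = 1000L, n_unique_per_species = 150L,
                     divergence = 0.20),
    classifier = list(k = 15L, min_identity = 0.95,
                      min_read_coverage = 0.90, band = 3L),
    de = list(alpha_level = 0.05, lfc_cutoff = 1),
    summaries = list(n_top = 1000L),
    phenotype = list(n_control = 35L, n_treated = 36L),
    annotation = list(cisplatin_um = 15)
  )
}

#' Validate a pipeline configuration
#'
#' Checks the key structure against [default_config()]; unknown keys raise
#' a `xenosplit_config_error`.
#'
#' @param config nested list.
#' @return the config, with defaults filled in, invisibly.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check <- function(cfg, template, path = "") {
    extra <- setdiff(names(cfg), names(template))
    if (length(extra)) {
      abort(sprintf("unknown config key(s): %s",
                    paste0(path, extra, collapse = ", ")),
            class = "xenosplit_config_error")
    }
    for (nm in names(cfg)) {
      if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
        check(cfg[[nm]], template[[nm]], paste0(path, nm, "$"))
      }
    }
  }
  check(config, ref)
  merged <- modifyList(ref, config)
  invisible(merged)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config nested list (validated before writing).
#' @name config_io
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

stage_seed <- function(seed, stage) {
  offsets <- c(`simulate-refs` = 11L, `simulate-reads` = 23L,
               classify = 37L, count = 41L, de = 53L,
               summarize = 67L, phenotype = 79L)
  (as.integer(seed) %% 100000L) * 1000L + offsets[[stage]]
}

PIPELINE_STAGES <- c("simulate-refs", "simulate-reads", "classify", "count",
                     "de", "summarize", "phenotype")

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind named subcommands: `simulate-refs`,
#' `simulate-reads`, `classify`, `count`, `de`, `summarize`, `phenotype`,
#' or `all`. Each stage writes its artifacts under `out_dir/<stage>/` and
#' records inputs, seeds and file checksums in `out_dir/manifest.json`; a
#' run is reproducible from its manifest. Downstream stages require their
#' upstream artifacts and raise a `xenosplit_missing_artifact` error when
#' absent; partial outputs of a failing stage are removed. One top-level
#' seed fans out to fixed per-stage substreams, so stages are individually
#' reproducible.
#'
#' @param out_dir output directory.
#' @param config configuration list (see [default_config()]).
#' @param stages character vector of stage names, or `"all"`.
#' @param seed top-level seed (defaults to `config$seed`).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(out_dir, config = default_config(), stages = "all",
                         seed = NULL) {
  config <- validate_config(config)
  seed <- as.integer(seed %ifnull% config$seed)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
          class = "xenosplit_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(package_version = as.character(utils::packageVersion("xenosplit")),
         seed = seed, config = config, stages = list())
  }

  need <- function(path, what) {
    if (!file.exists(path)) {
      abort(sprintf("missing upstream artifact for '%s': %s", what, path),
            class = "xenosplit_missing_artifact")
    }
    path
  }
  run_stage <- function(stage, fn) {
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    t0 <- Sys.time()
    withCallingHandlers(
      tryCatch(fn(sdir), error = function(e) {
        unlink(sdir, recursive = TRUE)
        stop(e)
      }),
      message = function(m) invokeRestart("muffleMessage"))
    files <- list.files(sdir, recursive = TRUE, full.names = TRUE)
    manifest$stages[[stage]] <<- list(
      seed = stage_seed(seed, stage),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
      checksums = as.list(setNames(unname(tools::md5sum(files)),
                                   basename(files))))
  }

  ref_path <- file.path(out_dir, "simulate-refs", "reference.rds")

  if ("simulate-refs" %in% stages) {
    run_stage("simulate-refs", function(sdir) {
      ref <- do.call(simulate_reference_pair,
                     c(config$reference,
                       list(seed = stage_seed(seed, "simulate-refs"))))
      write_reference(ref, sdir)
      saveRDS(ref, file.path(sdir, "reference.rds"))
    })
  }
  if ("simulate-reads" %in% stages) {
    run_stage("simulate-reads", function(sdir) {
      ref <- readRDS(need(ref_path, "simulate-reads"))
      s <- stage_seed(seed, "simulate-reads")
      for (i in seq_along(config$presets)) {
        p <- config$presets[i]
        sim <- simulate_reads(ref, p, n_reads = config$n_reads,
                              seed = s + i)
        write_reads_fastq(sim, file.path(sdir, p))
        readr::write_tsv(sim$truth, file.path(sdir, paste0(p, "_truth.tsv")))
      }
    })
  }
  if ("classify" %in% stages) {
    run_stage("classify", function(sdir) {
      ref <- readRDS(need(ref_path, "classify"))
      idx <- kmer_index(ref, k = config$classifier$k)
      for (p in config$presets) {
        f1 <- file.path(out_dir, "simulate-reads", paste0(p, ".fastq"))
        fp <- file.path(out_dir, "simulate-reads", paste0(p, "_1.fastq"))
        reads <- if (file.exists(fp)) {
          read_fastq(need(fp, "classify"),
                     file.path(out_dir, "simulate-reads", paste0(p, "_2.fastq")))
        } else {
          read_fastq(need(f1, "classify"))
        }
        cls <- classify_reads(reads, idx,
                              min_identity = config$classifier$min_identity,
                              min_read_coverage = config$classifier$min_read_coverage,
                              band = config$classifier$band)
        write_classification(cls, file.path(sdir, p))
        saveRDS(cls, file.path(sdir, paste0(p, ".rds")))
      }
    })
  }
  if ("count" %in% stages) {
    run_stage("count", function(sdir) {
      ref <- readRDS(need(ref_path, "count"))
      cls <- lapply(config$presets, function(p) {
        readRDS(need(file.path(out_dir, "classify", paste0(p, ".rds")),
                     "count"))
      })
      names(cls) <- config$presets
      meta <- filter(sample_presets, .data$preset %in% config$presets) |>
        select(sample = "preset", "condition")
      counted <- count_reads(cls, ref, metadata = meta)
      write_counts(counted, sdir)
      saveRDS(counted, file.path(sdir, "counted.rds"))
    })
  }
  if ("de" %in% stages) {
    run_stage("de", function(sdir) {
      # classified presets lack replication; the DE stage runs on
      # truth-level simulated counts for both compartments
      ref <- readRDS(need(ref_path, "de"))
      s <- stage_seed(seed, "de")
      for (sp in c("A", "B")) {
        prog <- simulate_expression_program(ref, sp, seed = s + (sp == "B"))
        cm <- simulate_counts(prog, seed = s + 10 + (sp == "B"))
        rc <- run_contrasts(cm, alpha_level = config$de$alpha_level,
                            lfc_cutoff = config$de$lfc_cutoff)
        for (nm in names(rc$results)) {
          write_de_tsv(rc$results[[nm]],
                       file.path(sdir, sprintf("de_%s_%s.tsv", sp, nm)))
        }
        readr::write_tsv(rc$summary,
                         file.path(sdir, sprintf("de_%s_summary.tsv", sp)))
        saveRDS(cm, file.path(sdir, sprintf("counts_%s.rds", sp)))
      }
    })
  }
  if ("summarize" %in% stages) {
    run_stage("summarize", function(sdir) {
      cm <- readRDS(need(file.path(out_dir, "de", "counts_B.rds"),
                         "summarize"))
      v <- vst_transform(cm)
      readr::write_tsv(as_tibble(v, rownames = "gene"),
                       file.path(sdir, "vst.tsv"))
      top <- top_expressed(v, n = min(config$summaries$n_top, nrow(v)))
      pca <- pca_samples(v[top, , drop = FALSE])
      readr::write_tsv(
        mutate(pca$scores,
               var_pc1 = pca$var_explained[1], var_pc2 = pca$var_explained[2]),
        file.path(sdir, "pca.tsv"))
      ho <- hclust_order(v[top, , drop = FALSE], "samples")
      writeLines(ho$order, file.path(sdir, "sample_order.txt"))
    })
  }
  if ("phenotype" %in% stages) {
    run_stage("phenotype", function(sdir) {
      s <- stage_seed(seed, "phenotype")
      sc <- simulate_phenotype_scores(
        n_control = config$phenotype$n_control,
        n_treated = config$phenotype$n_treated, seed = s)
      readr::write_tsv(sc, file.path(sdir, "scores.tsv"))
      cons <- consensus_scores(sc)
      readr::write_tsv(cons, file.path(sdir, "consensus.tsv"))
      tab <- contingency_table(cons, "white_areas")
      readr::write_tsv(as_tibble(tab, rownames = "group"),
                       file.path(sdir, "contingency.tsv"))
      jsonlite::write_json(as.list(phenotype_chisq(tab)),
                           file.path(sdir, "chisq.json"),
                           auto_unbox = TRUE, digits = NA)
      readr::write_tsv(blind_order(unique(sc$tumor_id), seed = s + 1),
                       file.path(sdir, "blind_order.tsv"))
    })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
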