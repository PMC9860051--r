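# configuration-driven orchestration of the pipeline stages

#' Default pipeline configuration
#'
#' One nested list holds every stage's parameters and seeds; a
#' configuration file (YAML) or the `config` argument of [run_pipeline()]
#' overrides individual fields, leaving the rest at their defaults.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "annotate", "mine", "compare"),
    simulate = list(
      genome = list(n_contigs = 1L, n_genes_per_contig = 40L, n_puls = 1L,
                    n_decoys = 1L),
      noise = list(fp_rate = 0, fn_rate = 0, near_threshold_fraction = 0),
      proteome = list(n_proteins = 200L, n_reps = 3L, n_effect = 10L,
                      effect_fold = 8, cv = 0.2, missing_rate = 0),
      arrays = list(n_extracts = 3L, n_probes = 2L, deletion_depth = 1,
                    n_spots = 2L, noise_cv = 0)
    ),
    annotate = list(mode = "confirmed"),
    mine = list(frame = 7L, max_gap = 1L, require_same_strand = TRUE,
                require_gh26 = TRUE),
    proteomics = list(alpha = 0.05, n_perm = 250L,
                      conditions = c("galactomannan", "pectin"),
                      reference = "galactomannan"),
    arrays = list(control = "buffer", treatment = "GH26C")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as YAML and round-trip losslessly through
#' these helpers.
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Validate (and default-complete) a pipeline configuration
#'
#' Fills missing fields from [default_config()], then checks parameter
#' ranges without mutating anything else. An empty configuration validates
#' to the full default configuration.
#'
#' @param config Partial configuration list.
#' @return A list of class `config_validation` with elements `ok`
#'   (logical), `errors` (character vector naming the offending fields) and
#'   `config` (the completed configuration).
#' @export
#' @examples
#' validate_config(list(proteomics = list(alpha = 0.05)))$ok
validate_config <- function(config = list()) {
  cfg <- merge_config(default_config(), config)
  errors <- character(0)
  add <- function(field, msg) errors <<- c(errors, sprintf("%s: %s", field, msg))

  in01 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 0 && x <= 1
  posint <- function(x, min) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == as.integer(x) && x >= min

  if (!posint(cfg$seed, 0)) add("seed", "must be a non-negative integer")
  bad_stage <- setdiff(cfg$stages, c("simulate", "annotate", "mine",
                                     "compare", "proteomics", "arrays"))
  if (length(bad_stage)) add("stages", paste("unknown stage(s):",
                                             paste(bad_stage, collapse = ", ")))
  for (f in c("fp_rate", "fn_rate", "near_threshold_fraction")) {
    if (!in01(cfg$simulate$noise[[f]])) {
      add(paste0("simulate.noise.", f), "must be in [0, 1]")
    }
  }
  if (!posint(cfg$mine$frame, 1)) add("mine.frame", "must be an integer >= 1")
  if (!posint(cfg$mine$max_gap, 0)) add("mine.max_gap", "must be an integer >= 0")
  a <- cfg$proteomics$alpha
  if (!(is.numeric(a) && length(a) == 1L && !is.na(a) && a > 0 && a <= 1)) {
    add("proteomics.alpha", "must be in (0, 1]")
  }
  if (!posint(cfg$proteomics$n_perm, 2)) {
    add("proteomics.n_perm", "must be an integer >= 2")
  }
  if (!in01(cfg$simulate$proteome$missing_rate)) {
    add("simulate.proteome.missing_rate", "must be in [0, 1]")
  }
  if (!in01(cfg$simulate$arrays$deletion_depth)) {
    add("simulate.arrays.deletion_depth", "must be in [0, 1]")
  }

  structure(list(ok = !length(errors), errors = errors, config = cfg),
            class = "config_validation")
}

#' @export
print.config_validation <- function(x, ...) {
  if (x$ok) cat("configuration OK\n")
  else cat("invalid configuration:\n", paste0("  - ", x$errors, "\n"), sep = "")
  invisible(x)
}

#' Run the pipeline end to end
#'
#' Executes the selected stages (simulate, annotate, mine, compare, and/or
#' proteomics, arrays) under one configuration and seed, writes every
#' stage's table to `output_dir`, and finishes with a manifest recording
#' parameters, package version and the MD5 of each output. Two runs with
#' the same configuration and seed produce identical outputs and identical
#' manifests apart from the timestamp.
#'
#' @param config Partial configuration (see [default_config()]).
#' @param output_dir Output directory, created if needed.
#' @return Invisibly, a run report: the completed configuration, the output
#'   file table and key results.
#' @export
run_pipeline <- function(config = list(), output_dir = tempfile("pulrun")) {
  val <- validate_config(config)
  if (!val$ok) {
    stop(paste0("invalid configuration:\n",
                paste0("  - ", val$errors, collapse = "\n")), call. = FALSE)
  }
  cfg <- val$config
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  report <- list(config = cfg)

  stages <- cfg$stages
  truth <- NULL; annotations <- NULL; puls <- NULL

  if ("simulate" %in% stages) {
    gcfg <- cfg$simulate$genome
    truth <- generate_genome(gcfg$n_contigs, gcfg$n_genes_per_contig,
                             gcfg$n_puls, n_decoys = gcfg$n_decoys,
                             seed = cfg$seed)
    ncfg <- cfg$simulate$noise
    hits <- generate_hit_tables(truth, noise_config(
      fp_rate = ncfg$fp_rate, fn_rate = ncfg$fn_rate,
      near_threshold_fraction = ncfg$near_threshold_fraction,
      seed = cfg$seed))
    emit("genes.tsv", function(p) write_gene_table(truth$genes, p))
    emit("domain_hits.domtbl", function(p) write_domain_hits(hits$domain_hits, p))
    emit("search_hits.tsv", function(p) write_search_hits(hits$search_hits, p))
    emit("truth.json", function(p) write_truth_json(
      list(true_labels = as.list(truth$true_labels),
           planted_puls = truth$planted_puls), p))
    report$truth <- truth
    report$hits <- hits
  } else if (any(c("annotate", "mine", "compare") %in% stages)) {
    inp <- cfg$inputs
    if (is.null(inp$gene_table) || is.null(inp$domain_hits)) {
      stop("inputs.gene_table and inputs.domain_hits are required when the simulate stage is disabled",
           call. = FALSE)
    }
    truth <- list(genes = read_gene_table(inp$gene_table))
    hits <- list(domain_hits = read_domain_hits(inp$domain_hits),
                 search_hits = if (!is.null(inp$search_hits)) {
                   read_search_hits(inp$search_hits)
                 } else NULL)
  }

  if ("annotate" %in% stages) {
    annotations <- annotate_genome(truth$genes, hits$domain_hits,
                                   hits$search_hits,
                                   mode = cfg$annotate$mode)
    emit("annotation.tsv", function(p) write_tsv(as.data.frame(annotations), p))
    report$annotations <- annotations
  }

  if ("mine" %in% stages) {
    if (is.null(annotations)) {
      stop("stages: mine requires the annotate stage", call. = FALSE)
    }
    puls <- mine_assembly(truth$genes, annotations,
                          frame = cfg$mine$frame, max_gap = cfg$mine$max_gap,
                          require_same_strand = cfg$mine$require_same_strand,
                          require_gh26 = cfg$mine$require_gh26)
    emit("puls.tsv", function(p) write_tsv(as.data.frame(puls), p))
    emit("puls.json", function(p) jsonlite::write_json(
      lapply(puls, function(x) unclass(x)), p, auto_unbox = TRUE,
      digits = NA, pretty = TRUE))
    report$puls <- puls
  }

  if ("compare" %in% stages) {
    if (is.null(puls)) stop("stages: compare requires the mine stage",
                            call. = FALSE)
    cooc <- cooccurrence(puls)
    inter <- intersection_counts(puls)
    modular <- data.frame(
      pul = seq_along(puls),
      same_modularity = vapply(puls, same_modularity, logical(1)),
      stringsAsFactors = FALSE)
    emit("cooccurrence.tsv", function(p) write_tsv(cooc, p))
    emit("intersections.tsv", function(p) write_tsv(inter, p))
    emit("modularity.tsv", function(p) write_tsv(modular, p))
    report$cooccurrence <- cooc
    report$intersections <- inter
    report$modularity <- modular
  }

  if ("proteomics" %in% stages) {
    pcfg <- cfg$simulate$proteome
    prot <- generate_proteome(
      n_proteins = pcfg$n_proteins,
      conditions = unique(c(cfg$proteomics$reference,
                            cfg$proteomics$conditions, "mannose")),
      n_reps = pcfg$n_reps,
      effect_proteins = seq_len(pcfg$n_effect),
      effect_fold = pcfg$effect_fold, cv = pcfg$cv,
      missing_rate = pcfg$missing_rate, seed = cfg$seed)
    rib <- compute_ribaq(prot$intensities)
    kept <- detection_filter(prot$intensities, prot$metadata)
    res <- permutation_fdr(rib[kept, , drop = FALSE], prot$metadata,
                           conditions = cfg$proteomics$conditions,
                           alpha = cfg$proteomics$alpha,
                           n_perm = cfg$proteomics$n_perm, seed = cfg$seed)
    fc <- fold_changes(rib, prot$metadata, cfg$proteomics$reference)
    emit("intensities.tsv", function(p) write_intensity_matrix(
      prot$intensities, prot$metadata, p))
    emit("test_results.tsv", function(p) write_tsv(as.data.frame(res), p))
    emit("fold_changes.tsv", function(p) write_tsv(fc, p))
    report$proteomics <- res
  }

  if ("arrays" %in% stages) {
    acfg <- cfg$simulate$arrays
    targets <- data.frame(extract_id = "extract01", probe_id = "probe01",
                          treatment = cfg$arrays$treatment,
                          stringsAsFactors = FALSE)
    arr <- generate_arrays(acfg$n_extracts, acfg$n_probes,
                           treatments = c(cfg$arrays$control,
                                          cfg$arrays$treatment),
                           deletion_targets = targets,
                           deletion_depth = acfg$deletion_depth,
                           n_spots = acfg$n_spots, noise_cv = acfg$noise_cv,
                           seed = cfg$seed)
    means <- mean_replicates(arr$spots)
    norm <- normalize_dataset(means)
    scores <- epitope_deletion_score(norm, cfg$arrays$treatment,
                                     cfg$arrays$control)
    emit("spots.tsv", function(p) write_spot_table(arr$spots, p))
    emit("array_scores.tsv", function(p) write_tsv(scores, p))
    report$array_scores <- scores
  }

  manifest <- list(
    package = "pulcascade",
    version = as.character(packageVersion("pulcascade")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    config = cfg,
    outputs = lapply(setNames(outputs, basename(outputs)), function(p) {
      list(md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$manifest <- manifest
  report$manifest_path <- manifest_path
  report$outputs <- outputs
  invisible(report)
}
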