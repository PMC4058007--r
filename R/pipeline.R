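# End-to-end orchestration: simulate or load a bundle of inputs, run the
# stages in dependency order (ORFs -> redundancy -> specificity ->
# screens / clustering / enrichment / proteomics), and write the summary
# tables plus a provenance manifest. Identical config + seed give
# byte-identical outputs.

#' Default pipeline run configuration
#'
#' All stage parameters with their documented defaults: 90 nt minimum
#' ORF, 0.75 M-start ratio, upper 2.5% ratio quantile, exclusive rule
#' eCPM > 1, cysteine screen < 200 aa / >= 6 Cys, 30-95% step-5
#' identity/coverage clustering grids, 10,000 resamples at FDR 0.05, and
#' proteomic filters 0.95 probability / 2 unique peptides.
#'
#' @param input_dir directory of input files (as written by
#'   [write_bundle()]), or `NULL` to simulate.
#' @param synthetic a [synthetic_config()] used when `input_dir` is NULL.
#' @param ... overrides for individual parameters.
#' @param seed seed for the stochastic stages (GO resampling; and the
#'   synthetic config's own seed governs simulation).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, synthetic = synthetic_config(),
                       ..., seed = 1L) {
  cfg <- list(
    input_dir = input_dir, synthetic = synthetic,
    min_orf_nt = 90L, mstart_ratio = 0.75,
    quantile = 0.025, min_ecpm = 1,
    screen_max_len = 200L, screen_min_cys = 6L,
    identity_grid = seq(30, 95, by = 5),
    coverage_grid = seq(30, 95, by = 5),
    n_resamples = 10000L, fdr_alpha = 0.05,
    min_prob = 0.95, min_unique = 2L,
    rules_file = system.file("extdata", "toxin_categories.yaml",
                             package = "arachnotox"),
    seed = as.integer(seed))
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg <- utils::modifyList(cfg, dots)
  stopifnot(cfg$min_orf_nt %% 3 == 0, cfg$mstart_ratio > 0,
            cfg$quantile > 0, cfg$quantile < 1, cfg$min_ecpm >= 0,
            cfg$fdr_alpha > 0, cfg$fdr_alpha < 1,
            cfg$min_prob >= 0, cfg$min_prob <= 1, cfg$min_unique >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys mirror [run_config()] arguments; a `synthetic` block
#' is passed to [synthetic_config()].
#'
#' @param path YAML (or JSON) file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  syn <- do.call(synthetic_config, as.list(raw$synthetic %||% list()))
  raw$synthetic <- NULL
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  args <- c(list(input_dir = raw$input_dir, synthetic = syn),
            raw[setdiff(names(raw), "input_dir")], list(seed = seed))
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# load the input bundle either from disk or by simulation
.load_inputs <- function(config) {
  if (!is.null(config$input_dir)) {
    d <- config$input_dir
    need <- file.path(d, c("transcripts.fasta", "counts.tsv"))
    if (!all(file.exists(need))) {
      stop("input stage: missing required input(s): ",
           paste(need[!file.exists(need)], collapse = ", "))
    }
    opt <- function(f) {
      p <- file.path(d, f)
      if (file.exists(p)) read_tsv(p) else NULL
    }
    list(transcripts = read_fasta(file.path(d, "transcripts.fasta")),
         counts = read_tsv(file.path(d, "counts.tsv")),
         annotations = opt("annotations.tsv"), go = opt("go.tsv"),
         signal = opt("signal.tsv"), peptides = opt("peptides.tsv"),
         truth = opt("truth.tsv"), source = normalizePath(d))
  } else {
    b <- generate_bundle(config$synthetic)
    b$source <- "synthetic"
    b
  }
}

#' Run the full discovery pipeline
#'
#' @param config a [run_config()].
#' @param out_dir output directory for tables and the manifest.
#' @param stages character vector of stages to emit; default all. One or
#'   more of `orfs`, `collapse`, `specificity`, `screen`, `cluster`,
#'   `enrich`, `proteome`. Prerequisite computations always run
#'   in-memory; only the requested stages write files.
#' @return invisible list with all in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("orfs", "collapse", "specificity",
                                    "screen", "cluster", "enrich",
                                    "proteome")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("orfs", "collapse", "specificity", "screen", "cluster",
                  "enrich", "proteome")
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- .load_inputs(config)
  emit <- function(stage, file, x) {
    if (stage %in% stages) write_tsv(x, file.path(out_dir, file))
  }

  # --- ORFs / best proteins ------------------------------------------
  hit_frames <- NULL
  if (!is.null(inp$annotations) && "hit_frame" %in% names(inp$annotations)) {
    hit_frames <- stats::setNames(inp$annotations$hit_frame,
                                  inp$annotations$transcript_id)
  }
  preds <- predict_best_proteins(inp$transcripts, hit_frames = hit_frames,
                                 min_len = config$min_orf_nt,
                                 mstart_ratio = config$mstart_ratio)
  proteins <- stats::setNames(preds$aa_seq, preds$transcript_id)
  emit("orfs", "best_proteins.tsv",
       preds[, c("transcript_id", "frame", "rule", "is_mstart",
                 "aa_length")])
  if ("orfs" %in% stages) {
    write_fasta(proteins, file.path(out_dir, "best_proteins.fasta"))
  }

  # --- redundancy collapse -------------------------------------------
  red <- collapse_redundant(proteins)
  proteins_nr <- red$kept
  emit("collapse", "redundancy_clusters.tsv", red$clusters)

  # --- tissue specificity --------------------------------------------
  cnt <- inp$counts
  cm <- as.matrix(cnt[, c("venom", "silk", "ceph")])
  rownames(cm) <- cnt$transcript_id
  ecpm <- compute_ecpm(cm)
  fpkm <- compute_fpkm(cm, cnt$effective_length_nt)
  vst <- classify_vst(ecpm, quantile = config$quantile,
                      min_ecpm = config$min_ecpm)
  vids <- vst_ids(vst)
  emit("specificity", "vst_table.tsv", vst$table)
  if ("specificity" %in% stages) {
    jsonlite::write_json(
      list(fold_cutoff_silk = vst$fold_cutoff_silk,
           fold_cutoff_ceph = vst$fold_cutoff_ceph,
           quantile = vst$quantile, min_ecpm = vst$min_ecpm,
           n_exclusive = sum(vst$table$class == "exclusive"),
           n_ratio_vst = sum(vst$table$class == "ratio_vst")),
      file.path(out_dir, "vst_run.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- toxin screens --------------------------------------------------
  rules <- load_category_rules(config$rules_file)
  ann <- inp$annotations %||%
    data.frame(transcript_id = character(0),
               hit_description = character(0), evalue = numeric(0))
  categories <- tag_categories(ann, vids, rules = rules)
  vst_prot <- proteins_nr[names(proteins_nr) %in% vids]
  cys_ids <- screen_cysteine_rich(vst_prot,
                                  max_len = config$screen_max_len,
                                  min_cys = config$screen_min_cys)
  cleav <- if (!is.null(inp$signal)) {
    stats::setNames(inp$signal$cleavage_pos, inp$signal$protein_id)
  } else NULL
  fw_rows <- lapply(cys_ids, function(id) {
    cp <- if (!is.null(cleav) && id %in% names(cleav)) cleav[[id]] else NA
    fw <- extract_framework(vst_prot[[id]], cleavage_pos = cp)
    data.frame(protein_id = id, n_cys = fw$n_cys,
               spacings = paste(fw$spacings, collapse = ","),
               ick_candidate = fw$ick_candidate, stringsAsFactors = FALSE)
  })
  frameworks <- if (length(fw_rows)) do.call(rbind, fw_rows) else
    data.frame(protein_id = character(0), n_cys = integer(0),
               spacings = character(0), ick_candidate = logical(0))
  fpkm_v <- stats::setNames(fpkm[, "venom"], rownames(fpkm))[vids]
  cat_summary <- if (length(vids)) {
    summarize_category_expression(fpkm_v, categories)
  } else NULL
  emit("screen", "categories.tsv",
       data.frame(transcript_id = names(categories),
                  category = unname(categories), stringsAsFactors = FALSE))
  emit("screen", "cysteine_screen.tsv", frameworks)
  if (!is.null(cat_summary)) {
    emit("screen", "category_summary.tsv", cat_summary)
  }

  # --- family clustering sweep ---------------------------------------
  sweep_res <- NULL
  if (length(vst_prot) >= 2L) {
    sweep_res <- sweep_clusters(vst_prot,
                                identity_grid = config$identity_grid,
                                coverage_grid = config$coverage_grid)
    emit("cluster", "cluster_sweep.tsv", sweep_res$grid)
  }

  # --- GO enrichment --------------------------------------------------
  enrich <- NULL
  if (!is.null(inp$go) && nrow(inp$go)) {
    bg <- rownames(ecpm)[ecpm[, "venom"] > 1]
    lengths <- stats::setNames(cnt$effective_length_nt,
                               cnt$transcript_id)[bg]
    go_bg <- inp$go[inp$go$transcript_id %in% bg, , drop = FALSE]
    if (nrow(go_bg) && length(intersect(vids, bg))) {
      enrich <- go_enrichment(go_bg, intersect(vids, bg), lengths,
                              n_resamples = config$n_resamples,
                              seed = config$seed,
                              alpha = config$fdr_alpha)
      emit("enrich", "go_enrichment.tsv", enrich)
    }
  }

  # --- proteome integration ------------------------------------------
  secretome <- NULL
  evidence <- NULL
  if (!is.null(inp$peptides) && nrow(inp$peptides)) {
    pep <- inp$peptides
    pep_probs <- tapply(pep$peptide_prob, pep$peptide_seq, max)
    placements <- map_peptides(unique(pep$peptide_seq), proteins_nr)
    prot_probs <- tapply(pep$protein_prob, pep$peptide_seq, max)
    # protein probability: max over the probabilities of the peptides
    # placed on it (the peptide table carries its source protein's
    # probability on every row)
    by_prot <- tapply(
      prot_probs[placements$peptide], placements$protein_id,
      function(x) max(x, na.rm = TRUE))
    evidence <- filter_evidence(placements, proteins_nr,
                                peptide_probs = pep_probs,
                                protein_probs = by_prot,
                                min_prob = config$min_prob,
                                min_unique = config$min_unique)
    secretome <- classify_secretome(evidence,
                                    inp$signal %||% data.frame(
                                      protein_id = character(0),
                                      has_signal = logical(0)),
                                    vids)
    emit("proteome", "proteome_evidence.tsv", evidence)
    if ("proteome" %in% stages) {
      jsonlite::write_json(
        list(n_confirmed = secretome$n_confirmed,
             pct_signal = secretome$pct_signal,
             counts = as.data.frame(as.table(secretome$counts))),
        file.path(out_dir, "secretome.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  # --- manifest -------------------------------------------------------
  params <- config[setdiff(names(config), c("synthetic", "input_dir"))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("arachnotox")),
    stages = stages, parameters = params,
    input = if (identical(inp$source, "synthetic")) {
      list(kind = "synthetic",
           config = unclass(config$synthetic))
    } else {
      fls <- list.files(config$input_dir, full.names = TRUE)
      list(kind = "files",
           checksums = as.list(tools::md5sum(fls)))
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(predictions = preds, redundancy = red, vst = vst,
                 categories = categories, frameworks = frameworks,
                 category_summary = cat_summary, sweep = sweep_res,
                 enrichment = enrich, evidence = evidence,
                 secretome = secretome, inputs = inp))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), one per stage
#' (`orfs`, `collapse`, `specificity`, `screen`, `cluster`, `enrich`,
#' `proteome`), and `all`. Flags: `--config <yaml|json>` (run
#' configuration), `--in <dir>` (input bundle), `--out <dir>`,
#' `--seed <int>`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, invisibly.
#' @export
arachnotox_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: arachnotox <simulate|orfs|collapse|specificity|screen|",
    "cluster|enrich|proteome|all> [--config FILE] [--in DIR]",
    "--out DIR [--seed N]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  if (is.null(opts$out)) stop(usage)
  seed <- as.integer(opts$seed %||% 1L)
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else run_config(input_dir = opts[["in"]],
                         synthetic = synthetic_config(seed = seed),
                         seed = seed)
  if (!is.null(opts[["in"]])) cfg$input_dir <- opts[["in"]]

  if (cmd == "simulate") {
    write_bundle(generate_bundle(cfg$synthetic), opts$out)
  } else if (cmd == "all") {
    run_pipeline(cfg, out_dir = opts$out)
  } else if (cmd %in% c("orfs", "collapse", "specificity", "screen",
                        "cluster", "enrich", "proteome")) {
    run_pipeline(cfg, out_dir = opts$out, stages = cmd)
  } else {
    stop("unknown subcommand: ", cmd, "\n", usage)
  }
  invisible(0L)
}
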