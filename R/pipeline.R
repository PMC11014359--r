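#' Load and validate a pipeline run configuration
#'
#' The configuration (YAML file or list) names the inputs and tolerances
#' of a full run: reference FASTA plus amplicon sidecar config, sample
#' sheet, FASTQ pairs, read layout, anchoring tolerances, the observable
#' tail window, the UMI collapse mode, an optional subfamily diagnostic
#' table, the output directory and a seed.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(window = 80L, max_mismatch_rate = 0.05, min_anchor = 10L,
                   max_end_trim = 0L, tolerance = 0L, dedup_mode = "exact",
                   diagnostics = NULL, out_dir = "tailrace_out", seed = NULL,
                   layout = list())
  config <- utils::modifyList(defaults, config)
  needed <- c("references", "amplicon_config", "sample_sheet", "fastq")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0L) {
    abort(sprintf("run config is missing: %s", paste(missing, collapse = ", ")))
  }
  for (p in c(config$references, config$sample_sheet,
              unlist(lapply(config$fastq, function(f) c(f$r1, f$r2))),
              config$diagnostics)) {
    if (!file.exists(p)) abort(sprintf("input path does not exist: %s", p))
  }
  if (config$window < 1L) abort("window must be >= 1")
  config$layout <- do.call(read_layout, config$layout)
  structure(config, class = c("run_config", "list"))
}

stage_counts <- function(stage, fates) {
  tibble(stage = stage, fate = names(fates), reads = as.integer(fates))
}

#' Run the full tail-analysis pipeline
#'
#' Executes parse -> tail calling -> (optional subfamily assignment) ->
#' UMI dedup -> summaries over the configured FASTQ pairs, writes the
#' summary TSVs and a JSON run manifest (configuration echo, package
#' version, input checksums, per-stage read-conservation counts), and
#' returns the intermediate tables. Any stage error aborts with the
#' stage name attached.
#'
#' @param config a `run_config` from [load_run_config()] (or a path /
#'   list coercible to one).
#' @return invisibly, a list with `parsed`, `calls`, `molecules`
#'   (deduplicated calls), `summary`, `conservation` and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", stage, conditionMessage(e)), parent = e)
    })
  }
  refs <- run_stage("references",
                    read_amplicons(config$references, config$amplicon_config))
  sheet <- run_stage("references", read_sample_sheet(config$sample_sheet))
  reads <- run_stage("parse", purrr::map(config$fastq, function(f) {
    read_paired_fastq(f$r1, f$r2)
  }) |> bind_rows())
  if (nrow(reads) == 0L) {
    warn("no reads in input FASTQ; producing empty summaries")
  }
  parsed <- run_stage("parse", parse_read_pairs(reads, sheet, config$layout))
  calls <- run_stage("tailcall", call_tails(
    parsed, refs, window = config$window,
    max_mismatch_rate = config$max_mismatch_rate,
    min_anchor = config$min_anchor, max_end_trim = config$max_end_trim,
    tolerance = config$tolerance,
    adapter = revcomp(config$layout$delimiter)))
  stratum <- "reference"
  if (!is.null(config$diagnostics)) {
    diags <- run_stage("subfamily", read_diagnostics(config$diagnostics, refs))
    calls <- run_stage("subfamily", assign_subfamilies(calls, diags, refs))
    stratum <- "subfamily"
  }
  molecules <- run_stage("dedup", dedup_calls(calls, mode = config$dedup_mode))
  summary <- run_stage("summarize", summarize_tails(molecules, stratum))

  conservation <- bind_rows(
    stage_counts("input", c(pairs = nrow(reads))),
    calls |> count(.data$fate, name = "reads") |>
      mutate(stage = "tailcall") |> select("stage", "fate", "reads"),
    stage_counts("dedup", c(consensus = nrow(molecules)))
  )
  n_called <- sum(conservation$reads[conservation$stage == "tailcall"])
  if (n_called != nrow(reads)) {
    abort("read-conservation check failed: tail-call fates do not sum to input pairs")
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  export_summaries(summary, config$out_dir)
  readr::write_tsv(calls |> select(-"template_facing"),
                   file.path(config$out_dir, "calls.tsv"))
  readr::write_tsv(molecules, file.path(config$out_dir, "molecules.tsv"))
  readr::write_tsv(conservation, file.path(config$out_dir, "conservation.tsv"))
  inputs <- c(config$references, config$sample_sheet,
              unlist(lapply(config$fastq, function(f) c(f$r1, f$r2))))
  manifest <- list(
    package = "tailrace",
    version = as.character(utils::packageVersion("tailrace")),
    seed = config$seed,
    window = config$window,
    dedup_mode = config$dedup_mode,
    stratum = stratum,
    input_md5 = as.list(tools::md5sum(inputs)),
    conservation = conservation
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(parsed = parsed, calls = calls, molecules = molecules,
                 summary = summary, conservation = conservation,
                 manifest_path = manifest_path))
}
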