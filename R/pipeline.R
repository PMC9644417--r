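#' Read a BED interval file
#'
#' BED input is 0-based half-open throughout the package. Lines are
#' validated up front so that a malformed line fails hard with its line
#' number.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `name`
#'   (optional, `NA` when absent).
#' @export
read_bed <- function(path) {
  stop_if(!file.exists(path), "BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) >= 3L &&
      !is.na(suppressWarnings(as.integer(f[2]))) &&
      !is.na(suppressWarnings(as.integer(f[3]))) &&
      as.integer(f[2]) < as.integer(f[3])
    stop_if(!ok, "malformed BED line %d in %s", i, path)
  }
  tibble(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = vapply(fields, function(f) as.integer(f[2]), integer(1)),
    end = vapply(fields, function(f) as.integer(f[3]), integer(1)),
    name = vapply(fields, function(f) if (length(f) >= 4L) f[4] else
      NA_character_, character(1))
  )
}

output_header <- function(config_hash = "none") {
  sprintf("#capig %s config_hash=%s",
          as.character(utils::packageVersion("capig")), config_hash)
}

#' Write translocation calls
#'
#' `write_calls_tsv()` writes the fixed scalar columns (clip sequence
#' list-columns are collapsed to comma-separated strings) behind a
#' versioned header comment; `write_calls_json()` keeps the full evidence
#' and is the format [read_calls_json()] restores losslessly.
#'
#' @param calls Call tibble.
#' @param path Output path.
#' @param config_hash Configuration hash recorded in the header.
#' @export
write_calls_tsv <- function(calls, path, config_hash = "none") {
  flat <- calls |>
    mutate(clip_seqs_A = vapply(.data$clip_seqs_A, paste, character(1),
                                collapse = ","),
           clip_seqs_B = vapply(.data$clip_seqs_B, paste, character(1),
                                collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config_hash), con)
  suppressWarnings(write.table(flat, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_json <- function(calls, path, config_hash = "none") {
  jsonlite::write_json(
    list(header = output_header(config_hash), calls = calls),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calls <- tibble::as_tibble(x$calls)
  if (nrow(calls) == 0L) return(empty_call_tbl())
  fix_list <- function(col) {
    if (is.list(col)) lapply(col, as.character) else as.list(as.character(col))
  }
  calls$clip_seqs_A <- fix_list(calls$clip_seqs_A)
  calls$clip_seqs_B <- fix_list(calls$clip_seqs_B)
  calls
}

run_config_defaults <- function() {
  list(
    sim = unclass(sim_config(
      ref_spec = list(list(chrom = "chr1", length = 50000L),
                      list(chrom = "chr2", length = 50000L)),
      breakpoints = list(list(chromA = "chr1", posA = 25000L,
                              chromB = "chr2", posB = 30000L)),
      tumor_fraction = 0.1, n_fragments = 5000L)),
    clump = unclass(clump_config()),
    filter = unclass(filter_config()),
    probe = unclass(probe_config()),
    cohort = list(n_samples = 6L, seed = 7L)
  )
}

merge_section <- function(base, upd, section, provenance, source) {
  for (k in names(upd)) {
    stop_if(!(k %in% names(base)),
            "unknown config key '%s' in section '%s'", k, section)
    base[[k]] <- upd[[k]]
    provenance[[paste(section, k, sep = ".")]] <- source
  }
  list(cfg = base, provenance = provenance)
}

#' Assemble a run configuration
#'
#' Merges parameter values with precedence flags > YAML config > package
#' defaults, recording each value's source in a provenance map. Unknown
#' keys are rejected.
#'
#' @param yaml_path Optional YAML file with sections `sim`, `clump`,
#'   `filter`, `probe`, `cohort`.
#' @param overrides Optional nested list with the same sections (highest
#'   precedence, e.g. parsed command-line flags).
#' @return A list of config sections with attributes `provenance` (named
#'   character vector) and `hash`.
#' @export
capig_run_config <- function(yaml_path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  provenance <- list()
  for (section in names(cfg)) {
    for (k in names(cfg[[section]])) {
      provenance[[paste(section, k, sep = ".")]] <- "default"
    }
  }
  layers <- list()
  if (!is.null(yaml_path)) {
    stop_if(!file.exists(yaml_path), "config file not found: %s", yaml_path)
    layers <- c(layers, list(list(src = "config", val = yaml::read_yaml(yaml_path))))
  }
  if (length(overrides) > 0L) {
    layers <- c(layers, list(list(src = "flag", val = overrides)))
  }
  for (layer in layers) {
    for (section in names(layer$val)) {
      stop_if(!(section %in% names(cfg)),
              "unknown config section '%s'", section)
      m <- merge_section(cfg[[section]], layer$val[[section]], section,
                         provenance, layer$src)
      cfg[[section]] <- m$cfg
      provenance <- m$provenance
    }
  }
  attr(cfg, "provenance") <- unlist(provenance)
  attr(cfg, "hash") <- rlang::hash(cfg)
  cfg
}

#' Run the end-to-end toy pipeline
#'
#' Orchestrates simulate -> call-sv -> verify -> filter-clones -> lod on
#' seeded synthetic data and writes all artifacts under `out_dir`. Every
#' text artifact carries a header comment with the package version and the
#' configuration hash, so a rerun with the same configuration is
#' byte-identical apart from nothing (no timestamps are written).
#'
#' @param config Configuration from [capig_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the calls, verified calls, candidate
#'   clones, audit and detection matrix; artifact paths in `$artifacts`.
#' @export
run_pipeline <- function(config = capig_run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- attr(config, "hash") %||% "none"
  sim_cfg <- do.call(sim_config, config$sim)
  clump_cfg <- do.call(clump_config, config$clump)
  filt_cfg <- do.call(filter_config, config$filter)

  sim <- simulate_translocation_reads(sim_cfg)
  sam_path <- file.path(out_dir, "reads.sam")
  write_alignments(sim$reads, sim$ref$lengths, sam_path)

  calls <- call_translocations(sim$reads, clump_cfg,
                               ig_loci = sim$ref$ig_loci)
  verified <- verify_batch(calls)
  write_calls_tsv(verified, file.path(out_dir, "calls.tsv"), h)
  write_calls_json(verified, file.path(out_dir, "calls.json"), h)

  cohort <- simulate_clone_cohort(config$cohort$n_samples,
                                  seed = config$cohort$seed)
  tables <- purrr::imap(cohort$tables,
                        function(tb, sid) load_clone_table(tb, sample_id = sid))
  res <- call_candidates(tables, filt_cfg)
  cand_dir <- file.path(out_dir, "candidates")
  dir.create(cand_dir, showWarnings = FALSE)
  for (sid in names(res$candidates)) {
    write.table(res$candidates[[sid]],
                file.path(cand_dir, paste0(sid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(header = output_header(h), audit = res$audit),
                       file.path(out_dir, "audit.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)

  markers <- sim$truth$breakpoints |>
    mutate(marker_id = sprintf("t_%s_%s", .data$chromA, .data$chromB),
           class = "translocation") |>
    select("marker_id", "class", "chromA", "posA", "chromB", "posB")
  dm <- detection_matrix(list(run1 = list(calls = verified, clones = NULL)),
                         markers)
  con <- file(file.path(out_dir, "lod.tsv"), "w")
  writeLines(output_header(h), con)
  suppressWarnings(write.table(dm, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)

  jsonlite::write_json(
    list(header = output_header(h),
         provenance = as.list(attr(config, "provenance"))),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    calls = calls, verified = verified, candidates = res$candidates,
    audit = res$audit, detection = dm,
    artifacts = file.path(out_dir, c("reads.sam", "calls.tsv", "calls.json",
                                     "audit.json", "lod.tsv",
                                     "run_config.json"))))
}
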