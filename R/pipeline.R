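#' Build a full-pipeline run configuration
#'
#' A single serializable configuration drives the whole cascade:
#' preprocessing, ncRNA subtraction, conserved identification with the
#' abundance floor, novel-candidate extraction, conservation scoring and
#' the cross-kingdom screen. The defaults are the catalogue-building
#' profile: 15-nt length floor, 18-nt novel-candidate floor, 10-copy
#' abundance floor, r-value 0.55 and 5 seed matches.
#'
#' @param out_dir directory receiving all outputs (created if absent).
#' @param simulate when `TRUE`, inputs are generated by the simulator from
#'   `sim`; otherwise `reads_fastq` and the reference FASTA paths are
#'   read.
#' @param sim a [simulation_config()] list (used when `simulate = TRUE`).
#' @param reads_fastq,plant_reference_fasta,ncrna_reference_fasta,animal_reference_fasta
#'   input paths for real-data runs.
#' @param species_prefix species code stamped onto assigned names.
#' @param preprocess a [preprocess_params()] list.
#' @param min_tag_length,min_count,novel_min_length annotation thresholds.
#' @param conservation_mode matching mode for [conservation_rate()].
#' @param compare a [compare_params()] list.
#' @return a `seedmir_run_config` list.
#' @export
run_config <- function(out_dir,
                       simulate = TRUE,
                       sim = simulation_config(),
                       reads_fastq = NULL,
                       plant_reference_fasta = NULL,
                       ncrna_reference_fasta = NULL,
                       animal_reference_fasta = NULL,
                       species_prefix = "mol",
                       preprocess = preprocess_params(),
                       min_tag_length = 15L,
                       min_count = 10L,
                       novel_min_length = 18L,
                       conservation_mode = "exact_equal",
                       compare = compare_params()) {
  structure(
    list(out_dir = out_dir, simulate = isTRUE(simulate), sim = sim,
         reads_fastq = reads_fastq,
         plant_reference_fasta = plant_reference_fasta,
         ncrna_reference_fasta = ncrna_reference_fasta,
         animal_reference_fasta = animal_reference_fasta,
         species_prefix = species_prefix, preprocess = preprocess,
         min_tag_length = as.integer(min_tag_length),
         min_count = as.integer(min_count),
         novel_min_length = as.integer(novel_min_length),
         conservation_mode = conservation_mode, compare = compare),
    class = "seedmir_run_config")
}

#' Write or read a run configuration as YAML
#'
#' Serialization is a fixed point: write, read and write again produces
#' byte-identical YAML, so a run can always be re-executed from its
#' recorded configuration.
#'
#' @param config a [run_config()] list.
#' @param path YAML file path.
#' @return `path` (write) or the restored config (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_config(config), path)
  invisible(path)
}

unclass_config <- function(x) {
  x <- unclass(x)
  x$sim <- if (!is.null(x$sim)) unclass(x$sim)
  if (!is.null(x$sim$family_length_classes)) {
    # yaml drops names on atomic vectors; a list serializes as a map
    x$sim$family_length_classes <- as.list(x$sim$family_length_classes)
  }
  x$preprocess <- if (!is.null(x$preprocess)) unclass(x$preprocess)
  x$compare <- if (!is.null(x$compare)) unclass(x$compare)
  x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- drop_nulls(x$sim)
  # yaml reads named maps back as lists; restore the named-vector fields
  if (!is.null(sim$family_length_classes)) {
    sim$family_length_classes <- unlist(sim$family_length_classes)
  }
  do.call(run_config, c(
    drop_nulls(x[setdiff(names(x), c("sim", "preprocess", "compare"))]),
    list(sim = do.call(simulation_config, sim),
         preprocess = do.call(preprocess_params, x$preprocess),
         compare = do.call(compare_params, x$compare))))
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

#' Execute the whole pipeline from one configuration
#'
#' Stages run in catalogue order: preprocessing, ncRNA subtraction,
#' conserved identification with the abundance floor, novel-candidate
#' extraction, conservation scoring against the plant reference and the
#' plant-animal screen. Every report table is written to `out_dir` as TSV
#' (plus candidate FASTA and, for simulated runs, the generated FASTQ,
#' references and truth manifest), and every output is reproducible from
#' the configuration alone: rerunning an identical config gives
#' byte-identical files.
#'
#' @param config a [run_config()] list.
#' @return a `seedmir_run` list (stage counts, tags, annotations, family
#'   summary, length distributions, conservation and comparison tables,
#'   manifest when simulated), invisibly.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  if (config$simulate) {
    refs <- build_references(config$sim)
    lib <- simulate_library(config$sim, refs,
                            fastq = out("simulated.fastq"),
                            manifest_path = out("truth_manifest.tsv"))
    write_reference(refs$plant, out("plant_reference.fasta"))
    write_reference(refs$ncrna, out("ncrna_reference.fasta"))
    write_reference(refs$animal, out("animal_reference.fasta"))
    reads <- lib$reads
    manifest <- lib$manifest
    plant_ref <- refs$plant
    ncrna_ref <- refs$ncrna
    animal_ref <- refs$animal
  } else {
    if (is.null(config$reads_fastq) ||
        is.null(config$plant_reference_fasta) ||
        is.null(config$ncrna_reference_fasta)) {
      seedmir_abort(
        "non-simulated runs need reads_fastq, plant and ncRNA references",
        "config")
    }
    reads <- read_fastq(config$reads_fastq)
    plant_ref <- load_reference(config$plant_reference_fasta)
    ncrna_ref <- load_reference(config$ncrna_reference_fasta,
                                default_class = "other_ncRNA")
    animal_ref <- if (!is.null(config$animal_reference_fasta)) {
      load_reference(config$animal_reference_fasta)
    }
    manifest <- NULL
  }

  pre <- preprocess_reads(reads, config$preprocess)
  ann <- annotate_tags(pre$tags, ncrna_ref, plant_ref,
                       species_prefix = config$species_prefix,
                       min_tag_length = config$min_tag_length,
                       min_count = config$min_count,
                       novel_min_length = config$novel_min_length)
  fam <- family_summary(ann$annotations)
  len_reads <- length_distribution(pre$tags, "by_read")
  len_tags <- length_distribution(pre$tags, "by_tag")
  cons <- conservation_rate(ann$annotations, plant_ref,
                            query_species = config$species_prefix,
                            mode = config$conservation_mode)
  cmp <- if (!is.null(animal_ref) && nrow(ann$annotations) > 0) {
    plant_lib <- ann$annotations |>
      transmute(accession = .data$source_accession,
                species_code = config$species_prefix,
                name = sub("^[A-Za-z]{3,4}-", "", .data$assigned_name),
                family = .data$family, rna_class = "miRNA",
                sequence = .data$sequence, arm = .data$arm)
    compare_libraries(plant_lib, animal_ref, config$compare)
  }

  stage_counts <- bind_rows(
    mutate(pre$stage_counts, phase = "preprocess"),
    mutate(ann$stage_counts, phase = "annotate")) |>
    select("phase", "stage", "entering", "surviving") |>
    mutate(discarded = .data$entering - .data$surviving)

  readr::write_tsv(stage_counts, out("stage_counts.tsv"), progress = FALSE)
  readr::write_tsv(pre$tags, out("tags.tsv"), progress = FALSE)
  readr::write_tsv(ann$annotations, out("annotations.tsv"), progress = FALSE)
  readr::write_tsv(fam, out("family_summary.tsv"), progress = FALSE)
  readr::write_tsv(bind_rows(mutate(as_tibble(len_reads), weighting = "by_read"),
                             mutate(as_tibble(len_tags), weighting = "by_tag")),
                   out("length_distribution.tsv"), progress = FALSE)
  readr::write_tsv(cons, out("conservation.tsv"), progress = FALSE)
  if (!is.null(cmp)) {
    readr::write_tsv(cmp, out("mircompare.tsv"), progress = FALSE)
  }
  write_candidates(ann$candidate, out("candidates.fasta"))
  write_run_config(config, out("run_config.yaml"))

  structure(
    list(out_dir = config$out_dir, config = config,
         stage_counts = stage_counts, tags = pre$tags, bins = ann,
         annotations = ann$annotations, family_summary = fam,
         length_by_read = len_reads, length_by_tag = len_tags,
         conservation = cons, comparison = cmp, manifest = manifest),
    class = "seedmir_run")
}

#' @export
print.seedmir_run <- function(x, ...) {
  cat("seedmir pipeline run\n")
  cat("  output:     ", x$out_dir, "\n")
  cat("  tags:       ", nrow(x$tags), "\n")
  cat("  annotated:  ", nrow(x$annotations), "miRNAs in",
      nrow(x$family_summary), "families\n")
  if (!is.null(x$comparison)) {
    cat("  cross-kingdom passes:", nrow(x$comparison), "\n")
  }
  invisible(x)
}

#' Stage-count cascade of a run
#'
#' One row per pipeline stage with entering, surviving and discarded
#' counts; entering minus discarded equals surviving at every stage.
#'
#' @param run a `seedmir_run` object from [run_all()].
#' @return tibble of stage counts.
#' @export
report_stage_counts <- function(run) {
  run$stage_counts
}
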