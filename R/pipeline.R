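#' Load a genome specification
#'
#' Either the builtin mouse genome (`"mouse"`) or a path to a
#' tab-separated table with columns `chrom`, `length_bp` and optionally
#' `cls`; without `cls`, chromosomes named "X"/"Y" (after
#' normalisation) are taken as sex chromosomes and the rest as
#' autosomes.
#'
#' @param spec `"mouse"` or a file path.
#' @return A `genome_model`.
#' @export
load_genome <- function(spec = "mouse") {
  if (inherits(spec, "genome_model")) return(spec)
  if (identical(spec, "mouse")) return(mouse_genome())
  if (!file.exists(spec)) stop("no such genome file: ", spec, call. = FALSE)
  df <- utils::read.delim(spec, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  stopifnot(all(c("chrom", "length_bp") %in% names(df)))
  chrom <- normalise_chrom(df$chrom)
  cls <- if ("cls" %in% names(df)) df$cls else
    ifelse(chrom == "X", "X", ifelse(chrom == "Y", "Y", "autosome"))
  genome_model(chrom, df$length_bp, cls)
}

#' Assemble and validate a run configuration
#'
#' Collects every tunable of the pipeline into one validated record:
#' the genome spec, meiosis probabilities, noise model, calling
#' threshold, reference mode and cohort sizes, plus the seed that is
#' echoed into every output header.
#'
#' @param n Number of simulated oocytes.
#' @param p_bivalent,p_pssc,p_mii_ndj Meiosis probabilities.
#' @param depth,rho Noise-model parameters.
#' @param delta_rel Calling threshold.
#' @param ref_mode `"sex_matched"` or `"pooled"`.
#' @param n_ref_female,n_ref_male Reference cohort composition.
#' @param genome Genome spec for [load_genome()].
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n = 10, p_bivalent = 0, p_pssc = 0.5, p_mii_ndj = 0,
                       depth = 200000, rho = 0.002, delta_rel = 0.2,
                       ref_mode = c("sex_matched", "pooled"),
                       n_ref_female = 10, n_ref_male = 10,
                       genome = "mouse", seed = 1) {
  ref_mode <- match.arg(ref_mode)
  # constructors validate their own slices of the config
  meiosis_params(p_bivalent, p_pssc, p_mii_ndj)
  noise_model(depth, rho)
  call_thresholds(delta_rel)
  if (is.character(genome) && !identical(genome, "mouse") &&
      !file.exists(genome)) {
    stop("genome file does not exist: ", genome, call. = FALSE)
  }
  structure(list(n = as.integer(n), p_bivalent = p_bivalent, p_pssc = p_pssc,
                 p_mii_ndj = p_mii_ndj, depth = depth, rho = rho,
                 delta_rel = delta_rel, ref_mode = ref_mode,
                 n_ref_female = as.integer(n_ref_female),
                 n_ref_male = as.integer(n_ref_male),
                 genome = if (inherits(genome, "genome_model")) "inline"
                          else genome,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()]; missing keys take the defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Provenance header for every output file: version, seed, config hash.
output_header <- function(seed, config_path = NULL) {
  h <- c(sprintf("# meiocnv %s",
                 as.character(utils::packageVersion("meiocnv"))),
         sprintf("# seed=%d", as.integer(seed)))
  if (!is.null(config_path) && file.exists(config_path)) {
    h <- c(h, sprintf("# config_md5=%s", unname(tools::md5sum(config_path))))
  }
  h
}

#' Simulate a cohort and write its count tables
#'
#' Runs the meiosis simulator, converts each zygote and second polar
#' body into an idxstats count table, simulates the euploid reference
#' cohort, and writes everything under `outdir`: `counts/*.tsv`, a
#' manifest, the chromatid-resolution karyotypes as JSON lines, and the
#' echoed config.
#'
#' @param outdir Output directory (created).
#' @param config A `run_config`.
#' @return Invisibly, a list with the manifest path and the simulated
#'   cohort.
#' @export
pipeline_simulate <- function(outdir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  genome <- load_genome(config$genome)
  params <- meiosis_params(config$p_bivalent, config$p_pssc, config$p_mii_ndj)
  noise <- noise_model(config$depth, config$rho)
  dir.create(file.path(outdir, "counts"), recursive = TRUE,
             showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_run_config(config, cfg_path)
  hdr <- output_header(config$seed, cfg_path)

  cohort <- simulate_cohort(config$n, params, genome, seed = config$seed)
  write_karyotypes(cohort, file.path(outdir, "karyotypes.jsonl"))

  rows <- list()
  for (i in seq_along(cohort$oocytes)) {
    oo <- cohort$oocytes[[i]]
    pair_id <- sprintf("pair%03d", i)
    for (st in c("zygote", "pb2")) {
      prof <- simulate_counts(oo[[st]], noise, genome)
      rel <- file.path("counts", paste0(prof$sample_id, ".tsv"))
      write_idxstats(prof, genome, file.path(outdir, rel), header = hdr)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = prof$sample_id, sex_label = prof$sex_label,
        role = "test", path = rel, stage = st, pair_id = pair_id,
        stringsAsFactors = FALSE)
    }
  }
  refs <- simulate_reference_cohort(config$n_ref_female, config$n_ref_male,
                                    noise, genome)
  for (prof in refs) {
    rel <- file.path("counts", paste0(prof$sample_id, ".tsv"))
    write_idxstats(prof, genome, file.path(outdir, rel), header = hdr)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = prof$sample_id, sex_label = prof$sex_label,
      role = "reference", path = rel, stage = "reference", pair_id = "",
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(outdir, "manifest.tsv"), header = hdr)
  message(sprintf("simulate: wrote %d test and %d reference samples to %s",
                  sum(manifest$role == "test"),
                  sum(manifest$role == "reference"), outdir))
  invisible(list(manifest = file.path(outdir, "manifest.tsv"),
                 cohort = cohort))
}

read_manifest_profiles <- function(outdir, manifest, role = NULL) {
  genome <- load_genome(read_run_config(file.path(outdir,
                                                  "config.yaml"))$genome)
  if (!is.null(role)) manifest <- manifest[manifest$role == role, ]
  profs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_idxstats(file.path(outdir, manifest$path[i]), genome,
                  sample_id = manifest$sample_id[i],
                  sex_label = manifest$sex_label[i])
  })
  stats::setNames(profs, manifest$sample_id)
}

#' Build the reference from a run directory
#'
#' Reads the manifest's reference-role samples and writes
#' `reference.tsv`.
#'
#' @param outdir Run directory produced by [pipeline_simulate()].
#' @param mode Reference mode.
#' @return Invisibly, the reference path.
#' @export
pipeline_build_ref <- function(outdir, mode = c("sex_matched", "pooled")) {
  mode <- match.arg(mode)
  manifest <- read_manifest(file.path(outdir, "manifest.tsv"))
  profs <- read_manifest_profiles(outdir, manifest, role = "reference")
  if (length(profs) == 0) {
    stop("manifest lists no reference samples", call. = FALSE)
  }
  ref <- build_reference(profs, mode)
  cfg <- read_run_config(file.path(outdir, "config.yaml"))
  path <- file.path(outdir, "reference.tsv")
  write_reference(ref, path,
                  header = output_header(cfg$seed,
                                         file.path(outdir, "config.yaml")))
  message(sprintf("build-ref: %s reference from %d female + %d male samples",
                  mode, ref$n_female, ref$n_male))
  invisible(path)
}

#' Call aneuploidies for every test sample of a run
#'
#' Infers sex (sex-matched mode), predicts copy numbers and calls
#' gains/losses; writes `calls.tsv`.
#'
#' @param outdir Run directory with `reference.tsv` present.
#' @param delta_rel Optional override of the configured threshold.
#' @return Invisibly, the calls path.
#' @export
pipeline_call <- function(outdir, delta_rel = NULL) {
  cfg <- read_run_config(file.path(outdir, "config.yaml"))
  ref <- read_reference(file.path(outdir, "reference.tsv"))
  thr <- call_thresholds(delta_rel %||% cfg$delta_rel)
  manifest <- read_manifest(file.path(outdir, "manifest.tsv"))
  profs <- read_manifest_profiles(outdir, manifest, role = "test")
  cnps <- list(); sets <- list()
  for (id in names(profs)) {
    sex <- if (ref$mode == "sex_matched") infer_sex(profs[[id]], ref)
           else manifest$sex_label[manifest$sample_id == id]
    if (identical(sex, "unknown")) {
      stop("sample '", id, "' has unknown sex and the pooled reference ",
           "cannot infer it", call. = FALSE)
    }
    cnps[[id]] <- predict_copy_number(profs[[id]], ref, sex)
    sets[[id]] <- call_aneuploidy(cnps[[id]], thr)
  }
  path <- file.path(outdir, "calls.tsv")
  write_calls(cnps, sets, path,
              header = output_header(cfg$seed,
                                     file.path(outdir, "config.yaml")))
  message(sprintf("call: %d samples at delta_rel=%g", length(sets),
                  thr$delta_rel))
  invisible(path)
}

#' Pair zygotes with polar bodies and summarise reciprocity
#'
#' Joins calls with the manifest's pair structure, writes per-pair
#' relation tables (`pairs.tsv`), the heatmap-ready deviation matrix
#' (`matrix.tsv`) and a cohort summary (`summary.json`).
#'
#' @param outdir Run directory with `calls.tsv` present.
#' @return Invisibly, a list with the `cohort_summary` and the pair
#'   reports.
#' @export
pipeline_pair_report <- function(outdir) {
  cfg <- read_run_config(file.path(outdir, "config.yaml"))
  calls_path <- file.path(outdir, "calls.tsv")
  if (!file.exists(calls_path)) {
    stop("no calls.tsv in ", outdir, " (run the call step first)",
         call. = FALSE)
  }
  calls <- read_calls(calls_path)
  manifest <- read_manifest(file.path(outdir, "manifest.tsv"))
  test <- manifest[manifest$role == "test" & nzchar(manifest$pair_id), ]
  pair_ids <- unique(test$pair_id)
  pairs <- lapply(pair_ids, function(pid) {
    zid <- test$sample_id[test$pair_id == pid & test$stage == "zygote"]
    bid <- test$sample_id[test$pair_id == pid & test$stage == "pb2"]
    if (length(zid) != 1 || length(bid) != 1) {
      stop("pair '", pid, "' lacks a zygote/pb2 sample in the manifest",
           call. = FALSE)
    }
    reciprocity(calls[[zid]], calls[[bid]], pair_id = pid)
  })
  summ <- cohort_summary(pairs, calls)
  hdr <- output_header(cfg$seed, file.path(outdir, "config.yaml"))
  write_pair_reports(pairs, file.path(outdir, "pairs.tsv"), header = hdr)
  write_cohort_matrix(summ, file.path(outdir, "matrix.tsv"), header = hdr)
  s <- summ$summary
  s$per_chrom_aneuploidy_freq <- as.list(s$per_chrom_aneuploidy_freq)
  s$seed <- cfg$seed
  jsonlite::write_json(s, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("pair-report: %d pairs, mean reciprocity %s",
                  s$n_pairs,
                  if (is.na(s$mean_reciprocity)) "undefined"
                  else sprintf("%.3f", s$mean_reciprocity)))
  invisible(list(summary = summ, pairs = pairs))
}

#' End-to-end synthetic demonstration run
#'
#' Simulates a crossover-null cohort and a control cohort, builds the
#' reference, calls aneuploidies and writes pair reports for both,
#' under `outdir/mutant` and `outdir/control`. With a fixed seed the
#' whole output tree is byte-identical across reruns.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param n_mutant,n_control Cohort sizes.
#' @return Invisibly, a list of the two cohort summaries.
#' @export
pipeline_demo <- function(outdir, seed = 1, n_mutant = 10, n_control = 9) {
  run_one <- function(sub, cfg) {
    dir <- file.path(outdir, sub)
    pipeline_simulate(dir, cfg)
    pipeline_build_ref(dir)
    pipeline_call(dir)
    pipeline_pair_report(dir)
  }
  mut <- run_one("mutant",
                 run_config(n = n_mutant, p_bivalent = 0, p_pssc = 0.5,
                            seed = seed))
  ctl <- run_one("control",
                 run_config(n = n_control, p_bivalent = 1, p_pssc = 0,
                            seed = seed + 1))
  invisible(list(mutant = mut$summary, control = ctl$summary))
}
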