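#' Normalise chromosome names
#'
#' Maps common aliases onto the package's canonical names ("1".."19",
#' "X", "Y" for mouse): strips a leading "chr"/"Chr"/"CHR" prefix and
#' applies any user-supplied alias map on top.
#'
#' @param x Character vector of chromosome names.
#' @param aliases Optional named character vector, `c(alias = canonical)`.
#' @return Character vector of normalised names.
#' @export
normalise_chrom <- function(x, aliases = NULL) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  if (!is.null(aliases)) {
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

#' Read a samtools-idxstats-style count table
#'
#' Parses a tab-separated table with columns chromosome, length, mapped
#' reads and (optionally) unmapped reads — the dialect produced by
#' `samtools idxstats` and equivalent per-chromosome read counters.
#' Lines starting with `#` and the `*` unplaced-reads row are skipped.
#' Chromosome names are normalised, then checked against the genome:
#' unknown chromosomes are an error in strict mode and dropped with a
#' warning otherwise; recorded lengths must agree with the genome
#' within 1%. Chromosomes absent from the file get count 0.
#'
#' @param path File path.
#' @param genome A `genome_model`.
#' @param sample_id Sample label; default the file name without
#'   extension.
#' @param sex_label `"male"`, `"female"` or `"unknown"`.
#' @param strict Reject unknown chromosomes (default) instead of
#'   dropping them.
#' @param aliases Optional alias map passed to [normalise_chrom()].
#' @return A `count_profile`.
#' @export
read_idxstats <- function(path, genome, sample_id = NULL,
                          sex_label = "unknown", strict = TRUE,
                          aliases = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  counts <- stats::setNames(integer(nrow(genome)), genome$chrom)
  seen <- character(0)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 3) {
      stop(sprintf("%s line %d: expected >= 3 tab-separated fields",
                   path, lineno[i]), call. = FALSE)
    }
    if (f[1] == "*") next
    chrom <- normalise_chrom(f[1], aliases)
    len <- suppressWarnings(as.numeric(f[2]))
    mapped <- suppressWarnings(as.numeric(f[3]))
    if (is.na(len) || is.na(mapped)) {
      stop(sprintf("%s line %d: non-numeric length or count",
                   path, lineno[i]), call. = FALSE)
    }
    if (mapped < 0) {
      stop(sprintf("%s line %d: negative mapped-read count",
                   path, lineno[i]), call. = FALSE)
    }
    if (chrom %in% seen) {
      stop(sprintf("%s line %d: duplicate chromosome '%s'",
                   path, lineno[i], chrom), call. = FALSE)
    }
    if (!chrom %in% genome$chrom) {
      if (strict) {
        stop(sprintf("%s line %d: chromosome '%s' not in genome model",
                     path, lineno[i], chrom), call. = FALSE)
      }
      warning(sprintf("%s line %d: dropping unknown chromosome '%s'",
                      path, lineno[i], chrom), call. = FALSE)
      next
    }
    glen <- genome$length_bp[genome$chrom == chrom]
    if (len > 0 && abs(len - glen) / glen > 0.01) {
      stop(sprintf(
        "%s line %d: length %s for '%s' differs from genome (%s) by > 1%%",
        path, lineno[i], format(len, scientific = FALSE), chrom,
        format(glen, scientific = FALSE)), call. = FALSE)
    }
    seen <- c(seen, chrom)
    counts[chrom] <- as.integer(mapped)
  }
  count_profile(sample_id %||% tools::file_path_sans_ext(basename(path)),
                sex_label, counts)
}

#' Write a count profile in idxstats dialect
#'
#' One row per genome chromosome: chrom, length_bp, mapped, unmapped
#' (always 0). Header `#` comment lines carry provenance; they are
#' skipped by [read_idxstats()], so the round trip is exact.
#'
#' @param profile A `count_profile`.
#' @param genome A `genome_model`.
#' @param path Output path.
#' @param header Optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_idxstats <- function(profile, genome, path, header = NULL) {
  stopifnot(inherits(profile, "count_profile"),
            inherits(genome, "genome_model"))
  counts <- stats::setNames(integer(nrow(genome)), genome$chrom)
  common <- intersect(names(profile$counts), genome$chrom)
  counts[common] <- profile$counts[common]
  body <- sprintf("%s\t%d\t%d\t0", genome$chrom,
                  as.integer(genome$length_bp), counts)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a cohort manifest
#'
#' A tab-separated table listing every sample of a run: `sample_id`,
#' `sex_label`, `role` (`test` or `reference`), `path` to its idxstats
#' file, plus `stage` and `pair_id` so matched zygote/polar-body pairs
#' can be reassembled.
#'
#' @param manifest Data frame with the columns above.
#' @param path File path.
#' @param header Optional `#` comment lines.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   data frame.
#' @export
write_manifest <- function(manifest, path, header = NULL) {
  need <- c("sample_id", "sex_label", "role", "path", "stage", "pair_id")
  stopifnot(all(need %in% names(manifest)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(manifest[, need], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Write simulated karyotypes as JSON lines
#'
#' One JSON object per cell:
#' `{"stage":..., "content":{"1":{"dyads":..,"singles":..},...},
#'   "paternal":{...}, "sample_id":..., "seed":...}`.
#'
#' @param cohort A `meiosis_cohort`.
#' @param path Output path (`.jsonl`).
#' @param stages Which cells of each oocyte to write.
#' @return `path`, invisibly.
#' @export
write_karyotypes <- function(cohort, path,
                             stages = c("egg", "pb1", "zygote", "pb2")) {
  stopifnot(inherits(cohort, "meiosis_cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  for (oo in cohort$oocytes) {
    for (st in stages) {
      k <- oo[[st]]
      content <- lapply(stats::setNames(names(k$dyads), names(k$dyads)),
                        function(ch) list(dyads = unname(k$dyads[[ch]]),
                                          singles = unname(k$singles[[ch]])))
      obj <- list(stage = k$stage, sample_id = k$meta$sample_id,
                  content = content)
      if (!is.null(k$paternal)) obj$paternal <- as.list(k$paternal)
      if (!is.null(cohort$seed)) obj$seed <- cohort$seed
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read karyotypes written by [write_karyotypes()]
#'
#' @param path A `.jsonl` path.
#' @return List of `cell_karyotype` objects.
#' @export
read_karyotypes <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    chroms <- names(obj$content)
    dyads <- vapply(obj$content, function(x) as.integer(x$dyads), integer(1))
    singles <- vapply(obj$content, function(x) as.integer(x$singles),
                      integer(1))
    paternal <- if (!is.null(obj$paternal)) {
      stats::setNames(vapply(obj$paternal, as.integer, integer(1)),
                      names(obj$paternal))
    }
    cell_karyotype(obj$stage,
                   stats::setNames(dyads, chroms),
                   stats::setNames(singles, chroms),
                   paternal = paternal,
                   meta = list(sample_id = obj$sample_id,
                               seed = obj$seed))
  })
}

#' Write / read a copy-number reference as TSV
#'
#' Columns `chrom`, `prop_female`, `prop_male` (or `prop_pooled`);
#' header comments record the mode and per-sex sample counts.
#'
#' @param ref A `reference_profile`.
#' @param path File path.
#' @param header Optional extra `#` comment lines.
#' @return `write_reference`: `path` invisibly; `read_reference`: a
#'   `reference_profile`.
#' @export
write_reference <- function(ref, path, header = NULL) {
  stopifnot(inherits(ref, "reference_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header,
               sprintf("# mode=%s", ref$mode),
               sprintf("# n_female=%d", ref$n_female),
               sprintf("# n_male=%d", ref$n_male)), con)
  if (ref$mode == "sex_matched") {
    df <- data.frame(chrom = ref$chroms,
                     prop_female = unname(ref$female[ref$chroms]),
                     prop_male = unname(ref$male[ref$chroms]))
  } else {
    df <- data.frame(chrom = ref$chroms,
                     prop_pooled = unname(ref$pooled[ref$chroms]))
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    stop("no such reference file: ", path,
         " (run the build-ref step first)", call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get <- function(key) {
    m <- sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
    if (length(m)) m[1] else NA_character_
  }
  mode <- get("mode")
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  ref <- list(mode = mode, chroms = df$chrom,
              n_female = as.integer(get("n_female")),
              n_male = as.integer(get("n_male")))
  if (identical(mode, "sex_matched")) {
    ref$female <- stats::setNames(df$prop_female, df$chrom)
    ref$male <- stats::setNames(df$prop_male, df$chrom)
  } else {
    ref$pooled <- stats::setNames(df$prop_pooled, df$chrom)
  }
  structure(ref, class = "reference_profile")
}

#' Write copy-number calls as TSV
#'
#' One row per sample x chromosome: `sample`, `chrom`, `ratio`,
#' `copy_number`, `call`.
#'
#' @param cn_profiles List of `copy_number_profile`s.
#' @param call_sets List of matching `aneuploidy_calls`.
#' @param path File path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_calls <- function(cn_profiles, call_sets, path, header = NULL) {
  stopifnot(length(cn_profiles) == length(call_sets))
  rows <- do.call(rbind, Map(function(cnp, cs) {
    chroms <- names(cs$calls)
    data.frame(sample = cnp$sample_id, chrom = chroms,
               ratio = unname(cnp$ratio[chroms]),
               copy_number = unname(cnp$copy_number[chroms]),
               call = unname(cs$calls[chroms]), stringsAsFactors = FALSE)
  }, cn_profiles, call_sets))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read calls written by [write_calls()] back into call-set objects
#'
#' @param path TSV path.
#' @param sex_map Optional named vector sample -> sex used for
#'   baselines; samples with an X copy number below 1.5 and a Y entry
#'   are otherwise taken as male.
#' @return Named list of `aneuploidy_calls`.
#' @export
read_calls <- function(path, sex_map = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  out <- lapply(split(df, df$sample), function(d) {
    cn <- stats::setNames(d$copy_number, d$chrom)
    male <- if (!is.null(sex_map) && d$sample[1] %in% names(sex_map)) {
      sex_map[[d$sample[1]]] == "male"
    } else "Y" %in% d$chrom
    base <- stats::setNames(rep(2, nrow(d)), d$chrom)
    if (male) base[d$chrom %in% c("X", "Y")] <- 1
    new_aneuploidy_calls(d$sample[1], stats::setNames(d$call, d$chrom),
                         cn, base)
  })
  out[unique(df$sample)]
}

#' Write pair reciprocity reports as TSV
#'
#' One row per pair x chromosome: `pair`, `chrom`, `zygote_call`,
#' `pb_call`, `relation`.
#'
#' @param pairs List of `pair_reciprocity` reports.
#' @param path File path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_pair_reports <- function(pairs, path, header = NULL) {
  rows <- do.call(rbind, lapply(pairs, function(p) {
    cbind(pair = p$pair_id, p$table)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the cohort deviation matrix as TSV
#'
#' Samples x chromosomes matrix of diploid-equivalent copy-number
#' deviations, ready for heatmap plotting.
#'
#' @param summary A `cohort_summary`.
#' @param path File path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_cohort_matrix <- function(summary, path, header = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  m <- summary$deviation_matrix
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
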