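# Readers/writers for peak tables and reports, the run configuration, and
# the end-to-end pipeline: blank subtraction -> precursor matching ->
# fragment annotation -> cross-system comparison.

#' Default run configuration
#'
#' Tolerances and settings used across the pipeline. Precursor tolerance is
#' +/-2 mDa (the accurate-mass identification window); the fragment channel
#' uses 0.5 Da because fragment lists are nominal-mass; at most 10 fragment
#' ions are considered per match.
#'
#' @param ... named overrides of any default field.
#' @return List of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    parent = "C15H22O5",
    parent_alias = "ART",
    reduced_alias = "DHA",
    rules = default_rule_set(),
    max_steps = 3L,
    adducts = c("M+H", "M+Na", "M+K"),
    tol_precursor_mda = 2,
    tol_fragment_da = 0.5,
    blank_mz_tol_mda = 2,
    blank_rt_tol_min = 0.1,
    rt_tol_min = 0.1,
    max_fragments = 10L,
    max_depth = 4L,
    allow_h2 = TRUE,
    losses = default_loss_registry(),
    scan_range = c(50, 1000)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$tol_precursor_mda > 0, cfg$tol_fragment_da > 0,
            cfg$rt_tol_min > 0, cfg$max_fragments >= 1)
  structure(cfg, class = "run_config")
}

#' Read a peak table from disk
#'
#' Delimited format: tab-separated with header columns `sample_id`, `system`,
#' `energy`, `mz`, `rt_min`, `intensity` (extra columns preserved). MGF
#' format: each `BEGIN IONS`/`END IONS` block contributes its `PEPMASS` as a
#' low-energy precursor peak and its peak lines as high-energy fragments;
#' retention time is taken from `RTINSECONDS` (converted to minutes) when
#' present, else 0.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"delim"` or `"mgf"`.
#' @param sample_id,system defaults used by the MGF reader, which has no
#'   such fields.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, format = c("auto", "delim", "mgf"),
                            sample_id = basename(path), system = "other") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "delim"
  }
  if (format == "mgf") return(read_mgf(path, sample_id, system))
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    warning("empty peak-table file: ", path)
    return(peak_table(data.frame(sample_id = character(0),
                                 system = character(0), energy = character(0),
                                 mz = numeric(0), rt_min = numeric(0),
                                 intensity = numeric(0))))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "system", "energy", "mz", "rt_min", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("peak table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$mz)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$mz))))[1]
    stop(sprintf("non-numeric m/z in %s at data line %d", path, bad),
         call. = FALSE)
  }
  peak_table(df)
}

#' Minimal MGF reader
#'
#' @param path MGF file.
#' @param sample_id,system tags applied to all peaks.
#' @return A [peak_table()]; precursors in the low-energy channel, peak
#'   lines in the high-energy channel.
#' @export
read_mgf <- function(path, sample_id = basename(path), system = "other") {
  lines <- trimws(readLines(path))
  rows <- list()
  in_block <- FALSE
  pepmass <- NA_real_
  rt <- 0
  frags <- list()
  flush <- function() {
    out <- list()
    if (!is.na(pepmass)) {
      out[[1]] <- data.frame(sample_id = sample_id, system = system,
                             energy = "low", mz = pepmass, rt_min = rt,
                             intensity = 1, stringsAsFactors = FALSE)
    }
    if (length(frags)) {
      fm <- do.call(rbind, frags)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, system = system, energy = "high",
        mz = fm[, 1], rt_min = rt, intensity = fm[, 2],
        stringsAsFactors = FALSE)
    }
    out
  }
  for (ln in lines) {
    if (ln == "BEGIN IONS") {
      in_block <- TRUE; pepmass <- NA_real_; rt <- 0; frags <- list()
    } else if (ln == "END IONS") {
      rows <- c(rows, flush())
      in_block <- FALSE
    } else if (in_block && grepl("^PEPMASS=", ln)) {
      pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
    } else if (in_block && grepl("^RTINSECONDS=", ln)) {
      rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
    } else if (in_block && grepl("^[0-9]", ln)) {
      v <- as.numeric(strsplit(ln, "\\s+")[[1]])
      frags[[length(frags) + 1L]] <- c(v[1], if (length(v) > 1) v[2] else 1)
    }
  }
  if (!length(rows)) {
    return(peak_table(data.frame(sample_id = character(0),
                                 system = character(0), energy = character(0),
                                 mz = numeric(0), rt_min = numeric(0),
                                 intensity = numeric(0))))
  }
  peak_table(do.call(rbind, rows))
}

#' Write a peak table (tab-delimited, lossless round-trip)
#'
#' @param x peak table.
#' @param path output path.
#' @export
write_peak_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join per-system match tables into metabolite records
#'
#' Cross-system identity for pipeline output: two matches are the same
#' metabolite when they share a class label and elute within `rt_tol_min`
#' of each other (one-to-one, nearest retention time first). Records get
#' sequential ids `P01, P02, ...` ordered by class then retention time.
#'
#' @param in_vivo,in_vitro match tables from [match_precursors()] (possibly
#'   augmented with annotation columns).
#' @param rt_tol_min retention-time window for the join (default 0.1 min).
#' @return data.frame of records suitable for [compare_systems()].
#' @export
pipeline_records <- function(in_vivo, in_vitro, rt_tol_min = 0.1) {
  tag <- function(df, sys) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(class = df$class, rt_min = df$rt_min, sys = sys,
               stringsAsFactors = FALSE)
  }
  a <- tag(in_vivo, "in_vivo")
  b <- tag(in_vitro, "in_vitro")
  recs <- list()
  if (!is.null(a)) {
    used_b <- rep(FALSE, if (is.null(b)) 0 else nrow(b))
    for (i in seq_len(nrow(a))) {
      j <- NA_integer_
      if (!is.null(b)) {
        cand <- which(!used_b & b$class == a$class[i] &
                        abs(b$rt_min - a$rt_min[i]) <= rt_tol_min)
        if (length(cand)) {
          j <- cand[which.min(abs(b$rt_min[cand] - a$rt_min[i]))]
          used_b[j] <- TRUE
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        class = a$class[i],
        rt_min = if (is.na(j)) a$rt_min[i] else mean(c(a$rt_min[i], b$rt_min[j])),
        in_vivo = TRUE, in_vitro = !is.na(j), stringsAsFactors = FALSE)
    }
    if (!is.null(b)) b <- b[!used_b, , drop = FALSE]
  }
  if (!is.null(b) && nrow(b)) {
    for (i in seq_len(nrow(b))) {
      recs[[length(recs) + 1L]] <- data.frame(
        class = b$class[i], rt_min = b$rt_min[i],
        in_vivo = FALSE, in_vitro = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(id = character(0), class = character(0),
                      rt_min = numeric(0), in_vivo = logical(0),
                      in_vitro = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  out <- out[order(out$class, out$rt_min), , drop = FALSE]
  out <- cbind(id = sprintf("P%02d", seq_len(nrow(out))), out)
  out$id <- as.character(out$id)
  rownames(out) <- NULL
  out
}

#' Run the full identification pipeline
#'
#' For each system: subtract the paired blank, match surviving low-energy
#' peaks to enumerated candidate metabolites, annotate each match with the
#' high-energy fragments co-eluting within the retention-time window, then
#' join the per-system identifications into metabolite records and compare
#' the systems.
#'
#' @param samples named list (`in_vivo`, `in_vitro` — either may be absent)
#'   of peak tables or file paths.
#' @param blanks named list of paired blank peak tables or paths, keyed as
#'   `samples`.
#' @param config a [default_config()].
#' @return List of class `pipeline_result`: `report`
#'   ([compare_systems()] output), `records`, `matches` (per-system match
#'   tables with `coverage`, `n_fragments_explained`, `n_fragments_considered`
#'   columns), `candidates`, `config`.
#' @export
run_pipeline <- function(samples, blanks, config = default_config()) {
  if (!length(samples)) stop("no samples supplied", call. = FALSE)
  stopifnot(inherits(config, "run_config"),
            all(names(samples) %in% c("in_vivo", "in_vitro")),
            all(names(samples) %in% names(blanks)))
  load_tbl <- function(x) if (is.character(x)) read_peak_table(x) else peak_table(x)
  cand <- enumerate_candidates(config$parent, config$rules, config$max_steps,
                               config$parent_alias, config$reduced_alias)
  matches <- list()
  for (sys in names(samples)) {
    sample <- load_tbl(samples[[sys]])
    blank <- load_tbl(blanks[[sys]])
    clean <- subtract_blank(sample, blank, config$blank_mz_tol_mda,
                            config$blank_rt_tol_min)
    m <- match_precursors(clean, cand, config$adducts,
                          config$tol_precursor_mda)
    high <- clean[clean$energy == "high", , drop = FALSE]
    ann <- lapply(seq_len(nrow(m)), function(i) {
      fr <- high[abs(high$rt_min - m$rt_min[i]) <= config$rt_tol_min, ,
                 drop = FALSE]
      annotate_spectrum(m$formula[i],
                        data.frame(mz = fr$mz, intensity = fr$intensity),
                        config$losses, config$max_fragments,
                        config$max_depth, config$allow_h2,
                        config$tol_fragment_da)
    })
    m$coverage <- vapply(ann, function(a) a$coverage, numeric(1))
    m$n_fragments_considered <- vapply(ann, function(a) a$n_considered,
                                       integer(1))
    m$n_fragments_explained <- vapply(ann, function(a) a$n_explained,
                                      integer(1))
    matches[[sys]] <- m
  }
  records <- pipeline_records(matches$in_vivo, matches$in_vitro,
                              config$rt_tol_min)
  structure(list(report = compare_systems(records), records = records,
                 matches = matches, candidates = cand, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Replay the packaged summary-table fixture
#'
#' Runs the cross-system comparison directly on the packaged transcription
#' of the study's metabolite table — the desk-reproducible route to its
#' headline 23 / 32 / 16 in vivo / in vitro / common counts.
#'
#' @inheritParams read_metabolite_fixture
#' @return A `comparison_report`, see [compare_systems()].
#' @examples
#' replay_fixture()$n
#' @export
replay_fixture <- function(path = system.file(
  "extdata", "artemisinin_metabolites.tsv", package = "artmetab")) {
  compare_systems(read_metabolite_fixture(path))
}

#' Write a comparison report as delimited text plus a summary
#'
#' @param report a `comparison_report`.
#' @param path output path for the per-class table; the human-readable
#'   summary goes to `<path>.summary.txt`.
#' @export
write_comparison_report <- function(report, path) {
  cls <- report$class_counts
  classes <- sort(unique(unlist(lapply(cls, names))))
  tab <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (set in names(cls)) {
    tab[[set]] <- vapply(classes, function(cl) {
      v <- cls[[set]]
      if (cl %in% names(v)) v[[cl]] else 0L
    }, integer(1))
  }
  tab$rt_min <- report$rt_windows[tab$class, "rt_min"]
  tab$rt_max <- report$rt_windows[tab$class, "rt_max"]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary_path <- paste0(path, ".summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("in vivo: %d", report$n[["in_vivo"]]),
    sprintf("in vitro: %d", report$n[["in_vitro"]]),
    sprintf("common: %d", report$n[["common"]]),
    paste("common ids:", paste(report$common, collapse = ", "))
  ), con)
  invisible(path)
}
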