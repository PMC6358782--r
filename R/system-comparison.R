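# Cross-system comparison of metabolite panels (in vivo vs in vitro) and
# consistency auditing of the packaged summary-table fixture.

#' Read the packaged artemisinin metabolite summary table
#'
#' A machine-readable transcription of the source study's summary of the 39
#' artemisinin metabolites detected in mouse plasma (in vivo) and in
#' *Cunninghamella elegans* fermentation broth (in vitro): component class,
#' formula + adduct as printed, retention time, per-system observed m/z and
#' mass error (mDa), and the nominal-mass fragment list. Printed values are
#' stored verbatim, including rows known to be internally inconsistent;
#' use [validate_fixture()] to audit them.
#'
#' @param path fixture path; defaults to the packaged file.
#' @return data.frame of metabolite records: `id`, `class`, `formula_ion`
#'   (verbatim), `formula` (Hill string), `ion`, `rt_min`, `mz_in_vivo`,
#'   `err_in_vivo`, `mz_in_vitro`, `err_in_vitro`, `in_vivo`, `in_vitro`
#'   (presence flags), `fragments` (list column of numeric m/z).
#' @export
read_metabolite_fixture <- function(path = system.file(
  "extdata", "artemisinin_metabolites.tsv", package = "artmetab")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  num <- function(x) {
    x <- trimws(x)
    x[x %in% c("-", "")] <- NA_character_  # both blank conventions
    as.numeric(x)
  }
  split_ion <- lapply(raw$formula_ion, parse_ion_notation)
  out <- data.frame(
    id = raw$id,
    class = raw$component,
    formula_ion = raw$formula_ion,
    formula = vapply(split_ion, function(s) write_formula(s$formula),
                     character(1)),
    ion = vapply(split_ion, `[[`, character(1), "ion"),
    rt_min = num(raw$rt_min),
    mz_in_vivo = num(raw$mz_in_vivo),
    err_in_vivo = num(raw$err_in_vivo),
    mz_in_vitro = num(raw$mz_in_vitro),
    err_in_vitro = num(raw$err_in_vitro),
    stringsAsFactors = FALSE
  )
  out$in_vivo <- !is.na(out$mz_in_vivo)
  out$in_vitro <- !is.na(out$mz_in_vitro)
  out$fragments <- lapply(strsplit(trimws(raw$fragments), "\\s+"), as.numeric)
  out
}

#' Read the packaged reference-compound table
#'
#' The three reference substances (artemisinin, deoxyartemisinin,
#' dihydroartemisinin) with their printed positive-mode adduct ions and
#' high-energy fragment lists.
#'
#' @param path fixture path; defaults to the packaged file.
#' @return data.frame with `alias`, `formula`, observed `mz_mh`, `mz_mna`,
#'   `mz_mk`, `fragments` (list column), `note`.
#' @export
read_reference_compounds <- function(path = system.file(
  "extdata", "reference_compounds.tsv", package = "artmetab")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$fragments <- lapply(strsplit(trimws(df$fragments), "\\s+"), as.numeric)
  df
}

.check_records <- function(records) {
  need <- c("id", "class", "rt_min", "in_vivo", "in_vitro")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("metabolite records lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup)) {
    stop("duplicate metabolite id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  records
}

#' Compare metabolite sets across the in vivo and in vitro systems
#'
#' Set membership is determined by presence of the per-system observation;
#' the common set is the exact intersection. Output ordering is by
#' metabolite id, so the report is invariant to record order.
#'
#' @param records metabolite records (see [read_metabolite_fixture()] or
#'   [pipeline_records()]); ids must be unique.
#' @return List of class `comparison_report`: id vectors `in_vivo`,
#'   `in_vitro`, `common`, `in_vivo_only`, `in_vitro_only`; `n` (named counts);
#'   `class_counts` (per-set class tallies); `rt_windows` (per-class Rt range
#'   over all records).
#' @examples
#' compare_systems(read_metabolite_fixture())
#' @export
compare_systems <- function(records) {
  records <- .check_records(records)
  records <- records[order(records$id), , drop = FALSE]
  in_vivo <- records$id[records$in_vivo]
  in_vitro <- records$id[records$in_vitro]
  common <- intersect(in_vivo, in_vitro)
  sets <- c("all", "in_vivo", "in_vitro", "common", "in_vivo_only",
            "in_vitro_only")
  cls <- lapply(sets, function(s) class_counts(records, s))
  names(cls) <- sets
  classes <- sort(unique(records$class))
  rt <- t(vapply(classes, function(cl) rt_range(records, cl), numeric(2)))
  colnames(rt) <- c("rt_min", "rt_max")
  structure(list(
    in_vivo = in_vivo, in_vitro = in_vitro, common = common,
    in_vivo_only = setdiff(in_vivo, common),
    in_vitro_only = setdiff(in_vitro, common),
    n = c(in_vivo = length(in_vivo), in_vitro = length(in_vitro),
          common = length(common)),
    class_counts = cls,
    rt_windows = as.data.frame(rt)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> in vivo %d | in vitro %d | common %d\n",
              x$n[["in_vivo"]], x$n[["in_vitro"]], x$n[["common"]]))
  cat("common set:", paste(x$common, collapse = ", "), "\n")
  cat("per-class counts (all records):\n")
  print(x$class_counts$all)
  cat("per-class retention-time windows (min):\n")
  print(x$rt_windows)
  invisible(x)
}

#' Per-class metabolite tallies
#'
#' @param records metabolite records.
#' @param set which subset to tally: `"all"`, `"in_vivo"`, `"in_vitro"`,
#'   `"common"`, `"in_vivo_only"` or `"in_vitro_only"`.
#' @return Named integer vector, class -> count; sums to the set size.
#' @export
class_counts <- function(records, set = "all") {
  records <- .check_records(records)
  sel <- switch(set,
    all = rep(TRUE, nrow(records)),
    in_vivo = records$in_vivo,
    in_vitro = records$in_vitro,
    common = records$in_vivo & records$in_vitro,
    in_vivo_only = records$in_vivo & !records$in_vitro,
    in_vitro_only = records$in_vitro & !records$in_vivo,
    stop("unknown set selector: ", set, call. = FALSE)
  )
  tab <- table(records$class[sel])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Retention-time window of a metabolite class
#'
#' @param records metabolite records.
#' @param class component class label (e.g. `"ART + O"`).
#' @return Numeric vector `c(min, max)` of retention times (min).
#' @export
rt_range <- function(records, class) {
  rt <- records$rt_min[records$class == class]
  if (!length(rt)) stop("no records for class '", class, "'", call. = FALSE)
  c(min(rt), max(rt))
}

#' Audit fixture rows against recomputed mass errors
#'
#' For each per-system observation, recomputes the theoretical m/z from the
#' printed formula + adduct and the mass error from the printed observed
#' m/z, and grades the absolute difference between the printed and the
#' recomputed error: `pass` (<= 0.05 mDa), `warn` (<= 0.3 mDa), `fail`
#' otherwise. Findings are reported, never repaired — several printed rows
#' are known typos (e.g. an observed m/z inconsistent with the printed
#' formula) and stay in the fixture verbatim.
#'
#' @param records metabolite records from [read_metabolite_fixture()].
#' @param masses element mass table.
#' @return data.frame of findings: `id`, `system`, `class`, `theoretical_mz`,
#'   `observed_mz`, `printed_err`, `recomputed_err` (unrounded mDa), `delta`
#'   (|printed - recomputed|), `grade`.
#' @export
validate_fixture <- function(records, masses = element_masses()) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    theo <- ion_mz(records$formula[i], records$ion[i], masses = masses)
    for (sys in c("in_vivo", "in_vitro")) {
      obs <- records[[paste0("mz_", sys)]][i]
      printed <- records[[paste0("err_", sys)]][i]
      if (is.na(obs)) next
      rec <- mass_error_mda(obs, theo)
      delta <- abs(printed - rec)
      rows[[length(rows) + 1L]] <- data.frame(
        id = records$id[i], system = sys, class = records$class[i],
        theoretical_mz = theo, observed_mz = obs, printed_err = printed,
        recomputed_err = rec, delta = delta,
        grade = if (delta <= 0.05) "pass" else if (delta <= 0.3) "warn"
                else "fail",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
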