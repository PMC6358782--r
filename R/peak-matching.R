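# Blank subtraction and precursor-ion matching against candidate metabolites.

#' Construct / validate a peak table
#'
#' A peak table holds one sample's centroided peaks. Required columns:
#' `sample_id`, `system` (one of `"in_vivo"`, `"in_vitro"`, `"blank"`,
#' `"other"`), `energy` (`"low"` or `"high"`), `mz` (Th), `rt_min` (min),
#' `intensity`. Rows are canonically sorted by (`rt_min`, `mz`). Extra
#' columns are preserved.
#'
#' @param df data.frame of peaks.
#' @param scan_range permitted m/z window (instrument scan range).
#' @return The canonicalised data.frame (class `peak_table`).
#' @export
peak_table <- function(df, scan_range = c(50, 1000)) {
  need <- c("sample_id", "system", "energy", "mz", "rt_min", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$mz)) stop("mz must be numeric", call. = FALSE)
  bad_sys <- setdiff(unique(df$system), c("in_vivo", "in_vitro", "blank", "other"))
  if (length(bad_sys)) {
    stop("unknown system tag(s): ", paste(bad_sys, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df)) {
    stopifnot(all(df$energy %in% c("low", "high")),
              all(df$rt_min >= 0), all(df$intensity >= 0))
    if (any(df$mz < scan_range[1] | df$mz > scan_range[2])) {
      warning("peaks outside the scan range ",
              scan_range[1], "-", scan_range[2], " m/z")
    }
    df <- df[order(df$rt_min, df$mz), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- unique(c("peak_table", class(df)))
  df
}

#' Remove peaks also present in a blank sample
#'
#' Drops every sample peak that has a blank peak within both the m/z and
#' retention-time tolerances, in the same energy channel — the step that
#' isolates drug-derived signals from matrix background. Idempotent, and
#' never removes a peak the blank lacks.
#'
#' @param sample,blank peak tables (see [peak_table()]).
#' @param mz_tol_mda m/z tolerance in mDa (default 2).
#' @param rt_tol_min retention-time tolerance in minutes (default 0.1).
#' @return The surviving sample peaks as a peak table.
#' @export
subtract_blank <- function(sample, blank, mz_tol_mda = 2, rt_tol_min = 0.1) {
  sample <- peak_table(sample)
  blank <- peak_table(blank)
  if (!nrow(sample) || !nrow(blank)) return(sample)
  keep <- vapply(seq_len(nrow(sample)), function(i) {
    same <- blank$energy == sample$energy[i]
    !any(same &
           abs(blank$mz - sample$mz[i]) * 1000 <= mz_tol_mda &
           abs(blank$rt_min - sample$rt_min[i]) <= rt_tol_min)
  }, logical(1))
  out <- sample[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match low-energy precursor peaks to candidate metabolites
#'
#' For every low-energy peak, computes the mass error against each
#' (candidate, adduct) theoretical m/z and keeps pairs within `tol_mda`.
#' Each peak is reduced to a single best match by the deterministic
#' tie-break: smallest |error| (compared at the 0.1 mDa reporting
#' precision), then fewest biotransformation steps, then lexicographically
#' smaller class label. All within-tolerance alternatives are retained in
#' the `alternatives` diagnostics column — isomeric classes (e.g. DHA vs
#' DHA-O + O, both C15H24O5) are genuinely ambiguous by mass alone.
#' Peaks with no match are absent from the output.
#'
#' @param peaks a peak table; only `energy == "low"` rows are considered.
#' @param candidates candidate table from [enumerate_candidates()].
#' @param adducts adduct kinds to try (subset of [default_adducts()] names).
#' @param tol_mda precursor mass tolerance in mDa (default 2).
#' @return data.frame with one row per matched peak: the peak columns plus
#'   `class`, `ion`, `formula`, `theoretical_mz`, `error_mda` (unrounded),
#'   `n_steps`, `n_alternatives`, `alternatives` (`;`-joined
#'   `class[ion]` strings, best match first).
#' @export
match_precursors <- function(peaks, candidates,
                             adducts = c("M+H", "M+Na", "M+K"),
                             tol_mda = 2) {
  stopifnot(tol_mda > 0)
  peaks <- peak_table(peaks)
  peaks <- peaks[peaks$energy == "low", , drop = FALSE]
  empty <- cbind(
    peaks[0, , drop = FALSE],
    data.frame(class = character(0), ion = character(0),
               formula = character(0), theoretical_mz = numeric(0),
               error_mda = numeric(0), n_steps = integer(0),
               n_alternatives = integer(0), alternatives = character(0),
               stringsAsFactors = FALSE)
  )
  if (!nrow(peaks) || is.null(candidates) || !nrow(candidates)) return(empty)

  reg <- default_adducts()
  unknown <- setdiff(adducts, names(reg))
  if (length(unknown)) {
    stop("unsupported adduct(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # theoretical m/z grid: candidates x adducts
  grid <- expand.grid(ci = seq_len(nrow(candidates)), ion = adducts,
                      stringsAsFactors = FALSE)
  grid$theoretical_mz <- candidates$monoisotopic_mass[grid$ci] + reg[grid$ion]
  grid$class <- candidates$class[grid$ci]
  grid$formula <- candidates$formula[grid$ci]
  grid$n_steps <- candidates$n_steps[grid$ci]

  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    err <- mass_error_mda(peaks$mz[i], grid$theoretical_mz)
    hit <- which(abs(err) <= tol_mda)
    if (!length(hit)) return(NULL)
    ord <- hit[order(abs(round_mda(err[hit])), grid$n_steps[hit],
                     grid$class[hit], grid$ion[hit])]
    best <- ord[1]
    alt <- sprintf("%s[%s]", grid$class[ord], grid$ion[ord])
    cbind(
      peaks[i, , drop = FALSE],
      data.frame(class = grid$class[best], ion = grid$ion[best],
                 formula = grid$formula[best],
                 theoretical_mz = grid$theoretical_mz[best],
                 error_mda = err[best], n_steps = grid$n_steps[best],
                 n_alternatives = length(ord) - 1L,
                 alternatives = paste(alt, collapse = ";"),
                 stringsAsFactors = FALSE)
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
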