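# Neutral-loss fragment annotation: explain high-energy fragment ions as
# loss ladders from a precursor ion, with an optional single +/-H2
# rearrangement, and score spectrum coverage.

#' Default neutral-loss registry
#'
#' The losses that generate the fragmentation ladders of artemisinin-type
#' compounds under collision-induced dissociation: water, formic acid,
#' acetic acid, carbon monoxide, and ethylene (the C2H4 unit lost as
#' CHCH3). Masses are computed from the formulas, never typed in.
#'
#' @return data.frame with columns `label`, `formula`, `mass` (Da).
#' @export
default_loss_registry <- function() {
  reg <- data.frame(
    label = c("H2O", "HCOOH", "CH3COOH", "CO", "C2H4"),
    formula = c("H2O", "CH2O2", "C2H4O2", "CO", "C2H4"),
    stringsAsFactors = FALSE
  )
  reg$mass <- vapply(reg$formula, formula_mass, numeric(1))
  reg
}

#' Read a loss registry from a config file
#'
#' Tab-delimited file with columns `label` and `formula`; masses are derived
#' from the formulas.
#'
#' @param path file path.
#' @return Loss registry data.frame as [default_loss_registry()].
#' @export
read_loss_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("label", "formula"), names(df))
  if (length(missing)) {
    stop("loss registry lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$mass <- vapply(df$formula, formula_mass, numeric(1))
  df[, c("label", "formula", "mass")]
}

.H2_MASS <- 2 * 1.007825

# Loss-count multisets of total cardinality `depth` over `n` losses, in
# lexicographic order of registry position (multisets drawing more from
# earlier registry entries come first). Returns a matrix, one row each.
.loss_compositions <- function(n, depth) {
  if (depth == 0L) return(matrix(0L, nrow = 1, ncol = n))
  if (n == 1L) return(matrix(depth, nrow = 1, ncol = 1))
  out <- list()
  for (k in depth:0) {
    rest <- .loss_compositions(n - 1L, depth - k)
    out[[length(out) + 1L]] <- cbind(k, rest)
  }
  do.call(rbind, out)
}

.adjustments <- function(allow_h2) {
  adj <- c(none = 0)
  if (allow_h2) adj <- c(adj, "+H2" = .H2_MASS, "-H2" = -.H2_MASS)
  adj
}

.assignment <- function(fragment_mz, labels, adjustment, theoretical, error) {
  adjustment <- unname(adjustment)
  data.frame(fragment_mz = fragment_mz,
             path = paste(labels, collapse = ";"),
             n_losses = length(labels),
             adjustment = adjustment,
             theoretical_mz = theoretical,
             error_da = error,
             stringsAsFactors = FALSE)
}

#' Explain one fragment ion as a neutral-loss path
#'
#' Searches for a multiset of neutral losses (optionally with a single
#' +/-H2 hydrogen rearrangement) whose cumulative mass accounts for the
#' difference between the precursor and the fragment within `tol`. Returns a
#' minimal-cardinality solution; among equal-cardinality solutions the
#' tie-break prefers no hydrogen adjustment over `+H2` over `-H2`, then the
#' solution drawing most from the earliest registry entries (with the default
#' registry: H2O before HCOOH before CH3COOH before CO before C2H4), ranking
#' the chemically common losses first — this is what assigns a nominal 28 Da
#' loss to CO rather than the isobaric-at-0.5-Da C2H4. Only the cumulative
#' mass is testable from peak lists, so the path is an unordered multiset.
#'
#' @param precursor_mz theoretical precursor m/z (Th).
#' @param fragment_mz observed fragment m/z (Th).
#' @param losses loss registry, see [default_loss_registry()].
#' @param max_depth maximum number of losses in a path (default 4).
#' @param allow_h2 permit one +/-H2 adjustment (default TRUE).
#' @param tol fragment mass tolerance in Da (default 0.5, appropriate for
#'   nominal-mass fragment lists; tighten for accurate-mass data).
#' @return One-row data.frame (`fragment_mz`, `path`, `n_losses`,
#'   `adjustment`, `theoretical_mz`, `error_da`) or `NULL` when no path
#'   exists within `max_depth` — absence of an explanation is a valid result.
#' @examples
#' explain_fragment(283.1540, 265)             # one water loss
#' explain_fragment(283.1540, 205)             # H2O then CH3COOH
#' @export
explain_fragment <- function(precursor_mz, fragment_mz,
                             losses = default_loss_registry(),
                             max_depth = 4L, allow_h2 = TRUE, tol = 0.5) {
  stopifnot(max_depth >= 0, tol > 0,
            fragment_mz <= precursor_mz + tol + .H2_MASS)
  target <- precursor_mz - fragment_mz
  adj <- .adjustments(allow_h2)
  for (depth in 0:max_depth) {
    comps <- .loss_compositions(nrow(losses), depth)
    lost <- as.vector(comps %*% losses$mass)
    for (a in seq_along(adj)) {
      resid <- target - lost + adj[a]
      hit <- which(abs(resid) <= tol)
      if (length(hit)) {
        i <- hit[1]  # compositions are generated in registry-priority order
        labels <- rep(losses$label, comps[i, ])
        theo <- precursor_mz - lost[i] + adj[a]
        return(.assignment(fragment_mz, labels, names(adj)[a], theo,
                           fragment_mz - theo))
      }
    }
  }
  NULL
}

#' Exhaustively enumerate all valid loss explanations
#'
#' Brute-force reference for [explain_fragment()]: every loss multiset (with
#' every permitted hydrogen adjustment) up to `max_depth` whose cumulative
#' mass matches the precursor-fragment difference within `tol`. Intended for
#' testing at small depth.
#'
#' @inheritParams explain_fragment
#' @return data.frame of all solutions (possibly 0 rows), columns as in
#'   [explain_fragment()].
#' @export
explain_fragment_oracle <- function(precursor_mz, fragment_mz,
                                    losses = default_loss_registry(),
                                    max_depth = 4L, allow_h2 = TRUE,
                                    tol = 0.5) {
  stopifnot(max_depth <= 5L)
  target <- precursor_mz - fragment_mz
  adj <- .adjustments(allow_h2)
  sol <- list()
  for (depth in 0:max_depth) {
    comps <- .loss_compositions(nrow(losses), depth)
    lost <- as.vector(comps %*% losses$mass)
    for (a in seq_along(adj)) {
      resid <- target - lost + adj[a]
      for (i in which(abs(resid) <= tol)) {
        labels <- rep(losses$label, comps[i, ])
        theo <- precursor_mz - lost[i] + adj[a]
        sol[[length(sol) + 1L]] <-
          .assignment(fragment_mz, labels, names(adj)[a], theo,
                      fragment_mz - theo)
      }
    }
  }
  if (!length(sol)) {
    return(data.frame(fragment_mz = numeric(0), path = character(0),
                      n_losses = integer(0), adjustment = character(0),
                      theoretical_mz = numeric(0), error_da = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(sol, list(make.row.names = FALSE)))
}

#' Annotate a high-energy fragment spectrum
#'
#' Explains the top-`max_fragments` most intense high-energy fragments of a
#' matched precursor via [explain_fragment()] and scores coverage (explained
#' / considered). Fragments are matched against the protonated-species
#' ladder: the ladder base is the `[M+H]+` theoretical m/z of the candidate
#' formula even when the precursor was detected as a sodium or potassium
#' adduct, since the fragment series continues from the protonated ion while
#' Na+/K+ ions behave as adduct clusters.
#'
#' @param formula candidate neutral formula (string or `chem_formula`).
#' @param fragments numeric vector of fragment m/z, or a data.frame with
#'   columns `mz` and optionally `intensity`.
#' @param losses loss registry.
#' @param max_fragments cap on considered fragments (default 10). Selection
#'   is by decreasing intensity when available, else by decreasing m/z.
#' @param max_depth,allow_h2,tol passed to [explain_fragment()].
#' @return List of class `annotated_spectrum`: `precursor_mz` (the ladder
#'   base), `assignments` (data.frame sorted by fragment m/z descending, with
#'   `explained` flag), `n_considered`, `n_explained`, `coverage` (NA with
#'   `evaluable = FALSE` when no fragments were supplied — distinct from 0).
#' @export
annotate_spectrum <- function(formula, fragments,
                              losses = default_loss_registry(),
                              max_fragments = 10L, max_depth = 4L,
                              allow_h2 = TRUE, tol = 0.5) {
  if (is.numeric(fragments)) {
    fragments <- data.frame(mz = fragments,
                            intensity = rep(NA_real_, length(fragments)))
  }
  stopifnot("mz" %in% names(fragments))
  if (!"intensity" %in% names(fragments)) fragments$intensity <- NA_real_
  precursor_mz <- ion_mz(formula, "M+H")

  if (!nrow(fragments)) {
    return(structure(list(precursor_mz = precursor_mz,
                          assignments = NULL, n_considered = 0L,
                          n_explained = 0L, coverage = NA_real_,
                          evaluable = FALSE),
                     class = "annotated_spectrum"))
  }
  ord <- if (all(is.na(fragments$intensity))) {
    order(-fragments$mz)
  } else {
    order(-fragments$intensity, -fragments$mz)
  }
  fragments <- fragments[utils::head(ord, max_fragments), , drop = FALSE]

  rows <- lapply(fragments$mz, function(fmz) {
    if (fmz > precursor_mz + tol + .H2_MASS) {
      return(.assignment(fmz, character(0), NA_character_, NA_real_, NA_real_))
    }
    hit <- explain_fragment(precursor_mz, fmz, losses, max_depth, allow_h2, tol)
    if (is.null(hit)) {
      .assignment(fmz, character(0), NA_character_, NA_real_, NA_real_)
    } else {
      hit
    }
  })
  asg <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  asg$explained <- !is.na(asg$adjustment)
  asg <- asg[order(-asg$fragment_mz), , drop = FALSE]
  rownames(asg) <- NULL
  structure(list(precursor_mz = precursor_mz,
                 assignments = asg,
                 n_considered = nrow(asg),
                 n_explained = sum(asg$explained),
                 coverage = sum(asg$explained) / nrow(asg),
                 evaluable = TRUE),
            class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat(sprintf("<annotated_spectrum> ladder base m/z %.4f; %d/%d fragments explained (coverage %s)\n",
              x$precursor_mz, x$n_explained, x$n_considered,
              if (isTRUE(x$evaluable)) sprintf("%.2f", x$coverage) else "not evaluable"))
  if (!is.null(x$assignments)) print(x$assignments, ...)
  invisible(x)
}
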