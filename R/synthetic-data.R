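# Ground-truthed synthetic MSE data: paired sample/blank peak tables with
# low-energy precursor ions, high-energy neutral-loss fragments, matrix
# peaks and decoy noise, plus the truth table used to score recovery.

#' Default synthetic truth panel
#'
#' One row per true metabolite, mirroring the structure of the packaged
#' summary table: 39 metabolites with its classes, adducts, retention times
#' and system membership, hence a 23 / 32 / 16 in vivo / in vitro / common
#' Venn by construction.
#'
#' @return data.frame with columns `id`, `class`, `ion`, `rt_min`,
#'   `in_vivo`, `in_vitro`.
#' @export
default_truth_panel <- function() {
  fx <- read_metabolite_fixture()
  fx[, c("id", "class", "ion", "rt_min", "in_vivo", "in_vitro")]
}

#' Specification of a synthetic MSE dataset
#'
#' @param parent parent-drug formula (default artemisinin, C15H22O5).
#' @param metabolites truth panel, see [default_truth_panel()]: columns
#'   `id`, `class`, `ion`, `rt_min`, `in_vivo`, `in_vitro`. Classes must be
#'   enumerable from `parent` under `rules`.
#' @param rules biotransformation rule set.
#' @param sigma_mda Gaussian m/z error scale for precursor ions, in mDa
#'   (default 0.5, typical accurate-mass scatter of a Q-TOF).
#' @param decoy_rate Poisson mean of decoy (noise) peaks per sample
#'   (default 25), placed uniformly over `scan_range`.
#' @param decoy_exclusion_mda decoys are rejection-sampled to lie at least
#'   this far (mDa) from every candidate adduct ion (default 5), so noise
#'   peaks are mass-distinguishable from true signals.
#' @param rt_jitter_min SD of retention-time jitter in minutes (default 0.02).
#' @param n_matrix_peaks matrix background peaks shared between each sample
#'   and its blank (default 30).
#' @param n_fragments fragments emitted per true metabolite (default 6).
#' @param max_losses maximum losses per sampled fragment path (default 3).
#' @param scan_range instrument m/z window (default 50-1000).
#' @param seed integer seed; fixes all randomness of [simulate_dataset()].
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(parent = "C15H22O5",
                           metabolites = default_truth_panel(),
                           rules = default_rule_set(),
                           sigma_mda = 0.5,
                           decoy_rate = 25,
                           decoy_exclusion_mda = 5,
                           rt_jitter_min = 0.02,
                           n_matrix_peaks = 30L,
                           n_fragments = 6L,
                           max_losses = 3L,
                           scan_range = c(50, 1000),
                           seed = 1L) {
  stopifnot(sigma_mda >= 0, decoy_rate >= 0, rt_jitter_min >= 0,
            n_fragments >= 1, all(c("id", "class", "ion", "rt_min",
                                    "in_vivo", "in_vitro")
                                  %in% names(metabolites)))
  structure(list(parent = parent, metabolites = metabolites, rules = rules,
                 sigma_mda = sigma_mda, decoy_rate = decoy_rate,
                 decoy_exclusion_mda = decoy_exclusion_mda,
                 rt_jitter_min = rt_jitter_min,
                 n_matrix_peaks = as.integer(n_matrix_peaks),
                 n_fragments = as.integer(n_fragments),
                 max_losses = as.integer(max_losses),
                 scan_range = scan_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sample a random loss multiset (1..max_losses losses) and return its labels
# and total mass. Paths are drawn with replacement from the registry.
.sample_loss_path <- function(losses, max_losses) {
  k <- sample.int(max_losses, 1L)
  idx <- sort(sample.int(nrow(losses), k, replace = TRUE))
  list(labels = losses$label[idx], mass = sum(losses$mass[idx]))
}

.uniform_excluding <- function(n, range, exclude_mz, exclusion_mda) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(n - length(out), range[1], range[2])
    if (length(exclude_mz)) {
      ok <- vapply(x, function(v) {
        all(abs(v - exclude_mz) * 1000 > exclusion_mda)
      }, logical(1))
      x <- x[ok]
    }
    out <- c(out, x)
  }
  out
}

#' Simulate a paired in vivo / in vitro MSE dataset
#'
#' For every true metabolite present in a system, emits a low-energy
#' precursor peak at its theoretical adduct m/z plus Gaussian error
#' (`sigma_mda`) and `n_fragments` high-energy fragment peaks at sampled
#' neutral-loss masses below the protonated ladder base, at a jittered
#' retention time. Each sample shares its matrix background with a paired
#' blank, and carries Poisson-count decoy peaks absent from the blank.
#' All randomness is fixed by `spec$seed`: the same spec yields identical
#' tables.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `samples` and `blanks` (named lists of peak tables,
#'   one per system) and `truth` (the panel augmented with the generated
#'   formula, theoretical precursor m/z and fragment paths).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  cand <- enumerate_candidates(spec$parent, spec$rules)
  losses <- default_loss_registry()
  reg <- default_adducts()

  truth <- spec$metabolites
  ci <- match(truth$class, cand$class)
  if (anyNA(ci)) {
    stop("metabolite class(es) not derivable from the parent under the rule set: ",
         paste(unique(truth$class[is.na(ci)]), collapse = ", "),
         call. = FALSE)
  }
  truth$formula <- cand$formula[ci]
  truth$precursor_mz <- cand$monoisotopic_mass[ci] + reg[truth$ion]
  truth$ladder_mz <- cand$monoisotopic_mass[ci] + reg[["M+H"]]
  paths <- lapply(seq_len(nrow(truth)), function(i) {
    lapply(seq_len(spec$n_fragments), function(j)
      .sample_loss_path(losses, spec$max_losses))
  })
  truth$fragment_paths <- lapply(paths, function(p)
    vapply(p, function(x) paste(x$labels, collapse = ";"), character(1)))

  exclude <- as.vector(outer(cand$monoisotopic_mass, reg, `+`))
  samples <- list()
  blanks <- list()
  for (sys in c("in_vivo", "in_vitro")) {
    sel <- which(truth[[sys]])
    sid <- paste0(sys, "_sample")
    bid <- paste0(sys, "_blank")

    # matrix background, shared verbatim between sample and blank
    matrix_peaks <- if (spec$n_matrix_peaks > 0) data.frame(
      sample_id = sid, system = sys, energy = "low",
      mz = .uniform_excluding(spec$n_matrix_peaks, spec$scan_range,
                              exclude, spec$decoy_exclusion_mda),
      rt_min = stats::runif(spec$n_matrix_peaks, 0.5, 16),
      intensity = exp(stats::runif(spec$n_matrix_peaks, log(1e3), log(1e6))),
      stringsAsFactors = FALSE
    ) else NULL

    prec <- data.frame(
      sample_id = sid, system = sys, energy = "low",
      mz = truth$precursor_mz[sel] +
        stats::rnorm(length(sel), 0, spec$sigma_mda / 1000),
      rt_min = pmax(0, truth$rt_min[sel] +
                      stats::rnorm(length(sel), 0, spec$rt_jitter_min)),
      intensity = exp(stats::runif(length(sel), log(1e4), log(1e7))),
      stringsAsFactors = FALSE
    )

    frag <- do.call(rbind, lapply(seq_along(sel), function(k) {
      i <- sel[k]
      pm <- paths[[i]]
      data.frame(
        sample_id = sid, system = sys, energy = "high",
        mz = vapply(pm, function(x) truth$ladder_mz[i] - x$mass, numeric(1)) +
          stats::rnorm(length(pm), 0, spec$sigma_mda / 1000),
        rt_min = prec$rt_min[k],
        intensity = exp(stats::runif(length(pm), log(1e3), log(1e6))),
        stringsAsFactors = FALSE
      )
    }))

    n_decoy <- stats::rpois(1, spec$decoy_rate)
    decoy <- if (n_decoy > 0) data.frame(
      sample_id = sid, system = sys, energy = "low",
      mz = .uniform_excluding(n_decoy, spec$scan_range, exclude,
                              spec$decoy_exclusion_mda),
      rt_min = stats::runif(n_decoy, 0.5, 16),
      intensity = exp(stats::runif(n_decoy, log(1e3), log(1e5))),
      stringsAsFactors = FALSE
    ) else NULL

    samples[[sys]] <- peak_table(rbind(matrix_peaks, prec, frag, decoy))
    blank <- if (is.null(matrix_peaks)) {
      data.frame(sample_id = character(0), system = character(0),
                 energy = character(0), mz = numeric(0), rt_min = numeric(0),
                 intensity = numeric(0), stringsAsFactors = FALSE)
    } else {
      transform(matrix_peaks, sample_id = bid, system = "blank")
    }
    blanks[[sys]] <- peak_table(blank)
  }
  list(samples = samples, blanks = blanks, truth = truth)
}

#' Score pipeline recovery against a synthetic truth table
#'
#' Per-system, per-stage recall and precision of a pipeline run on a
#' simulated dataset. A truth metabolite counts as recovered at the
#' precursor stage when some reported match lies within `rt_tol_min` of its
#' retention time and carries the true class among its best match or
#' within-tolerance alternatives (isobaric classes are indistinguishable by
#' mass alone); at the fragment stage it must additionally reach
#' `min_coverage`. Precision is the fraction of reported matches that
#' correspond to a truth metabolite under the same criteria.
#'
#' @param truth truth table from [simulate_dataset()].
#' @param result pipeline result from [run_pipeline()] on the same dataset.
#' @param rt_tol_min retention-time window for truth-report pairing.
#' @param min_coverage fragment-confirmation threshold (default 0.5).
#' @return data.frame with columns `system`, `stage` (`"precursor_match"`,
#'   `"fragment_confirmation"`), `n_truth`, `n_reported`, `recall`,
#'   `precision`.
#' @export
evaluate_recovery <- function(truth, result, rt_tol_min = 0.1,
                              min_coverage = 0.5) {
  out <- list()
  for (sys in c("in_vivo", "in_vitro")) {
    tt <- truth[truth[[sys]], , drop = FALSE]
    rep_tbl <- result$matches[[sys]]
    alt <- if (is.null(rep_tbl)) list()
           else strsplit(rep_tbl$alternatives, ";", fixed = TRUE)
    pair_ok <- function(ti, ri) {
      abs(rep_tbl$rt_min[ri] - tt$rt_min[ti]) <= rt_tol_min &&
        sprintf("%s[%s]", tt$class[ti], tt$ion[ti]) %in% alt[[ri]]
    }
    for (stage in c("precursor_match", "fragment_confirmation")) {
      keep <- if (is.null(rep_tbl) || !nrow(rep_tbl)) integer(0)
              else seq_len(nrow(rep_tbl))
      if (stage == "fragment_confirmation" && length(keep)) {
        keep <- keep[!is.na(rep_tbl$coverage[keep]) &
                       rep_tbl$coverage[keep] >= min_coverage]
      }
      recovered <- vapply(seq_len(nrow(tt)), function(ti)
        any(vapply(keep, function(ri) pair_ok(ti, ri), logical(1))),
        logical(1))
      true_pos <- vapply(keep, function(ri)
        any(vapply(seq_len(nrow(tt)), function(ti) pair_ok(ti, ri),
                   logical(1))), logical(1))
      out[[length(out) + 1L]] <- data.frame(
        system = sys, stage = stage, n_truth = nrow(tt),
        n_reported = length(keep),
        recall = if (nrow(tt)) mean(recovered) else NA_real_,
        precision = if (length(keep)) mean(true_pos) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
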