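# Candidate-metabolite enumeration: compose biotransformation rules
# (hydroxylation, deoxygenation, carbonyl reduction) on a parent drug.

#' A biotransformation rule
#'
#' @param label short rule label, unique within a rule set (e.g. `"+O"`).
#' @param delta signed element-count change, see [apply_formula_delta()].
#' @param max_uses maximum number of applications of this rule in one path.
#' @param max_uses_combined maximum number of applications when the path also
#'   contains any *other* rule; defaults to `max_uses`. This encodes
#'   observations like "dihydroxylation occurs only on the intact parent
#'   skeleton" without forbidding single hydroxylation of modified skeletons.
#' @return A `biotransformation_rule` list.
#' @export
biotransformation_rule <- function(label, delta, max_uses = 1L,
                                   max_uses_combined = max_uses) {
  stopifnot(is.character(label), nzchar(label), length(delta) > 0,
            !is.null(names(delta)), max_uses >= 0,
            max_uses_combined <= max_uses)
  structure(
    list(label = label, delta = delta, max_uses = as.integer(max_uses),
         max_uses_combined = as.integer(max_uses_combined)),
    class = "biotransformation_rule"
  )
}

#' Default phase-I rule set for artemisinin
#'
#' The three formula-level transformations that generate every metabolite
#' class observed for artemisinin: hydroxylation (`+O`, up to twice on the
#' unmodified skeleton, once on a deoxygenated or reduced one), loss of a
#' peroxide oxygen (`-O`, once), and carbonyl/lactone reduction (`+H2`,
#' once).
#'
#' @return Named list of [biotransformation_rule()] objects.
#' @export
default_rule_set <- function() {
  rules <- list(
    biotransformation_rule("+O", c(O = 1), max_uses = 2L,
                           max_uses_combined = 1L),
    biotransformation_rule("-O", c(O = -1), max_uses = 1L),
    biotransformation_rule("+H2", c(H = 2), max_uses = 1L)
  )
  names(rules) <- vapply(rules, `[[`, character(1), "label")
  rules
}

#' Read a rule set from a config file
#'
#' One rule per line in a delimited file with columns `label`, `delta`
#' (formula-style signed terms, e.g. `"O:1"` or `"H:2"`; comma-separated),
#' `max_uses`, `max_uses_combined`.
#'
#' @param path path to a tab-delimited rule file.
#' @return Named list of rules, as [default_rule_set()].
#' @export
read_rule_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "delta", "max_uses", "max_uses_combined")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("rule file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rules <- lapply(seq_len(nrow(df)), function(i) {
    terms <- strsplit(df$delta[i], ",", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(terms), ":", fixed = TRUE)
    delta <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
    names(delta) <- vapply(kv, `[[`, character(1), 1)
    biotransformation_rule(df$label[i], delta, df$max_uses[i],
                           df$max_uses_combined[i])
  })
  names(rules) <- df$label
  rules
}

# All admissible rule-application count vectors (one column per rule).
.rule_multisets <- function(rules, max_steps) {
  caps <- vapply(rules, `[[`, integer(1), "max_uses")
  grid <- do.call(expand.grid, lapply(caps, function(k) 0:k))
  names(grid) <- names(rules)
  keep <- rowSums(grid) <= max_steps
  for (j in seq_along(rules)) {
    others <- rowSums(grid[, -j, drop = FALSE]) > 0
    keep <- keep & !(others & grid[[j]] > rules[[j]]$max_uses_combined)
  }
  grid[keep, , drop = FALSE]
}

#' Class label for a biotransformation path
#'
#' Deterministic label grammar emitting the component strings of the source
#' study's summary table: parent alias `"ART"`, `"DHA"` once reduced (`+H2`),
#' `"de-"` prefix / `"-O"` suffix for deoxygenation, and `" + O"` /
#' `" + O2"` suffixes for hydroxylation. Paths over rules outside
#' `{+O, -O, +H2}` fall back to `"<alias> <label>xN ..."`.
#'
#' @param counts named integer vector, rule label -> number of applications.
#' @param parent_alias display name of the parent drug.
#' @param reduced_alias display name of the `+H2` (reduced) parent.
#' @return Single class-label string.
#' @export
class_label <- function(counts, parent_alias = "ART", reduced_alias = "DHA") {
  counts <- counts[counts > 0]
  known <- c("+O", "-O", "+H2")
  if (!all(names(counts) %in% known)) {
    extra <- counts[!names(counts) %in% known]
    base <- class_label(counts[names(counts) %in% known],
                        parent_alias, reduced_alias)
    return(paste(c(base, sprintf("%sx%d", names(extra), as.integer(extra))),
                 collapse = " "))
  }
  n_o <- if ("+O" %in% names(counts)) counts[["+O"]] else 0L
  deox <- "-O" %in% names(counts)
  red <- "+H2" %in% names(counts)
  base <- if (red) reduced_alias else parent_alias
  if (deox) base <- if (red) paste0(base, "-O") else paste0("de-", base)
  if (n_o == 1L) base <- paste0(base, " + O")
  if (n_o >= 2L) base <- paste0(base, " + O", n_o)
  base
}

#' Enumerate candidate metabolites of a parent drug
#'
#' Breadth-first closure of rule applications (as unordered multisets — the
#' order of formula-level transformations is chemically irrelevant) up to
#' `max_steps` total steps, honouring per-rule caps. Candidates are
#' deduplicated by path multiset, never by formula: isomeric classes such as
#' DHA (`+H2`) and DHA-O + O (`+H2,-O,+O`) share C15H24O5 but remain
#' distinct candidates. Paths whose delta would drive an element count
#' negative are pruned silently.
#'
#' @param parent parent-drug formula (string or `chem_formula`).
#' @param rules rule set, see [default_rule_set()].
#' @param max_steps maximum total rule applications per path (default 3).
#' @param parent_alias,reduced_alias label grammar, see [class_label()].
#' @return data.frame with one row per candidate: `class`, `formula`,
#'   `monoisotopic_mass`, `n_steps`, `path` (`;`-joined rule labels, sorted),
#'   ordered by path length then class label.
#' @examples
#' enumerate_candidates("C15H22O5")
#' @export
enumerate_candidates <- function(parent, rules = default_rule_set(),
                                 max_steps = 3L, parent_alias = "ART",
                                 reduced_alias = "DHA") {
  stopifnot(max_steps >= 0)
  parent <- .as_formula(parent)
  grid <- .rule_multisets(rules, max_steps)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    counts <- vapply(grid, function(col) col[i], numeric(1))
    f <- parent
    ok <- TRUE
    for (lab in names(counts)) {
      if (counts[[lab]] == 0L) next
      for (k in seq_len(counts[[lab]])) {
        f <- tryCatch(apply_formula_delta(f, rules[[lab]]$delta),
                      error = function(e) NULL)
        if (is.null(f)) break
      }
      if (is.null(f)) { ok <- FALSE; break }
    }
    if (!ok) return(NULL)  # infeasible branch pruned
    path <- rep(names(counts), counts)
    data.frame(
      class = class_label(counts, parent_alias, reduced_alias),
      formula = write_formula(f),
      monoisotopic_mass = formula_mass(f),
      n_steps = sum(counts),
      path = paste(sort(path), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_steps, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
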