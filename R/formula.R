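# Molecular formula arithmetic, adduct-rule ionisation products, and
# exhaustive formula enumeration within a ppm mass window.

# Most-abundant-isotope masses (Da). CHNOPS cover enumeration; Na/K/Cl are
# needed for adduct mass deltas only.
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069,
  Na = 22.98976928,
  K = 38.96370668,
  Cl = 34.96885268
)

# Mass of a proton; used for charge bookkeeping in all adduct deltas.
PROTON_MASS <- 1.007276

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula string such as `"C15H14O6"` into a named
#' integer vector of element counts.
#'
#' @param formula Formula string, e.g. `"C15H14O6"`, or an already-parsed
#'   named numeric vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C15H14O6")
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stopf("numeric formula must be a named element-count vector")
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
      stopf("formula must be a single non-empty string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (sum(nchar(toks)) != nchar(formula))
      stopf("cannot parse formula '%s'", formula)
    els <- sub("[0-9]*$", "", toks)
    ns <- as.integer(ifelse(grepl("[0-9]+$", toks),
                            sub("^[A-Za-z]+", "", toks), "1"))
    counts <- tapply(ns, els, sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stopf("formula contains no atoms")
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stopf("unknown element(s): %s", paste(unknown, collapse = ", "))
  storage.mode(counts) <- "integer"
  counts
}

#' Format an element-count vector as a formula string
#'
#' Hill order: C, then H, then remaining elements alphabetically.
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the most-abundant-isotope masses of the constituent atoms.
#'
#' @param formula Formula string or named element-count vector.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")       # 18.010565
#' monoisotopic_mass("C15H14O6")  # epicatechin, 290.079038
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

# Ring-plus-double-bond equivalents for a CHNOPS formula. N and P are
# trivalent, O and S divalent (contribute 0).
rdbe <- function(counts) {
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  g("C") + 1 + (g("N") + g("P")) / 2 - g("H") / 2
}

#' Default adduct (ionisation-product) rules
#'
#' Each rule maps a neutral formula of mass M to an observable ion m/z
#' `(n * M + mass_delta) / z`. `requires_elements` lists elements the neutral
#' formula must contain (e.g. ammonia loss requires N); `requires_ion` names a
#' mobile-phase ion that must be declared in the assignment context (e.g.
#' `[M+NH4]+` is only sensible when the mobile phase supplies NH4+).
#'
#' @return Data frame with columns `name`, `polarity`, `n`, `z`, `mass_delta`,
#'   `requires_elements`, `requires_ion`.
#' @export
default_adduct_rules <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[2M+H]+",
             "[M+H-H2O]+", "[M+H-NH3]+",
             "[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[2M-H]-"),
    polarity = c(rep("positive", 7), rep("negative", 4)),
    n = c(1, 1, 1, 1, 2, 1, 1, 1, 1, 1, 2),
    z = 1,
    mass_delta = c(
      PROTON_MASS,
      MONOISOTOPIC_MASS[["Na"]] - 0.00054858,
      MONOISOTOPIC_MASS[["K"]] - 0.00054858,
      MONOISOTOPIC_MASS[["N"]] + 4 * MONOISOTOPIC_MASS[["H"]] - 0.00054858,
      PROTON_MASS,
      PROTON_MASS - (2 * MONOISOTOPIC_MASS[["H"]] + MONOISOTOPIC_MASS[["O"]]),
      PROTON_MASS - (MONOISOTOPIC_MASS[["N"]] + 3 * MONOISOTOPIC_MASS[["H"]]),
      -PROTON_MASS,
      MONOISOTOPIC_MASS[["Cl"]] + 0.00054858,
      MONOISOTOPIC_MASS[["H"]] + MONOISOTOPIC_MASS[["C"]] +
        2 * MONOISOTOPIC_MASS[["O"]] + 0.00054858,
      -PROTON_MASS
    ),
    requires_elements = c("", "", "", "", "", "O", "N", "", "", "", ""),
    requires_ion = c("", "", "", "NH4+", "", "", "", "", "", "HCOO-", ""),
    stringsAsFactors = FALSE
  )
}

#' Read adduct rules from a TSV file
#'
#' The file must carry the columns of [default_adduct_rules()].
#'
#' @param path Path to a tab-separated rule file.
#' @return Adduct-rule data frame.
#' @export
read_adduct_rules <- function(path) {
  df <- read_tsv(path)
  need <- c("name", "polarity", "n", "z", "mass_delta",
            "requires_elements", "requires_ion")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("rule file missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$requires_elements[is.na(df$requires_elements)] <- ""
  df$requires_ion[is.na(df$requires_ion)] <- ""
  df
}

#' Write adduct rules to a TSV file
#' @param rules Adduct-rule data frame.
#' @param path Output path.
#' @export
write_adduct_rules <- function(rules, path) write_tsv(rules, path)

#' Is an adduct rule applicable to a formula?
#'
#' A rule is rejected when the neutral formula lacks a required element (a
#' molecule without nitrogen cannot lose ammonia) or when the rule needs a
#' mobile-phase ion that the declared context does not supply.
#'
#' @param formula Formula string or element-count vector.
#' @param rule One row of an adduct-rule data frame.
#' @param context List with element `mobile_phase_ions` (character vector of
#'   ion names present in the mobile phase, e.g. `"NH4+"`). Default: none.
#' @return `TRUE` or `FALSE`.
#' @export
rule_applicable <- function(formula, rule,
                            context = list(mobile_phase_ions = character())) {
  counts <- parse_formula(formula)
  req_el <- rule$requires_elements
  if (!is.na(req_el) && nzchar(req_el)) {
    need <- strsplit(req_el, ",", fixed = TRUE)[[1]]
    if (!all(need %in% names(counts))) return(FALSE)
  }
  req_ion <- rule$requires_ion
  if (!is.na(req_ion) && nzchar(req_ion)) {
    ions <- context$mobile_phase_ions
    if (is.null(ions) || !(req_ion %in% ions)) return(FALSE)
  }
  TRUE
}

#' Ion m/z of a formula under an adduct rule
#'
#' `(n * M + mass_delta) / z` with `M = monoisotopic_mass(formula)`.
#'
#' @inheritParams rule_applicable
#' @return Ion m/z in Da.
#' @export
#' @examples
#' rules <- default_adduct_rules()
#' ion_mz("C15H14O6", rules[rules$name == "[M-H]-", ])  # 289.071762
ion_mz <- function(formula, rule,
                   context = list(mobile_phase_ions = character())) {
  if (!rule_applicable(formula, rule, context))
    stopf("rule %s not applicable to formula %s", rule$name,
          if (is.character(formula)) formula else format_formula(formula))
  (rule$n * monoisotopic_mass(formula) + rule$mass_delta) / rule$z
}

#' Default CHNOPS element ranges for formula enumeration
#' @return Named list of `c(min, max)` element counts.
#' @export
default_element_ranges <- function() {
  list(C = c(0, 30), H = c(0, 60), N = c(0, 5),
       O = c(0, 15), P = c(0, 2), S = c(0, 2))
}

#' Enumerate molecular formulas within a ppm window of a neutral mass
#'
#' Searches the CHNOPS grid for formulas whose monoisotopic mass lies within
#' `ppm_tol` parts per million of `neutral_mass`, keeping only chemically
#' plausible candidates: ring-plus-double-bond equivalents (RDBE) must be
#' non-negative and integer-valued (an even-electron neutral species).
#' Results are sorted by absolute ppm error.
#'
#' @param neutral_mass Target neutral mass (Da), > 0.
#' @param ppm_tol Mass tolerance in ppm (default 3).
#' @param element_ranges Named list of `c(min, max)` counts per element; see
#'   [default_element_ranges()].
#' @return Data frame with columns `formula`, `mass`, `ppm`, `rdbe`.
#' @export
enumerate_formulas <- function(neutral_mass, ppm_tol = 3,
                               element_ranges = default_element_ranges()) {
  if (!is.numeric(neutral_mass) || neutral_mass <= 0)
    stopf("neutral_mass must be > 0")
  rng <- lapply(element_ranges, function(r) {
    if (length(r) == 1) c(0, r) else r
  })
  unknown <- setdiff(names(rng), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stopf("unknown element(s) in ranges: %s", paste(unknown, collapse = ", "))

  lo <- neutral_mass * (1 - ppm_tol * 1e-6)
  hi <- neutral_mass * (1 + ppm_tol * 1e-6)

  # Grid over the non-H elements; the H count is then pinned to a narrow
  # integer window by the residual mass, so the search is linear in the
  # non-H grid size rather than the full product grid.
  heavy <- setdiff(names(rng), "H")
  grids <- lapply(heavy, function(el) seq(rng[[el]][1], rng[[el]][2]))
  names(grids) <- heavy
  grid_size <- prod(vapply(grids, length, 1L))
  if (grid_size > 5e6)
    stopf("element ranges produce a %g-point search grid; narrow the ranges",
          grid_size)
  combos <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  heavy_mass <- as.numeric(as.matrix(combos) %*% MONOISOTOPIC_MASS[heavy])

  h_rng <- if ("H" %in% names(rng)) rng[["H"]] else c(0, 0)
  mh <- MONOISOTOPIC_MASS[["H"]]
  h_lo <- pmax(h_rng[1], ceiling((lo - heavy_mass) / mh - 1e-9))
  h_hi <- pmin(h_rng[2], floor((hi - heavy_mass) / mh + 1e-9))
  keep <- which(h_lo <= h_hi)

  out <- vector("list", length(keep))
  n_out <- 0L
  for (i in keep) {
    for (h in seq(h_lo[i], h_hi[i])) {
      counts <- c(as.integer(combos[i, , drop = TRUE]), H = as.integer(h))
      names(counts) <- c(heavy, "H")
      counts <- counts[counts > 0]
      if (length(counts) == 0L) next
      r <- rdbe(counts)
      if (r < 0 || abs(r - round(r)) > 1e-9) next
      mass <- heavy_mass[i] + h * mh
      n_out <- n_out + 1L
      if (n_out > 1e6)
        stopf("more than 1e6 candidate formulas; narrow the element ranges")
      out[[n_out]] <- list(formula = format_formula(counts), mass = mass,
                           ppm = 1e6 * (neutral_mass - mass) / mass, rdbe = r)
    }
  }
  if (n_out == 0L)
    return(data.frame(formula = character(), mass = numeric(),
                      ppm = numeric(), rdbe = numeric()))
  df <- do.call(rbind, lapply(out[seq_len(n_out)], as.data.frame))
  df[order(abs(df$ppm)), , drop = FALSE]
}

#' Assign candidate molecular formulas to a binned m/z feature
#'
#' For every adduct rule matching the feature's polarity (and the declared
#' mobile-phase context), the observed ion m/z is inverted to a neutral mass,
#' formulas are enumerated within the ppm tolerance, and candidates are kept
#' when the rule is applicable to them and the ion-m/z error is within
#' tolerance. Candidates are sorted by absolute ppm error.
#'
#' @param mz Observed ion m/z (typically a bin centre).
#' @param polarity `"positive"` or `"negative"`.
#' @param rules Adduct-rule data frame; see [default_adduct_rules()].
#' @param element_ranges See [default_element_ranges()].
#' @param ppm_tol Mass tolerance in ppm (default 3).
#' @param context Assignment context; see [rule_applicable()].
#' @return Data frame of candidates: `formula`, `adduct`, `neutral_mass`,
#'   `ion_mz`, `ppm` (empty when nothing matches).
#' @export
assign_feature <- function(mz, polarity, rules = default_adduct_rules(),
                           element_ranges = default_element_ranges(),
                           ppm_tol = 3,
                           context = list(mobile_phase_ions = character())) {
  stopifnot(polarity %in% c("positive", "negative"))
  rules <- rules[rules$polarity == polarity, , drop = FALSE]
  # Mobile-phase requirement is formula-independent: filter rules up front.
  ok_ion <- vapply(seq_len(nrow(rules)), function(i) {
    ri <- rules$requires_ion[i]
    is.na(ri) || !nzchar(ri) || ri %in% context$mobile_phase_ions
  }, TRUE)
  rules <- rules[ok_ion, , drop = FALSE]

  res <- list()
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    m0 <- (rule$z * mz - rule$mass_delta) / rule$n
    if (m0 <= 0) next
    # Enumerate with a padded window on the neutral mass, then filter on the
    # exact ion-m/z ppm error (the two scales differ when mass_delta != 0).
    cand <- enumerate_formulas(m0, ppm_tol * 2, element_ranges)
    if (nrow(cand) == 0) next
    ok <- vapply(cand$formula, function(f)
      rule_applicable(f, rule, context), TRUE)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    theo <- (rule$n * cand$mass + rule$mass_delta) / rule$z
    ppm <- 1e6 * (mz - theo) / theo
    keep <- abs(ppm) <= ppm_tol
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      formula = cand$formula[keep], adduct = rule$name,
      neutral_mass = cand$mass[keep], ion_mz = theo[keep], ppm = ppm[keep],
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(formula = character(), adduct = character(),
                      neutral_mass = numeric(), ion_mz = numeric(),
                      ppm = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(abs(out$ppm)), , drop = FALSE]
}

#' Match compounds for a formula with tiered database fallback
#'
#' Returns primary-tier snapshot matches when any exist, otherwise
#' fallback-tier matches (mirroring a KEGG-first, PubChem-fallback search
#' against local snapshots).
#'
#' @param formula Formula string.
#' @param snapshot Compound snapshot data frame with columns `compound_id`,
#'   `formula`, `tier` (`"primary"`/`"fallback"`), `taxonomy_path`.
#' @return Subset of `snapshot` rows (possibly empty), with the tier used.
#' @export
match_compounds <- function(formula, snapshot) {
  hits <- snapshot[snapshot$formula == formula, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  prim <- hits[hits$tier == "primary", , drop = FALSE]
  if (nrow(prim) > 0) prim else hits[hits$tier == "fallback", , drop = FALSE]
}

#' Consensus structural classification of taxonomy paths
#'
#' Descends the taxonomy level by level. At each level the modal label among
#' the paths that survived to that level is kept if and only if its frequency
#' over *all* input paths reaches `threshold`; ties for the modal label stop
#' the descent. The result is the deepest agreed prefix.
#'
#' @param paths Character vector of `"/"`-separated taxonomy paths (or a list
#'   of character vectors of labels).
#' @param threshold Required consensus fraction in (0, 1] (default 0.66).
#' @return List with `path` (character vector of agreed labels, possibly
#'   empty) and `depth`.
#' @export
#' @examples
#' consensus_classification(c("A/B/C", "A/B/D", "A/E/F"))  # A/B, depth 2
consensus_classification <- function(paths, threshold = 0.66) {
  if (length(paths) == 0) stopf("no taxonomy paths supplied")
  if (is.character(paths)) paths <- strsplit(paths, "/", fixed = TRUE)
  n_total <- length(paths)
  consensus <- character()
  level <- 1L
  surviving <- paths
  repeat {
    labs <- vapply(surviving, function(p)
      if (length(p) >= level) p[[level]] else NA_character_, "")
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0) break
    tab <- sort(table(labs), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) break  # modal tie: no consensus
    modal <- names(tab)[1]
    if (tab[[1]] / n_total < threshold) break
    consensus <- c(consensus, modal)
    surviving <- Filter(function(p)
      length(p) >= level && p[[level]] == modal, surviving)
    level <- level + 1L
  }
  list(path = consensus, depth = length(consensus))
}

#' Assign formulas, compounds and consensus classes to a feature matrix
#'
#' Runs [assign_feature()] on every feature of a binned matrix, matches
#' compounds with tiered fallback, and derives a consensus taxonomy path per
#' feature. The candidate used for compound matching is the best-supported
#' one: candidates with primary-tier matches are preferred over fallback-tier,
#' then smaller absolute ppm error wins.
#'
#' @param matrix A `fiems_matrix` (see [bin_samples()]).
#' @param snapshot Compound snapshot data frame (see [match_compounds()]).
#' @param rules,element_ranges,ppm_tol,context See [assign_feature()].
#' @return Data frame with one row per feature: `feature_id`, `polarity`,
#'   `mz`, `formula`, `adduct`, `ppm`, `tier`, `compound_ids` (comma list),
#'   `consensus_path` ("/"-joined), `consensus_depth`.
#' @export
assign_features <- function(matrix, snapshot,
                            rules = default_adduct_rules(),
                            element_ranges = default_element_ranges(),
                            ppm_tol = 3,
                            context = list(mobile_phase_ions = character())) {
  feats <- matrix$features
  # the accurate (intensity-weighted) m/z carries the sub-bin mass
  # information; the rounded bin label is only a fallback
  mzs <- if ("mz" %in% names(feats)) feats$mz else feats$bin_mz
  out <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    cand <- assign_feature(mzs[i], feats$polarity[i], rules,
                           element_ranges, ppm_tol, context)
    row <- data.frame(feature_id = feats$id[i], polarity = feats$polarity[i],
                      mz = mzs[i], formula = NA_character_,
                      adduct = NA_character_, ppm = NA_real_,
                      tier = NA_character_, compound_ids = "",
                      consensus_path = "", consensus_depth = 0L,
                      stringsAsFactors = FALSE)
    if (nrow(cand) > 0) {
      matches <- lapply(cand$formula, match_compounds, snapshot = snapshot)
      tier_rank <- vapply(matches, function(m) {
        if (nrow(m) == 0) 3L else if (m$tier[1] == "primary") 1L else 2L
      }, 1L)
      best <- order(tier_rank, abs(cand$ppm))[1]
      row$formula <- cand$formula[best]
      row$adduct <- cand$adduct[best]
      row$ppm <- cand$ppm[best]
      m <- matches[[best]]
      if (nrow(m) > 0) {
        row$tier <- m$tier[1]
        row$compound_ids <- paste(m$compound_id, collapse = ",")
        cons <- consensus_classification(m$taxonomy_path)
        row$consensus_path <- paste(cons$path, collapse = "/")
        row$consensus_depth <- cons$depth
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Class-frequency table over consensus classifications
#'
#' For each taxonomy level, counts the features whose consensus path reaches
#' that level, by label. Each feature contributes at most once per level, so
#' level-k totals never exceed level-(k-1) totals.
#'
#' @param assignments Output of [assign_features()].
#' @return Data frame `level`, `label`, `count`.
#' @export
class_frequency_table <- function(assignments) {
  paths <- strsplit(assignments$consensus_path, "/", fixed = TRUE)
  paths <- Filter(function(p) length(p) > 0 && nzchar(p[1]), paths)
  if (length(paths) == 0)
    return(data.frame(level = integer(), label = character(),
                      count = integer()))
  max_d <- max(lengths(paths))
  out <- list()
  for (lev in seq_len(max_d)) {
    labs <- vapply(paths, function(p)
      if (length(p) >= lev) p[[lev]] else NA_character_, "")
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0) next
    tab <- table(labs)
    out[[lev]] <- data.frame(level = lev, label = names(tab),
                             count = as.integer(tab),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
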