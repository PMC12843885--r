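# Seeded synthetic FIE-MS datasets with known ground truth: experimental
# design, feature matrix with planted stage trends, centroided spectra,
# compound-snapshot library and a layered compound knowledge graph.

#' Ordered stage labels for the green-tea design
#' @return Character vector of six stages.
#' @export
green_stages <- function() {
  c("picking", "wither90", "fixation", "rolling", "oxidation", "roasting")
}

#' Ordered stage labels for the black-tea design
#'
#' Seven stages; `oxidation` and `roasting` branch into a 4 h and an
#' overnight oxidation arm.
#' @return Character vector of seven stages.
#' @export
black_stages <- function() {
  c("picking", "wither85", "wither70", "wither60", "rolling",
    "oxidation", "roasting")
}

# Typical moisture fraction per stage label; leaves start around 75-80%
# moisture, withering targets are encoded in the label, and roasting dries
# the leaf almost completely.
stage_moisture_target <- function(stage) {
  known <- c(picking = 0.78, wither90 = 0.90, wither85 = 0.85,
             wither70 = 0.70, wither60 = 0.60, fixation = 0.65,
             rolling = 0.60, oxidation = 0.55, roasting = 0.05)
  ifelse(stage %in% names(known), known[stage], 0.6)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Identical
#' configuration + seed yields byte-identical outputs from every generator.
#'
#' @param seed Integer master seed.
#' @param stages Ordered character vector of stage labels.
#' @param arms Character vector of process arms branching at `arm_stages`
#'   (empty for an unbranched design).
#' @param arm_stages Stages that branch into arms.
#' @param replicates_per_stage Biological replicates per stage (>= 2,
#'   default 3).
#' @param n_qc Number of pooled-QC injections (default 3).
#' @param n_features Total number of m/z features (default 2000).
#' @param n_informative Features carrying a stage-dependent trend.
#' @param n_trend_clusters Number of planted trend shapes.
#' @param noise_sigma Log-scale standard deviation of intensity noise.
#' @param trend_amplitude Log-scale range of the planted trends (difference
#'   between the lowest and highest stage mean). Default: a 3-sigma effect
#'   per stage step, `3 * noise_sigma * (length(stages) - 1)`, or 1 when
#'   `noise_sigma` is 0.
#' @param ppm_jitter Per-scan mass-error scale in ppm.
#' @param mz_range `c(low, high)` acquisition window in Da (default 55-1200).
#' @param n_scans Scans per polarity per sample (>= 5, default 10).
#' @param n_compounds Compounds in the snapshot library.
#' @param n_pathways Pathways in the knowledge graph (>= 2).
#' @param planted_pathway_fraction Fraction of informative features whose
#'   formulas map to compounds of the planted pathway.
#' @return A `fiems_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       stages = green_stages(),
                       arms = character(),
                       arm_stages = character(),
                       replicates_per_stage = 3L,
                       n_qc = 3L,
                       n_features = 2000L,
                       n_informative = 100L,
                       n_trend_clusters = 5L,
                       noise_sigma = 0.2,
                       trend_amplitude = NULL,
                       ppm_jitter = 3,
                       mz_range = c(55, 1200),
                       n_scans = 10L,
                       n_compounds = 120L,
                       n_pathways = 6L,
                       planted_pathway_fraction = 0.5) {
  if (length(stages) == 0) stopf("stages must be non-empty")
  if (replicates_per_stage < 2) stopf("replicates_per_stage must be >= 2")
  if (n_informative > n_features)
    stopf("n_informative (%d) exceeds n_features (%d)",
          n_informative, n_features)
  if (n_trend_clusters > max(n_informative, 1) && n_informative > 0)
    stopf("n_trend_clusters exceeds n_informative")
  if (mz_range[1] >= mz_range[2]) stopf("invalid mz_range")
  if (n_pathways < 2) stopf("n_pathways must be >= 2")
  if (n_scans < 5) stopf("n_scans must be >= 5")
  if (length(arms) > 0 && length(arm_stages) == 0)
    stopf("arms declared without arm_stages")
  if (is.null(trend_amplitude))
    trend_amplitude <- if (noise_sigma > 0)
      3 * noise_sigma * max(1L, length(stages) - 1L) else 1
  structure(list(
    seed = as.integer(seed), stages = stages, arms = arms,
    arm_stages = arm_stages,
    replicates_per_stage = as.integer(replicates_per_stage),
    n_qc = as.integer(n_qc), n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    n_trend_clusters = as.integer(n_trend_clusters),
    noise_sigma = noise_sigma, trend_amplitude = trend_amplitude,
    ppm_jitter = ppm_jitter, mz_range = mz_range,
    n_scans = as.integer(n_scans), n_compounds = as.integer(n_compounds),
    n_pathways = as.integer(n_pathways),
    planted_pathway_fraction = planted_pathway_fraction
  ), class = "fiems_sim_config")
}

#' Black-tea simulation configuration template
#'
#' Seven stages with `oxidation` and `roasting` branching into a 4 h and an
#' overnight arm.
#'
#' @param ... Passed to [sim_config()].
#' @export
sim_config_black <- function(...) {
  sim_config(stages = black_stages(), arms = c("4h", "overnight"),
             arm_stages = c("oxidation", "roasting"), ...)
}

#' Simulate the experimental design / sample table
#'
#' One record per stage x replicate (x arm for branching stages), plus
#' pooled-QC injections. Fresh weights are drawn uniformly around 1 g,
#' moisture per sample type follows the stage's moisture target with small
#' jitter (measured once per type and propagated to its replicates), and
#' extract weights are uniform around the 50 mg milling target.
#'
#' @param config A [sim_config()].
#' @return Data frame: `sample_id`, `stage`, `arm`, `replicate`,
#'   `fresh_weight`, `dry_weight`, `extract_weight`, `is_qc`.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "fiems_sim_config"))
  if (config$replicates_per_stage < 2)
    stopf("invalid design: fewer than 2 replicates per stage")
  set.seed(derive_seed(config$seed, 1L))

  types <- list()
  for (st in config$stages) {
    if (st %in% config$arm_stages && length(config$arms) > 0) {
      for (arm in config$arms) types[[length(types) + 1L]] <- c(st, arm)
    } else {
      types[[length(types) + 1L]] <- c(st, NA_character_)
    }
  }

  rows <- list()
  for (tp in types) {
    st <- tp[1]; arm <- tp[2]
    moisture <- min(max(stage_moisture_target(st) +
                          stats::rnorm(1, 0, 0.01), 0.01), 0.95)
    fresh <- stats::runif(1, 800, 1200)          # mg, moisture replicate
    dry <- fresh * (1 - moisture)
    for (r in seq_len(config$replicates_per_stage)) {
      tag <- if (is.na(arm)) st else paste0(st, "_", arm)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d", tag, r), stage = st, arm = arm,
        replicate = r, fresh_weight = fresh, dry_weight = dry,
        extract_weight = stats::runif(1, 45, 55), is_qc = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  for (q in seq_len(config$n_qc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("QC_r%d", q), stage = NA_character_,
      arm = NA_character_, replicate = q, fresh_weight = NA_real_,
      dry_weight = NA_real_, extract_weight = NA_real_, is_qc = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Canonical trend shapes on [0, 1] over the ordered stages: monotone rise,
# monotone fall, mid peak, mid valley, late rise, early fall, then phase-
# shifted peaks for larger k.
trend_shape <- function(idx, n_stages) {
  x <- seq(0, 1, length.out = n_stages)
  base <- switch(((idx - 1L) %% 6L) + 1L,
    x,                       # monotone up
    1 - x,                   # monotone down
    1 - abs(2 * x - 1),      # peak at middle
    abs(2 * x - 1),          # valley at middle
    pmax(0, 2 * x - 1),      # late rise
    pmax(0, 1 - 2 * x)       # early fall
  )
  shift <- ((idx - 1L) %/% 6L) * 0.25
  s <- (base + shift * sin(pi * x)) # phase-perturb repeats beyond 6 shapes
  (s - min(s)) / max(max(s) - min(s), 1e-12)
}

#' Simulate a binned feature matrix with planted trends
#'
#' Uninformative features have stage-independent log-normal intensities;
#' informative features additionally follow one of `n_trend_clusters`
#' per-stage trend templates, scaled to `trend_amplitude` on the log scale.
#' All intensities of a sample are multiplied by its dry-mass equivalent
#' relative to the smallest sample, emulating raw extracts of differing
#' material amounts; [weight_normalise()] removes this factor exactly.
#' Informative features are preferentially given true ion m/z values derived
#' from the compound library (via the base protonation/deprotonation rules),
#' so formula assignment can recover them; the remainder get random m/z
#' placed away from bin boundaries.
#'
#' @param config A [sim_config()].
#' @param design Optional pre-computed [simulate_design()] output.
#' @return List with `matrix` (a `fiems_matrix`), `truth` (ground-truth list:
#'   `informative_feature_ids`, `cluster_membership`, `trend_templates` as a
#'   cluster x stage matrix of percentage profiles, `planted_pathway_id`,
#'   `planted_compound_ids`, `feature_formula`, `feature_true_mz`), and
#'   `design`.
#' @export
simulate_feature_matrix <- function(config, design = simulate_design(config)) {
  stopifnot(inherits(config, "fiems_sim_config"))
  if (config$n_trend_clusters > config$n_informative &&
      config$n_informative > 0)
    stopf("n_trend_clusters exceeds n_informative")
  lib <- simulate_compound_library(config)
  set.seed(derive_seed(config$seed, 2L))

  n_feat <- config$n_features
  n_inf <- config$n_informative
  stages <- config$stages
  n_stage <- length(stages)

  polarity <- sample(c("negative", "positive"), n_feat, replace = TRUE,
                     prob = c(0.55, 0.45))
  feature_formula <- rep(NA_character_, n_feat)
  true_mz <- numeric(n_feat)

  # Informative features take library formulas (planted-pathway compounds
  # first), ionised by the base rule of their polarity.
  rules <- default_adduct_rules()
  rule_pos <- rules[rules$name == "[M+H]+", ]
  rule_neg <- rules[rules$name == "[M-H]-", ]
  planted_forms <- unique(lib$compounds$formula[
    lib$compounds$compound_id %in% lib$planted_compound_ids])
  other_forms <- setdiff(unique(lib$compounds$formula), planted_forms)
  n_planted_feat <- min(n_inf, ceiling(config$planted_pathway_fraction * n_inf))
  form_pool <- c(rep_len(planted_forms, n_planted_feat),
                 if (n_inf > n_planted_feat)
                   rep_len(other_forms, n_inf - n_planted_feat))
  if (n_inf > 0) {
    for (i in seq_len(n_inf)) {
      f <- form_pool[i]
      rule <- if (polarity[i] == "positive") rule_pos else rule_neg
      imz <- ion_mz(f, rule)
      if (imz < config$mz_range[1] || imz > config$mz_range[2]) {
        f <- NA_character_
      }
      if (!is.na(f)) {
        feature_formula[i] <- f
        true_mz[i] <- imz
      }
    }
  }
  # Remaining features: random m/z kept in the central 60% of a 0.01 bin so
  # ppm jitter cannot cross a bin boundary.
  need <- which(true_mz == 0)
  bins <- round_half_up(stats::runif(length(need), config$mz_range[1] + 1,
                                     config$mz_range[2] - 1))
  true_mz[need] <- bins + stats::runif(length(need), -0.003, 0.003)

  # De-duplicate (polarity, bin) collisions by nudging to a free bin.
  bin_id <- paste0(ifelse(polarity == "positive", "p", "n"),
                   sprintf("%.2f", round_half_up(true_mz)))
  dup <- duplicated(bin_id)
  tries <- 0L
  while (any(dup) && tries < 200L) {
    idx <- which(dup)
    shift_bins <- round_half_up(stats::runif(length(idx), config$mz_range[1] + 1,
                                             config$mz_range[2] - 1))
    true_mz[idx] <- shift_bins + stats::runif(length(idx), -0.003, 0.003)
    feature_formula[idx] <- NA_character_
    bin_id <- paste0(ifelse(polarity == "positive", "p", "n"),
                     sprintf("%.2f", round_half_up(true_mz)))
    dup <- duplicated(bin_id)
    tries <- tries + 1L
  }
  if (any(dup)) stopf("could not place %d features in unique bins", sum(dup))

  cluster_membership <- rep(NA_integer_, n_feat)
  if (n_inf > 0)
    cluster_membership[seq_len(n_inf)] <-
      rep_len(seq_len(config$n_trend_clusters), n_inf)

  shapes <- t(vapply(seq_len(config$n_trend_clusters), trend_shape,
                     numeric(n_stage), n_stages = n_stage))
  log_offsets <- shapes * config$trend_amplitude

  baseline <- stats::runif(n_feat, log(1e4), log(1e6))
  samp <- design
  n_samp <- nrow(samp)
  values <- matrix(0, n_feat, n_samp)
  stage_idx <- match(samp$stage, stages)
  # Raw intensities scale with the amount of material extracted: multiply
  # each sample by its dry-mass equivalent relative to the smallest, which
  # weight normalisation later removes.
  dmass <- samp$extract_weight * (samp$dry_weight / samp$fresh_weight)
  size_factor <- ifelse(samp$is_qc, 1, dmass / min(dmass, na.rm = TRUE))
  for (j in seq_len(n_samp)) {
    mu <- baseline
    if (samp$is_qc[j]) {
      # pooled QC: average trend contribution, halved technical noise
      if (n_inf > 0) {
        cl <- cluster_membership[seq_len(n_inf)]
        mu[seq_len(n_inf)] <- mu[seq_len(n_inf)] + rowMeans(log_offsets)[cl]
      }
      eps <- stats::rnorm(n_feat, 0, config$noise_sigma / 2)
    } else {
      if (n_inf > 0) {
        cl <- cluster_membership[seq_len(n_inf)]
        mu[seq_len(n_inf)] <- mu[seq_len(n_inf)] + log_offsets[cl, stage_idx[j]]
      }
      eps <- stats::rnorm(n_feat, 0, config$noise_sigma)
    }
    values[, j] <- size_factor[j] * exp(mu + eps)
  }
  colnames(values) <- samp$sample_id
  rownames(values) <- bin_id

  features <- data.frame(id = bin_id, polarity = polarity,
                         bin_mz = round_half_up(true_mz), mz = true_mz,
                         stringsAsFactors = FALSE)
  mat <- new_fiems_matrix(values, features,
                          provenance = list(source = "synthetic",
                                            seed = config$seed))

  # Templates on the percentage-relative-abundance scale: the multiplicative
  # baseline cancels, so zero-noise features reproduce these exactly.
  templates <- t(apply(exp(log_offsets), 1L,
                       function(v) 100 * v / sum(v)))
  colnames(templates) <- stages

  truth <- list(
    informative_feature_ids = bin_id[which(!is.na(cluster_membership))],
    cluster_membership = stats::setNames(
      cluster_membership[!is.na(cluster_membership)],
      bin_id[!is.na(cluster_membership)]),
    trend_templates = templates,
    planted_pathway_id = lib$planted_pathway_id,
    planted_compound_ids = lib$planted_compound_ids,
    feature_formula = stats::setNames(feature_formula, bin_id),
    feature_true_mz = stats::setNames(true_mz, bin_id)
  )
  list(matrix = mat, truth = truth, design = design)
}

#' Simulate centroided per-sample scan lists from a feature matrix
#'
#' Each sample receives `n_scans` scans per polarity following a flow-infusion
#' TIC profile: short ramps (relative intensity < 0.5) flank a plateau at
#' exactly 1.0, so the default scan-window rule retains the plateau and
#' re-binning reproduces the input matrix when `ppm_jitter` is 0. Peak m/z is
#' jittered per scan as `true_mz * (1 + e)`, `e ~ N(0, ppm_jitter * 1e-6)`.
#'
#' @param sim Output of [simulate_feature_matrix()].
#' @param config The same [sim_config()].
#' @return Named list (per sample) of lists with elements `positive` and
#'   `negative`, each a list of scans; a scan is a list with `scan_index` and
#'   `peaks` (two-column matrix `mz`, `intensity`, sorted by m/z).
#' @export
simulate_spectra <- function(sim, config) {
  stopifnot(inherits(config, "fiems_sim_config"))
  mat <- sim$matrix
  truth <- sim$truth
  true_mz <- truth$feature_true_mz[mat$features$id]
  if (any(is.na(true_mz))) stopf("every feature needs a true m/z")
  set.seed(derive_seed(config$seed, 3L))

  # Warn about features whose true m/z sits close enough to a bin boundary
  # for 4-sigma mass jitter to cross it.
  if (config$ppm_jitter > 0) {
    off <- true_mz - (round_half_up(true_mz) - 0.005)
    margin <- pmin(off, 0.01 - off)
    risky <- mat$features$id[margin < 4 * config$ppm_jitter * 1e-6 * true_mz]
    if (length(risky))
      warnf("ppm jitter may cross bin boundaries for feature(s): %s",
            paste(utils::head(risky, 10), collapse = ", "))
  }

  n_scans <- config$n_scans
  ramp <- c(0.2, 0.4)
  tic_profile <- c(ramp, rep(1, n_scans - 4), rev(ramp))

  pol_split <- split(seq_len(nrow(mat$features)), mat$features$polarity)
  out <- vector("list", ncol(mat$values))
  names(out) <- colnames(mat$values)
  for (j in seq_len(ncol(mat$values))) {
    per_pol <- list()
    for (pol in c("positive", "negative")) {
      idx <- pol_split[[pol]]
      scans <- vector("list", n_scans)
      for (s in seq_len(n_scans)) {
        if (length(idx) == 0) {
          scans[[s]] <- list(scan_index = s,
                             peaks = matrix(numeric(), 0, 2,
                                            dimnames = list(NULL,
                                                            c("mz", "intensity"))))
          next
        }
        eps <- stats::rnorm(length(idx), 0, config$ppm_jitter * 1e-6)
        mz <- true_mz[idx] * (1 + eps)
        inten <- mat$values[idx, j] * tic_profile[s]
        ord <- order(mz)
        scans[[s]] <- list(scan_index = s,
                           peaks = cbind(mz = mz[ord], intensity = inten[ord]))
      }
      per_pol[[pol]] <- scans
    }
    out[[j]] <- per_pol
  }
  out
}

# Small synthetic chemical taxonomy used by the compound library.
SYNTH_TAXONOMY <- list(
  c("Organic compounds", "Phenylpropanoids and polyketides", "Flavonoids",
    "Flavans"),
  c("Organic compounds", "Phenylpropanoids and polyketides", "Flavonoids",
    "Flavonol glycosides"),
  c("Organic compounds", "Phenylpropanoids and polyketides",
    "Cinnamic acids and derivatives", "Hydroxycinnamic acids"),
  c("Organic compounds", "Organic acids and derivatives",
    "Carboxylic acids and derivatives", "Amino acids"),
  c("Organic compounds", "Organic acids and derivatives",
    "Carboxylic acids and derivatives", "Dicarboxylic acids"),
  c("Organic compounds", "Organic oxygen compounds",
    "Organooxygen compounds", "Carbohydrates"),
  c("Organic compounds", "Lipids and lipid-like molecules",
    "Fatty acyls", "Fatty acids"),
  c("Organic compounds", "Organoheterocyclic compounds",
    "Pyridines and derivatives", "Pyridine carboxylic acids"),
  c("Organic compounds", "Phenylpropanoids and polyketides",
    "Isoflavonoids", "Isoflavones")
)

# Random plausible CHNO formula with integer, non-negative RDBE.
random_formula <- function() {
  repeat {
    cc <- sample(5:24, 1)
    oo <- sample(0:12, 1)
    nn <- sample(0:3, 1, prob = c(0.6, 0.2, 0.15, 0.05))
    max_h <- 2 * cc + nn + 2
    hh <- sample(seq(max(1, cc %/% 2), max_h), 1)
    if ((hh + nn) %% 2 == 1) hh <- hh + 1  # integer RDBE
    if (hh > max_h) next
    counts <- c(C = cc, H = hh, N = nn, O = oo)
    counts <- counts[counts > 0]
    if (rdbe(counts) >= 0) return(format_formula(counts))
  }
}

#' Simulate a local compound-snapshot library with taxonomy paths
#'
#' Generates `n_compounds` compounds with molecular formulas, a database tier
#' (`primary` emulating a curated pathway database, `fallback` emulating a
#' broader structure database) and a chemical-taxonomy path of depth >= 3.
#' Some formulas are deliberately shared by several compounds — including one
#' trio whose paths agree only to depth 2 — to exercise consensus
#' classification.
#'
#' @param config A [sim_config()].
#' @return List with `compounds` (data frame `compound_id`, `name`, `formula`,
#'   `tier`, `taxonomy_path`), `planted_compound_ids`, `planted_pathway_id`.
#' @export
simulate_compound_library <- function(config) {
  stopifnot(inherits(config, "fiems_sim_config"))
  if (config$n_compounds < 1) stopf("n_compounds must be >= 1")
  set.seed(derive_seed(config$seed, 4L))
  n <- config$n_compounds

  n_formula <- max(1L, ceiling(n * 0.7))
  formulas <- character(n_formula)
  seen <- character()
  for (i in seq_len(n_formula)) {
    repeat {
      f <- random_formula()
      if (!(f %in% seen)) break
    }
    formulas[i] <- f
    seen <- c(seen, f)
  }

  form_of <- c(seq_len(n_formula),
               sample(n_formula, n - n_formula, replace = TRUE))
  tax_idx <- sample(seq_along(SYNTH_TAXONOMY), n, replace = TRUE)
  # Compounds sharing a formula usually share a taxonomy branch.
  for (f in unique(form_of)) {
    members <- which(form_of == f)
    if (length(members) > 1) tax_idx[members] <- tax_idx[members[1]]
  }
  paths <- vapply(tax_idx, function(i)
    paste(SYNTH_TAXONOMY[[i]], collapse = "/"), "")

  tier <- sample(c("primary", "fallback"), n, replace = TRUE,
                 prob = c(0.7, 0.3))

  df <- data.frame(
    compound_id = sprintf("CPD%04d", seq_len(n)),
    name = sprintf("compound %04d", seq_len(n)),
    formula = formulas[form_of], tier = tier, taxonomy_path = paths,
    stringsAsFactors = FALSE)

  # Guarantee one formula carried by 3 compounds whose paths agree to depth 2
  # only (same kingdom/superclass, three diverging classes).
  if (n >= 3) {
    trio <- utils::tail(seq_len(n), 3)
    df$formula[trio] <- formulas[1]
    df$tier[trio] <- "primary"
    df$taxonomy_path[trio] <- c(
      paste(SYNTH_TAXONOMY[[1]], collapse = "/"),
      paste(SYNTH_TAXONOMY[[3]], collapse = "/"),
      paste(SYNTH_TAXONOMY[[9]], collapse = "/"))
  }

  n_planted <- max(2L, min(n, ceiling(n * 0.15)))
  list(compounds = df,
       planted_compound_ids = df$compound_id[seq_len(n_planted)],
       planted_pathway_id = "PTH001")
}

#' Simulate a layered compound knowledge graph with a planted pathway
#'
#' Builds an undirected compound-reaction-enzyme-module-pathway graph in the
#' style of a metabolic knowledge base. Pathway `PTH001` is the planted one:
#' its reactions are wired to the planted compound set, so diffusion from
#' those compounds concentrates on it; the remaining pathways connect to
#' random non-planted compounds.
#'
#' @param config A [sim_config()].
#' @param library Optional pre-computed [simulate_compound_library()] output
#'   (regenerated from `config` when omitted; both routes are deterministic
#'   and consistent).
#' @return A `fiems_graph`: list with `nodes` (`id`, `type`, `label`) and
#'   `edges` (`from`, `to`), plus `planted_pathway_id`.
#' @export
simulate_knowledge_graph <- function(config,
                                     library = simulate_compound_library(config)) {
  stopifnot(inherits(config, "fiems_sim_config"))
  if (config$n_pathways < 2) stopf("n_pathways must be >= 2")
  set.seed(derive_seed(config$seed, 5L))

  cmp <- library$compounds
  planted <- library$planted_compound_ids
  others <- setdiff(cmp$compound_id, planted)

  nodes <- data.frame(id = cmp$compound_id, type = "compound",
                      label = cmp$name, stringsAsFactors = FALSE)
  edges <- list()
  rid <- 0L; eid <- 0L; mid <- 0L
  add_node <- function(id, type, label) {
    nodes <<- rbind(nodes, data.frame(id = id, type = type, label = label,
                                      stringsAsFactors = FALSE))
  }
  add_edge <- function(a, b) {
    edges[[length(edges) + 1L]] <<- data.frame(from = a, to = b,
                                               stringsAsFactors = FALSE)
  }

  for (p in seq_len(config$n_pathways)) {
    pid <- sprintf("PTH%03d", p)
    add_node(pid, "pathway", sprintf("pathway %03d", p))
    pool <- if (p == 1L) planted else others
    n_modules <- 2L
    for (m in seq_len(n_modules)) {
      mid <- mid + 1L
      mname <- sprintf("MOD%03d", mid)
      add_node(mname, "module", sprintf("module %03d", mid))
      add_edge(mname, pid)
      for (e in seq_len(2L)) {
        eid <- eid + 1L
        ename <- sprintf("ENZ%03d", eid)
        add_node(ename, "enzyme", sprintf("enzyme %03d", eid))
        add_edge(ename, mname)
        for (r in seq_len(2L)) {
          rid <- rid + 1L
          rname <- sprintf("RXN%03d", rid)
          add_node(rname, "reaction", sprintf("reaction %03d", rid))
          add_edge(rname, ename)
          k <- min(length(pool), sample(2:4, 1))
          for (cpd in sample(pool, k)) add_edge(cpd, rname)
        }
      }
    }
  }
  # Ensure planted-pathway reachability from (at least) 80% of planted
  # compounds: wire any unconnected planted compound to a planted reaction.
  # Unconnected non-planted compounds join a random non-planted reaction, so
  # the default graph has no isolated compounds.
  planted_rxn <- sprintf("RXN%03d", 1L)
  e_df <- do.call(rbind, edges)
  connected <- planted %in% c(e_df$from, e_df$to)
  for (cpd in planted[!connected]) add_edge(cpd, planted_rxn)
  rxn_per_pathway <- rid / config$n_pathways
  other_rxns <- sprintf("RXN%03d", seq(rxn_per_pathway + 1L, rid))
  loose <- setdiff(others, c(e_df$from, e_df$to))
  for (cpd in loose) add_edge(cpd, sample(other_rxns, 1))

  g <- new_fiems_graph(nodes, do.call(rbind, edges))
  g$planted_pathway_id <- "PTH001"

  deg <- table(c(g$edges$from, g$edges$to))
  isolated <- setdiff(g$nodes$id[g$nodes$type == "compound"], names(deg))
  if (length(isolated))
    warnf("%d compound node(s) are disconnected from the graph",
          length(isolated))
  g
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running every generator consistently from one config:
#' design, feature matrix + ground truth, compound library, knowledge graph,
#' and (optionally) per-sample centroided scans.
#'
#' @param config A [sim_config()].
#' @param spectra Also simulate scan lists (default `FALSE`; binning-level
#'   tests and pipelines that start from the matrix do not need them).
#' @return List: `config`, `design`, `matrix`, `truth`, `library`, `graph`,
#'   and `scans` when requested.
#' @export
simulate_dataset <- function(config, spectra = FALSE) {
  lib <- simulate_compound_library(config)
  sim <- simulate_feature_matrix(config)
  graph <- simulate_knowledge_graph(config, lib)
  out <- list(config = config, design = sim$design, matrix = sim$matrix,
              truth = sim$truth, library = lib, graph = graph)
  if (spectra) out$scans <- simulate_spectra(sim, config)
  out
}
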