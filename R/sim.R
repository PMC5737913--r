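#' Configure a synthetic EHR population
#'
#' Builds and validates the configuration for [generate_population()].  The
#' generator emulates the structured output of an NLP pipeline over
#' outpatient notes: per-patient latent comorbid conditions with marginal
#' prevalences and directed co-occurrence links, medications assigned
#' conditionally on conditions (treatment links, plus background "noise"
#' use), drug-class choice driven by comorbidities through a multinomial
#' logit, overdispersed per-patient visit counts, and per-visit recording
#' noise.
#'
#' Conditions are sampled in the order given; a comorbidity link
#' `(parent, child, odds_multiplier)` multiplies the child's prevalence odds
#' when the (already-sampled) parent is present, so links form a directed
#' structure and earlier conditions keep their configured marginals.
#'
#' For a condition whose treatments are mapped to drug classes via
#' `class_map`, a patient with the condition receives a class medication
#' with probability `1 - prod(1 - p)` over those treatments' prescribing
#' probabilities; the class is then drawn from a multinomial logit whose
#' baseline utility is the log of the class's summed prescribing
#' probability, shifted by the configured `(comorbidity, class, log-odds)`
#' effects for comorbidities the patient has; finally one medication within
#' the class is drawn with probability proportional to its prescribing
#' probability.  Treatments not in `class_map` fire independently with their
#' prescribing probabilities.
#'
#' Visit counts are `1 + NegBin(size = visit_count_dispersion,
#' mu = visit_count_mean - 1)`, so every patient has at least one visit and
#' the count is overdispersed (sd > mean) for moderate dispersion, as seen
#' in real outpatient data.  Each latent condition and medication is
#' recorded at each visit independently with probability `recording_prob`.
#'
#' @param n_patients Number of patients (non-negative integer).
#' @param conditions Data frame with columns `condition_id`, `prevalence`
#'   (marginal prevalence in \[0,1\]), or a named numeric vector.
#' @param comorbidity_links Optional data frame with columns `parent`,
#'   `child`, `odds_multiplier` (> 0).
#' @param treatments Optional data frame with columns `medication_id`,
#'   `condition_id`, `prob` (prescribing probability in \[0,1\]).
#' @param noise_meds Optional data frame with columns `medication_id`,
#'   `prob` (background use probability), or a named numeric vector.
#' @param class_map Optional named character vector mapping medication id to
#'   drug-class label.
#' @param class_preference_effects Optional data frame with columns
#'   `comorbidity_id`, `class`, `shift` (log-odds shift).
#' @param visit_count_mean Mean number of visits per patient (>= 1).
#' @param visit_count_dispersion Negative-binomial size parameter for the
#'   shifted visit-count distribution (> 0); smaller is more overdispersed.
#' @param recording_prob Probability in (0, 1\] that a latent concept is
#'   mentioned at any given visit.
#' @param seed Integer master seed.
#'
#' @return An object of class `"sim_config"`.
#' @seealso [generate_population()]
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_patients = 100,
#'   conditions = c(htn = 0.3, dm = 0.2),
#'   treatments = data.frame(medication_id = "hctz", condition_id = "htn",
#'                           prob = 0.7),
#'   seed = 1
#' )
sim_config <- function(n_patients,
                       conditions,
                       comorbidity_links = NULL,
                       treatments = NULL,
                       noise_meds = NULL,
                       class_map = NULL,
                       class_preference_effects = NULL,
                       visit_count_mean = 4,
                       visit_count_dispersion = 0.5,
                       recording_prob = 0.9,
                       seed = 1L) {
  if (is.numeric(conditions) && !is.null(names(conditions))) {
    conditions <- data.frame(condition_id = names(conditions),
                             prevalence = unname(conditions),
                             stringsAsFactors = FALSE)
  }
  if (is.numeric(noise_meds) && !is.null(names(noise_meds))) {
    noise_meds <- data.frame(medication_id = names(noise_meds),
                             prob = unname(noise_meds),
                             stringsAsFactors = FALSE)
  }
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0L) {
    stop_pr("`n_patients` must be a non-negative integer")
  }
  if (!is.data.frame(conditions) ||
      !all(c("condition_id", "prevalence") %in% names(conditions))) {
    stop_pr("`conditions` needs columns condition_id, prevalence")
  }
  if (anyDuplicated(conditions$condition_id)) {
    stop_pr("duplicate condition ids in `conditions`")
  }
  if (any(conditions$prevalence < 0 | conditions$prevalence > 1)) {
    stop_pr("condition prevalences must lie in [0, 1]")
  }
  if (!is.null(comorbidity_links)) {
    stopifnot(all(c("parent", "child", "odds_multiplier") %in%
                    names(comorbidity_links)))
    if (any(comorbidity_links$odds_multiplier <= 0)) {
      stop_pr("comorbidity odds multipliers must be > 0")
    }
    bad <- setdiff(c(comorbidity_links$parent, comorbidity_links$child),
                   conditions$condition_id)
    if (length(bad)) {
      stop_pr("comorbidity link refers to unknown condition(s): ",
              paste(bad, collapse = ", "))
    }
  }
  if (!is.null(treatments)) {
    stopifnot(all(c("medication_id", "condition_id", "prob") %in%
                    names(treatments)))
    if (any(treatments$prob < 0 | treatments$prob > 1)) {
      stop_pr("treatment prescribing probabilities must lie in [0, 1]")
    }
    bad <- setdiff(treatments$condition_id, conditions$condition_id)
    if (length(bad)) {
      stop_pr("treatment refers to unknown condition(s): ",
              paste(bad, collapse = ", "))
    }
  }
  if (!is.null(noise_meds)) {
    stopifnot(all(c("medication_id", "prob") %in% names(noise_meds)))
    if (any(noise_meds$prob < 0 | noise_meds$prob > 1)) {
      stop_pr("noise medication probabilities must lie in [0, 1]")
    }
  }
  if (!is.null(class_preference_effects)) {
    stopifnot(all(c("comorbidity_id", "class", "shift") %in%
                    names(class_preference_effects)))
    if (is.null(class_map)) {
      stop_pr("class_preference_effects given without a class_map")
    }
    bad <- setdiff(class_preference_effects$class, unname(class_map))
    if (length(bad)) {
      stop_pr("class preference effect refers to unknown class(es): ",
              paste(bad, collapse = ", "))
    }
  }
  if (visit_count_mean < 1) stop_pr("`visit_count_mean` must be >= 1")
  if (visit_count_dispersion <= 0) {
    stop_pr("`visit_count_dispersion` must be > 0")
  }
  if (recording_prob <= 0 || recording_prob > 1) {
    stop_pr("`recording_prob` must lie in (0, 1]")
  }
  structure(
    list(
      n_patients = n_patients,
      conditions = conditions,
      comorbidity_links = comorbidity_links,
      treatments = treatments,
      noise_meds = noise_meds,
      class_map = class_map,
      class_preference_effects = class_preference_effects,
      visit_count_mean = visit_count_mean,
      visit_count_dispersion = visit_count_dispersion,
      recording_prob = recording_prob,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("Synthetic EHR configuration\n")
  cat("  patients:       ", x$n_patients, "\n")
  cat("  conditions:     ", nrow(x$conditions), "\n")
  cat("  treatments:     ", if (is.null(x$treatments)) 0 else
    nrow(x$treatments), "\n")
  cat("  noise meds:     ", if (is.null(x$noise_meds)) 0 else
    nrow(x$noise_meds), "\n")
  cat("  visit mean:     ", x$visit_count_mean, "\n")
  cat("  recording prob: ", x$recording_prob, "\n")
  cat("  seed:           ", x$seed, "\n")
  invisible(x)
}

empty_mention_table <- function() {
  structure(
    data.frame(patient_id = integer(), visit_id = integer(),
               kind = character(), concept_id = character(),
               stringsAsFactors = FALSE),
    class = c("mention_table", "data.frame")
  )
}

#' Generate a synthetic EHR population
#'
#' Draws a longitudinal mention table and its ground truth from a
#' [sim_config()].  The mention table is long-format with one row per
#' (patient, visit, concept); the truth set records the treatment links,
#' class-preference effects and comorbidity structure used, so downstream
#' rankings can be scored against what the simulator actually planted.
#'
#' The generator is deterministic given the config (including its seed).
#' One RNG sub-stream per patient is derived from the master seed, and each
#' config block consumes a fixed number of uniforms per patient, so editing
#' one block of the config minimally perturbs the draws for the others.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `mentions` (a `mention_table` data frame
#'   with columns `patient_id`, `visit_id`, `kind`, `concept_id`) and
#'   `truth` (a `truth_set` list with `true_treatments`, `class_effects`,
#'   `comorbidity_links`, `noise_meds`, `class_map`).
#' @export
#' @examples
#' cfg <- sim_config(50, c(htn = 0.4),
#'                   treatments = data.frame(medication_id = "hctz",
#'                                           condition_id = "htn",
#'                                           prob = 0.8),
#'                   seed = 7)
#' pop <- generate_population(cfg)
#' head(pop$mentions)
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_pr("`config` must be a sim_config object")
  }
  truth <- structure(
    list(
      true_treatments = if (is.null(config$treatments)) {
        data.frame(medication_id = character(), condition_id = character(),
                   stringsAsFactors = FALSE)
      } else {
        unique(config$treatments[c("medication_id", "condition_id")])
      },
      class_effects = config$class_preference_effects,
      comorbidity_links = config$comorbidity_links,
      noise_meds = if (is.null(config$noise_meds)) character() else
        config$noise_meds$medication_id,
      class_map = config$class_map
    ),
    class = "truth_set"
  )
  n <- config$n_patients
  if (n == 0L) {
    return(list(mentions = empty_mention_table(), truth = truth))
  }

  conds <- config$conditions
  nc <- nrow(conds)
  cond_ids <- conds$condition_id
  # per-condition list of (parent index, multiplier)
  links <- vector("list", nc)
  if (!is.null(config$comorbidity_links)) {
    cl <- config$comorbidity_links
    for (r in seq_len(nrow(cl))) {
      j <- match(cl$child[r], cond_ids)
      links[[j]] <- rbind(links[[j]],
                          c(match(cl$parent[r], cond_ids),
                            cl$odds_multiplier[r]))
    }
  }

  # Split treatments into class-mapped blocks (grouped per condition, in
  # config order of first appearance) and unmapped rows.
  tr <- config$treatments
  class_map <- config$class_map
  class_blocks <- list()
  unmapped <- NULL
  if (!is.null(tr) && nrow(tr)) {
    mapped <- !is.null(class_map) & tr$medication_id %in% names(class_map)
    unmapped <- tr[!mapped, , drop = FALSE]
    trm <- tr[mapped, , drop = FALSE]
    if (nrow(trm)) {
      for (z in unique(trm$condition_id)) {
        rows <- trm[trm$condition_id == z, , drop = FALSE]
        rows$class <- unname(class_map[rows$medication_id])
        classes <- sort(unique(rows$class))
        base_w <- vapply(classes,
                         function(cc) sum(rows$prob[rows$class == cc]),
                         numeric(1))
        class_blocks[[z]] <- list(
          cond_idx = match(z, cond_ids),
          rows = rows,
          classes = classes,
          base_util = log(pmax(base_w, .Machine$double.xmin)),
          p_any = 1 - prod(1 - rows$prob)
        )
      }
    }
  }
  # class-preference effect lookup: effects[[class]] = named shifts
  pref <- config$class_preference_effects
  eff_for <- function(classes, present_conds) {
    u <- setNames(numeric(length(classes)), classes)
    if (!is.null(pref) && nrow(pref)) {
      sel <- pref$comorbidity_id %in% present_conds & pref$class %in% classes
      if (any(sel)) {
        for (r in which(sel)) u[pref$class[r]] <- u[pref$class[r]] +
            pref$shift[r]
      }
    }
    u
  }
  noise <- config$noise_meds
  disp <- config$visit_count_dispersion
  vmu <- config$visit_count_mean - 1
  rp <- config$recording_prob

  pat_seeds <- with_seed(config$seed, sample.int(2147483646L, n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(pat_seeds[i])
    # latent conditions, sequential with directed comorbidity multipliers
    u <- runif(nc)
    present <- logical(nc)
    for (j in seq_len(nc)) {
      p <- conds$prevalence[j]
      if (p <= 0) { present[j] <- FALSE; next }
      if (p >= 1) { present[j] <- TRUE; next }
      odds <- p / (1 - p)
      lj <- links[[j]]
      if (!is.null(lj)) {
        for (r in seq_len(nrow(lj))) {
          if (present[lj[r, 1]]) odds <- odds * lj[r, 2]
        }
      }
      present[j] <- u[j] < odds / (1 + odds)
    }
    present_conds <- cond_ids[present]
    meds <- character(0)
    # class-mapped treatment blocks: 3 uniforms each, always consumed
    for (blk in class_blocks) {
      u3 <- runif(3)
      if (present[blk$cond_idx] && u3[1] < blk$p_any) {
        util <- blk$base_util + eff_for(blk$classes, present_conds)
        pr <- exp(util - max(util))
        cs <- cumsum(pr / sum(pr))
        cs[length(cs)] <- 1
        cls <- blk$classes[findInterval(u3[2], cs, left.open = TRUE) + 1L]
        rows <- blk$rows[blk$rows$class == cls, , drop = FALSE]
        cw <- cumsum(rows$prob / sum(rows$prob))
        cw[length(cw)] <- 1
        med <- rows$medication_id[findInterval(u3[3], cw,
                                               left.open = TRUE) + 1L]
        meds <- c(meds, med)
      }
    }
    # unmapped treatments: one uniform per row, always consumed
    if (!is.null(unmapped) && nrow(unmapped)) {
      ut <- runif(nrow(unmapped))
      hit <- ut < unmapped$prob &
        present[match(unmapped$condition_id, cond_ids)]
      meds <- c(meds, unmapped$medication_id[hit])
    }
    # background noise medications
    if (!is.null(noise) && nrow(noise)) {
      un <- runif(nrow(noise))
      meds <- c(meds, noise$medication_id[un < noise$prob])
    }
    meds <- unique(meds)
    # visit count: exactly one uniform
    nv <- 1L + qnbinom(runif(1), size = disp, mu = vmu)
    # recording noise
    concepts <- c(present_conds, meds)
    kinds <- c(rep("condition", length(present_conds)),
               rep("medication", length(meds)))
    if (length(concepts)) {
      rec <- matrix(runif(nv * length(concepts)) < rp, nrow = nv)
      idx <- which(rec, arr.ind = TRUE)
      if (nrow(idx)) {
        out[[i]] <- data.frame(
          patient_id = i,
          visit_id = idx[, 1],
          kind = kinds[idx[, 2]],
          concept_id = concepts[idx[, 2]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  keep <- !vapply(out, is.null, logical(1))
  mentions <- if (any(keep)) {
    m <- do.call(rbind, out[keep])
    m <- m[order(m$patient_id, m$visit_id, m$kind, m$concept_id), ]
    rownames(m) <- NULL
    structure(m, class = c("mention_table", "data.frame"))
  } else {
    empty_mention_table()
  }
  list(mentions = mentions, truth = truth)
}

#' Medications linked to a condition only through comorbidity
#'
#' Given a simulator truth set and an index condition, returns the
#' medications that do not treat the index condition but do treat some
#' condition connected to it by a comorbidity link (in either direction) —
#' the drugs a naive marginal analysis is expected to flag spuriously.
#'
#' @param truth A `truth_set` from [generate_population()].
#' @param condition Index condition id.
#' @return Character vector of medication ids.
#' @export
confounder_meds <- function(truth, condition) {
  if (!inherits(truth, "truth_set")) stop_pr("`truth` must be a truth_set")
  tt <- truth$true_treatments
  cl <- truth$comorbidity_links
  if (is.null(cl) || !nrow(tt)) return(character(0))
  comorb <- unique(c(cl$child[cl$parent == condition],
                     cl$parent[cl$child == condition]))
  treats_index <- unique(tt$medication_id[tt$condition_id == condition])
  cand <- unique(tt$medication_id[tt$condition_id %in% comorb])
  setdiff(cand, treats_index)
}

#' True treatments of a condition in a truth set
#'
#' @param truth A `truth_set` from [generate_population()].
#' @param condition Index condition id.
#' @return Character vector of medication ids planted as treatments of
#'   `condition`.
#' @export
true_treatment_meds <- function(truth, condition) {
  if (!inherits(truth, "truth_set")) stop_pr("`truth` must be a truth_set")
  tt <- truth$true_treatments
  unique(tt$medication_id[tt$condition_id == condition])
}

#' Summary statistics for a case/control mention table
#'
#' Tabulates, separately for cases (patients with at least one mention of
#' the index condition) and controls, the patient count, mean (sd) visits
#' per patient, mean (sd) unique conditions and medications per patient
#' over all visits, and the same per-visit quantities at one selected visit
#' per patient (for cases, a random visit mentioning the index condition;
#' for controls, a random visit), mirroring the cohort construction used by
#' [build_case_control()].
#'
#' @param mentions A mention table.
#' @param index_condition Condition id defining cases.
#' @param seed Integer seed for the visit selection.
#' @param strict If `TRUE`, error when the index condition is absent from
#'   the table; the default treats an absent condition as zero cases.
#' @return A data frame with one row per statistic and columns `cases`,
#'   `controls`.
#' @export
summarize_mentions <- function(mentions, index_condition, seed = 1L,
                               strict = FALSE) {
  mentions <- as_mention_table(mentions)
  if (!nrow(mentions)) stop_pr("`mentions` is empty")
  is_index <- mentions$kind == "condition" &
    mentions$concept_id == index_condition
  if (strict && !any(is_index)) {
    stop_pr("index condition '", index_condition, "' not found in mentions")
  }
  patients <- sort(unique(mentions$patient_id))
  case_ids <- sort(unique(mentions$patient_id[is_index]))
  grp <- ifelse(patients %in% case_ids, "cases", "controls")

  visits_per <- tapply(mentions$visit_id, mentions$patient_id,
                       function(v) length(unique(v)))
  key <- paste(mentions$patient_id, mentions$kind)
  uniq_per <- tapply(mentions$concept_id, key,
                     function(x) length(unique(x)))
  get_counts <- function(kind) {
    v <- uniq_per[paste(patients, kind)]
    v[is.na(v)] <- 0
    v
  }
  sel <- select_visits(mentions, index_condition, seed)
  sel_key <- paste(mentions$patient_id, mentions$visit_id)
  at_sel <- mentions[sel_key %in% paste(sel$patient_id, sel$visit_id), ]
  key2 <- paste(at_sel$patient_id, at_sel$kind)
  uniq_sel <- tapply(at_sel$concept_id, key2, function(x) length(unique(x)))
  get_sel <- function(kind) {
    v <- uniq_sel[paste(patients, kind)]
    v[is.na(v)] <- 0
    v
  }
  stat_rows <- list(
    "Number of patients" = function(g) as.character(sum(grp == g)),
    "Mean number of visits per patient (sd)" =
      function(g) msd(visits_per[as.character(patients[grp == g])]),
    "Unique conditions per patient, all visits (sd)" =
      function(g) msd(get_counts("condition")[grp == g]),
    "Unique medications per patient, all visits (sd)" =
      function(g) msd(get_counts("medication")[grp == g]),
    "Unique conditions per patient, selected visit (sd)" =
      function(g) msd(get_sel("condition")[grp == g]),
    "Unique medications per patient, selected visit (sd)" =
      function(g) msd(get_sel("medication")[grp == g])
  )
  out <- data.frame(
    statistic = names(stat_rows),
    cases = vapply(stat_rows, function(f) f("cases"), character(1)),
    controls = vapply(stat_rows, function(f) f("controls"), character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out
}

msd <- function(x) {
  if (!length(x)) return("NA")
  sprintf("%.1f (%.1f)", mean(x), if (length(x) > 1) sd(x) else 0)
}

as_mention_table <- function(mentions) {
  req <- c("patient_id", "visit_id", "kind", "concept_id")
  if (!is.data.frame(mentions) || !all(req %in% names(mentions))) {
    stop_pr("`mentions` needs columns ", paste(req, collapse = ", "))
  }
  mentions
}
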