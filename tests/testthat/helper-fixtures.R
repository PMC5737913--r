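# Shared fixtures, generated in code.

# Four hand-listed patients; htn is the index condition.  Each case has
# exactly one visit mentioning htn, so cohort construction is fully
# deterministic whatever the seed.
fixture_mentions <- function() {
  rows <- list(
    c(1, 1, "condition", "htn"),
    c(1, 1, "medication", "hctz"),
    c(1, 2, "condition", "dm"),
    c(2, 1, "condition", "htn"),
    c(2, 1, "condition", "dm"),
    c(2, 1, "medication", "metformin"),
    c(3, 1, "condition", "dm"),
    c(3, 1, "medication", "metformin"),
    c(4, 1, "medication", "vitamin")
  )
  m <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(m) <- c("patient_id", "visit_id", "kind", "concept_id")
  m$patient_id <- as.integer(m$patient_id)
  m$visit_id <- as.integer(m$visit_id)
  m
}

# The confounded-study configuration: one index condition (htn), three
# comorbidities linked to it, five strongly-prescribed true treatments,
# three confounder-only medications (treating the comorbidities), and 50
# background-noise medications.
confounded_config <- function(n_patients = 20000, seed = 1) {
  noise_ids <- sprintf("noise%02d", 1:50)
  sim_config(
    n_patients = n_patients,
    conditions = data.frame(
      condition_id = c("htn", "ckd", "afib", "hyperlip"),
      prevalence = c(0.30, 0.12, 0.10, 0.15)
    ),
    comorbidity_links = data.frame(
      parent = "htn",
      child = c("ckd", "afib", "hyperlip"),
      odds_multiplier = c(4, 4, 4)
    ),
    treatments = data.frame(
      medication_id = c("hctz", "lisinopril", "amlodipine", "losartan",
                        "atenolol", "epoetin", "warfarin", "statin"),
      condition_id = c(rep("htn", 5), "ckd", "afib", "hyperlip"),
      prob = c(0.85, 0.80, 0.75, 0.70, 0.60, 0.80, 0.80, 0.80)
    ),
    noise_meds = data.frame(
      medication_id = noise_ids,
      prob = rep(c(0.02, 0.03, 0.05), length.out = 50)
    ),
    visit_count_mean = 4,
    recording_prob = 0.9,
    seed = seed
  )
}

# Two-class preference configuration: asthma shifts the A2-blocker
# log-odds by +1 relative to the beta blocker.
preference_config <- function(n_patients = 10000, shift = 1.0, seed = 1) {
  sim_config(
    n_patients = n_patients,
    conditions = data.frame(condition_id = c("htn", "asthma", "dm"),
                            prevalence = c(0.5, 0.3, 0.25)),
    treatments = data.frame(
      medication_id = c("valsartan", "atenolol"),
      condition_id = "htn",
      prob = c(0.45, 0.45)
    ),
    class_map = c(valsartan = "A2Blocker", atenolol = "Beta_Blocker"),
    class_preference_effects = data.frame(
      comorbidity_id = "asthma", class = "A2Blocker", shift = shift
    ),
    visit_count_mean = 3,
    recording_prob = 0.95,
    seed = seed
  )
}

# Hand-assembled class-choice dataset for unit tests of the multiclass
# screen and fit, bypassing the builder.
manual_class_choice <- function(x, class, classes = sort(unique(class))) {
  x <- Matrix::Matrix(x, sparse = TRUE)
  structure(
    list(
      x = x,
      class = factor(class, levels = classes),
      patient_id = seq_len(nrow(x)),
      selected_visit = rep(1L, nrow(x)),
      columns = data.frame(concept_id = colnames(x), kind = "condition",
                           stringsAsFactors = FALSE),
      classes = classes,
      index_condition = "index",
      seed = NA_integer_
    ),
    class = "class_choice"
  )
}
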