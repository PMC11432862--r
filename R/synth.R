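#' Specification of a synthetic ED-visit cohort
#'
#' Describes the statistical structure of a synthetic emergency-department
#' cohort: a rare binary 72-hour return-visit-admission (RVA) outcome, latent
#' risk-tiered cluster structure that shifts vital-sign/lab distributions and
#' clinical-order intensities, monthly visit seasonality, demographic mix, and
#' missing-completely-at-random lab missingness. The defaults emulate an urban
#' adult treat-and-release ED population with ~0.8% outcome prevalence.
#'
#' @param n_visits number of index ED visits to generate.
#' @param outcome_rate marginal RVA prevalence, in (0,1). Default 0.008.
#' @param n_latent_clusters number of planted risk tiers (>= 2). Default 2.
#' @param cluster_risk_ratio outcome-rate ratio between the highest- and
#'   lowest-risk tiers. Default 4.5. `1.0` plants no cluster-outcome effect.
#' @param n_months number of calendar months spanned. Default 12.
#' @param missing_rate per-analyte probability that a lab panel is absent
#'   from a visit (MCAR). Default 0.15.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param subgroup_mix named list of per-category proportion vectors for
#'   `race`, `insurance`, `sex`, `language`; each must sum to 1 within 1e-9.
#' @param disease_flag_rates named prevalences for the heart failure, COPD,
#'   UTI and pneumonia index-diagnosis flags.
#' @param cluster_separation per-feature shift, in within-cluster standard
#'   deviations, applied to the signal vitals/labs between adjacent risk
#'   tiers. Default 2.5 (well-separated phenotypes).
#' @param couple_disease_flags if TRUE, disease-flag prevalence is doubled in
#'   the highest-risk tier (used by subgroup-analysis simulations); default
#'   FALSE (flags independent of the planted structure).
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_visits,
                        outcome_rate = 0.008,
                        n_latent_clusters = 2L,
                        cluster_risk_ratio = 4.5,
                        n_months = 12L,
                        missing_rate = 0.15,
                        seed = 1L,
                        subgroup_mix = NULL,
                        disease_flag_rates = NULL,
                        cluster_separation = 2.5,
                        couple_disease_flags = FALSE) {
  if (!is_count(n_visits) || n_visits < 1) stopf("n_visits must be a positive integer")
  if (!is_prob(outcome_rate)) stopf("outcome_rate must be in (0,1)")
  if (!is_count(n_latent_clusters) || n_latent_clusters < 2)
    stopf("n_latent_clusters must be an integer >= 2")
  if (!is.numeric(cluster_risk_ratio) || cluster_risk_ratio <= 0)
    stopf("cluster_risk_ratio must be positive")
  if (!is_count(n_months) || n_months < 1) stopf("n_months must be a positive integer")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must be in [0,1)")

  if (is.null(subgroup_mix)) subgroup_mix <- default_subgroup_mix()
  for (nm in names(subgroup_mix)) {
    p <- subgroup_mix[[nm]]
    if (abs(sum(p) - 1) > 1e-9)
      stopf("subgroup_mix$%s proportions must sum to 1 (got %.12f)", nm, sum(p))
    if (any(p < 0)) stopf("subgroup_mix$%s has negative proportions", nm)
  }
  if (is.null(disease_flag_rates))
    disease_flag_rates <- c(hf = 0.04, copd = 0.05, uti = 0.06, pneumonia = 0.03)

  rates <- cluster_outcome_rates(outcome_rate, n_latent_clusters, cluster_risk_ratio)
  if (any(rates >= 1) || any(rates <= 0))
    stopf("outcome_rate x cluster_risk_ratio yields a per-cluster rate outside (0,1)")

  structure(list(
    n_visits = as.integer(n_visits),
    outcome_rate = outcome_rate,
    n_latent_clusters = as.integer(n_latent_clusters),
    cluster_risk_ratio = cluster_risk_ratio,
    n_months = as.integer(n_months),
    missing_rate = missing_rate,
    seed = as.integer(seed),
    subgroup_mix = subgroup_mix,
    disease_flag_rates = disease_flag_rates,
    cluster_separation = cluster_separation,
    couple_disease_flags = isTRUE(couple_disease_flags),
    cluster_rates = rates
  ), class = "cohort_spec")
}

# demographic mix of the emulated development population
default_subgroup_mix <- function() {
  race <- c(white = 25358, black = 13288, other = 14630, asian = 4715,
            unknown = 4163)
  ins <- c(commercial = 29182, medicaid = 14992, medicare = 12344,
           self_pay = 5569)
  list(
    race = race / sum(race),
    insurance = ins / sum(ins),
    sex = c(female = 0.5622, male = 0.4378),
    language = c(english = 0.8693, other = 0.1307)
  )
}

# per-tier outcome rates: geometric ladder from lowest to highest risk with
# max/min = RR, scaled so the mixture over equal tier proportions matches the
# marginal prevalence
cluster_outcome_rates <- function(outcome_rate, k, rr) {
  ladder <- rr^((seq_len(k) - 1) / (k - 1))
  outcome_rate * ladder / mean(ladder)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d visits, %d months, prevalence %.3f%%, %d latent tiers (RR %.2f), seed %d\n",
    x$n_visits, x$n_months, 100 * x$outcome_rate, x$n_latent_clusters,
    x$cluster_risk_ratio, x$seed))
  invisible(x)
}

# feature model shared by the generator and documented in the vignette:
# per-sign population mean/sd, measured repeatedly during the stay
vital_signs <- function() {
  list(
    temp      = c(mean = 37.0, sd_b = 0.45, sd_w = 0.20),
    pulse     = c(mean = 84,   sd_b = 13,   sd_w = 5),
    sbp       = c(mean = 128,  sd_b = 17,   sd_w = 7),
    resp_rate = c(mean = 17,   sd_b = 2.6,  sd_w = 1.2),
    spo2      = c(mean = 97.3, sd_b = 1.6,  sd_w = 0.7)
  )
}

lab_analytes <- function() {
  list(
    wbc        = c(mean = 8.2,  sd = 2.8),
    hgb        = c(mean = 13.4, sd = 1.7),
    sodium     = c(mean = 139,  sd = 3.2),
    creatinine = c(mean = 1.0,  sd = 0.35),
    lactate    = c(mean = 1.4,  sd = 0.6),
    basophil   = c(mean = 0.04, sd = 0.02)
  )
}

order_vocabulary <- function() {
  c(cbc = 0.9, bmp = 0.8, blood_culture = 0.12, urinalysis = 0.45,
    iv_fluids = 0.6, opiate = 0.25, antibiotic = 0.35,
    patient_navigator = 0.05, ecg = 0.5, troponin = 0.3)
}

# vitals/labs/orders whose distribution is shifted by the latent risk tier;
# sign gives the direction of the shift for higher-risk tiers
signal_features <- function() {
  list(
    vitals = c(pulse = +1, sbp = -1, resp_rate = +1),
    labs = c(wbc = +1, lactate = +1),
    orders = c(blood_culture = 1, iv_fluids = 1, patient_navigator = 1)
  )
}

comorbidity_panel <- function() {
  # van-Walraven-style weights over a small condition panel
  c(chf = 7, renal = 5, liver = 11, dm = 1, cancer = 12, htn = -1)
}

comorbidity_prevalence <- function() {
  c(chf = 0.06, renal = 0.05, liver = 0.02, dm = 0.12, cancer = 0.03,
    htn = 0.28)
}

diagnosis_code_pool <- function() {
  c("R07.9", "R10.9", "N39.0", "J18.9", "I50.9", "J44.1", "A41.9",
    "M54.5", "R51.9", "S61.409A", "K52.9", "J06.9")
}

#' Generate a synthetic ED-visit cohort
#'
#' Draws a visit table with the structure described by a [cohort_spec()]:
#' latent risk-tier membership drives both the feature distributions
#' (Gaussian shifts on a subset of vitals/labs, Poisson rate shifts on order
#' counts, higher acuity/LOS) and the per-tier outcome rate, so that the
#' outcome-rate ratio between the highest and lowest tiers matches
#' `spec$cluster_risk_ratio` in expectation. Monthly visit counts follow a
#' sinusoidal seasonality. On top of the tier rates, a weak within-tier
#' logistic gradient on three designated features (pulse level, lactate,
#' ED length of stay) gives supervised feature selection signal beyond tier
#' membership; its mean effect on the logit is offset so the marginal
#' prevalence is preserved.
#'
#' The emitted cohort is already eligibility-filtered (treat-and-release
#' dispositions only, `prior_year_visits <= 5`, no planned-return diagnosis
#' codes); [apply_eligibility_filters()] is provided for external tables.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `visit_table`, one row per visit, with
#'   list-columns `vitals` (named list of per-sign measurement vectors,
#'   always nonempty), `labs` (named list of per-analyte value vectors,
#'   possibly empty under missingness) and `order_counts` (named count
#'   vector), plus demographics, operational variables, comorbidity flags
#'   (`cmb_*`), `elixhauser_score`, disease flags (`flag_*`),
#'   `diagnosis_code`, the binary `outcome`, and the generator-truth
#'   `latent_cluster` (1 = lowest risk; never shown to models).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_visits
  k <- spec$n_latent_clusters
  sep <- spec$cluster_separation

  with_seed(spec$seed, {
    # sinusoidal monthly volume
    m_idx <- seq_len(spec$n_months)
    m_w <- 1 + 0.3 * sin(2 * pi * (m_idx - 1) / spec$n_months)
    month <- sample(m_idx, n, replace = TRUE, prob = m_w / sum(m_w))

    cluster <- sample.int(k, n, replace = TRUE)
    tier <- (cluster - 1) / (k - 1)   # 0 = lowest risk, 1 = highest

    mix <- spec$subgroup_mix
    race <- sample(names(mix$race), n, TRUE, prob = mix$race)
    insurance <- sample(names(mix$insurance), n, TRUE, prob = mix$insurance)
    sex <- sample(names(mix$sex), n, TRUE, prob = mix$sex)
    language <- sample(names(mix$language), n, TRUE, prob = mix$language)
    age <- pmin(pmax(round(stats::rnorm(n, 47.7, 18.55)), 18), 100)

    sig <- signal_features()

    # vitals: per-visit latent level (between-visit sd, tier-shifted for
    # signal signs) measured 1+Pois(2) times with within-stay noise
    vs <- vital_signs()
    vitals <- vector("list", n)
    vital_level <- matrix(0, n, length(vs), dimnames = list(NULL, names(vs)))
    n_meas <- 1L + stats::rpois(n, 2)
    for (s in names(vs)) {
      p <- vs[[s]]
      shift <- if (s %in% names(sig$vitals)) sig$vitals[[s]] * sep * p[["sd_b"]] else 0
      vital_level[, s] <- stats::rnorm(n, p[["mean"]] + shift * tier, p[["sd_b"]])
    }
    for (i in seq_len(n)) {
      vitals[[i]] <- lapply(stats::setNames(names(vs), names(vs)), function(s)
        round(stats::rnorm(n_meas[i], vital_level[i, s], vs[[s]][["sd_w"]]), 1))
    }

    la <- lab_analytes()
    labs <- vector("list", n)
    lab_present <- matrix(stats::runif(n * length(la)) >= spec$missing_rate,
                          n, length(la), dimnames = list(NULL, names(la)))
    lab_level <- matrix(0, n, length(la), dimnames = list(NULL, names(la)))
    for (a in names(la)) {
      p <- la[[a]]
      shift <- if (a %in% names(sig$labs)) sig$labs[[a]] * sep * p[["sd"]] else 0
      lab_level[, a] <- stats::rnorm(n, p[["mean"]] + shift * tier, p[["sd"]])
    }
    n_lab <- 1L + stats::rpois(n, 0.6)
    for (i in seq_len(n)) {
      present <- names(la)[lab_present[i, ]]
      labs[[i]] <- lapply(stats::setNames(present, present), function(a)
        round(stats::rnorm(n_lab[i], lab_level[i, a], la[[a]][["sd"]] * 0.2), 2))
    }

    # orders: Poisson counts, rate doubled in the top tier for signal orders
    voc <- order_vocabulary()
    order_counts <- vector("list", n)
    cnt <- matrix(0L, n, length(voc), dimnames = list(NULL, names(voc)))
    for (o in names(voc)) {
      mult <- if (o %in% names(sig$orders)) 1 + tier else 1
      cnt[, o] <- stats::rpois(n, voc[[o]] * mult)
    }
    for (i in seq_len(n)) {
      nz <- cnt[i, ][cnt[i, ] > 0L]
      order_counts[[i]] <- nz
    }
    imaging_count <- stats::rpois(n, 0.8 * (1 + 0.5 * tier))

    cp <- comorbidity_prevalence()
    cmb <- sapply(names(cp), function(cc)
      as.integer(stats::runif(n) < cp[[cc]]))
    colnames(cmb) <- paste0("cmb_", names(cp))
    elix <- as.integer(cmb %*% comorbidity_panel())

    # acuity and utilization: higher-risk tier is sicker on average
    esi_base <- rbind(
      c(0.02, 0.18, 0.45, 0.28, 0.07),  # low tier
      c(0.05, 0.30, 0.45, 0.17, 0.03)   # high tier
    )
    esi <- integer(n)
    for (i in seq_len(n)) {
      p <- (1 - tier[i]) * esi_base[1, ] + tier[i] * esi_base[2, ]
      esi[i] <- sample.int(5L, 1L, prob = p)
    }
    ed_los <- round(stats::rlnorm(n, log(4.0) + 0.25 * tier, 0.45), 2)
    prior_year_visits <- pmin(stats::rpois(n, 0.9), 5L)
    disposition <- sample(c("home", "facility", "ama"), n, TRUE,
                          prob = c(0.90, 0.06, 0.04))

    dfr <- spec$disease_flag_rates
    flg <- sapply(names(dfr), function(d) {
      r <- dfr[[d]]
      if (spec$couple_disease_flags) r <- r * (1 + tier)
      as.integer(stats::runif(n) < pmin(r, 0.99))
    })
    colnames(flg) <- paste0("flag_", names(dfr))

    diagnosis_code <- sample(diagnosis_code_pool(), n, TRUE)

    # outcome: per-tier base rate plus a weak logistic gradient on visit
    # features that carry risk signal beyond tier membership: comorbidity
    # burden, prior utilization, renal function, and care-team orders
    # (navigator consults, opiates) that flag clinician-perceived
    # vulnerability; the log-MGF offset keeps the marginal prevalence at
    # its nominal value
    b <- 0.4
    # navigator orders are tier-coupled, so use their residual against the
    # tier-expected rate; otherwise the gradient would bleed into the
    # between-tier risk ratio
    pn_resid <- cnt[, "patient_navigator"] -
      voc[["patient_navigator"]] * (1 + tier)
    u <- cbind(as.vector(scale(elix)),
               as.vector(scale(prior_year_visits)),
               as.vector(scale(lab_level[, "creatinine"])),
               as.vector(scale(pn_resid)),
               as.vector(scale(cnt[, "opiate"])))
    g <- b * rowSums(u)
    # empirical tilt correction (the gradient features are skewed, so a
    # normal-theory b^2/2 offset would leave the prevalence biased upward)
    eta <- stats::qlogis(spec$cluster_rates[cluster]) - log(mean(exp(g))) + g
    outcome <- as.integer(stats::runif(n) < stats::plogis(eta))

    tab <- data.frame(
      visit_id = sprintf("V%06d", seq_len(n)),
      patient_id = sprintf("P%06d", sample.int(max(1L, as.integer(n * 0.95)),
                                               n, replace = TRUE)),
      month = month, age = age, sex = sex, race = race,
      insurance = insurance, language = language,
      stringsAsFactors = FALSE
    )
    tab$vitals <- vitals
    tab$labs <- labs
    tab$order_counts <- order_counts
    tab$imaging_count <- as.integer(imaging_count)
    tab <- cbind(tab, as.data.frame(cmb))
    tab$elixhauser_score <- elix
    tab$esi <- esi
    tab$ed_los <- ed_los
    tab$prior_year_visits <- as.integer(prior_year_visits)
    tab$disposition <- disposition
    tab <- cbind(tab, as.data.frame(flg))
    tab$diagnosis_code <- diagnosis_code
    tab$outcome <- outcome
    tab$latent_cluster <- cluster
    class(tab) <- c("visit_table", "data.frame")
    attr(tab, "cohort_spec") <- spec
    tab
  })
}

#' @export
print.visit_table <- function(x, ...) {
  cat(sprintf("visit_table: %d visits, %d months, %d RVA outcomes (%.2f%%)\n",
              nrow(x), length(unique(x$month)), sum(x$outcome),
              100 * mean(x$outcome)))
  invisible(x)
}

#' Apply cohort eligibility filters to a visit table
#'
#' Retains treat-and-release index visits only: drops visits whose diagnosis
#' code is on the planned-return exclusion list (e.g. suture removal, wound
#' check), visits by ED high-utilizers (more than five ED visits in the prior
#' year), and visits with a disposition outside home / non-acute facility /
#' left against medical advice. Rules are applied in that order and the
#' per-rule removal counts are attached as `attr(, "removal_log")`.
#'
#' @param table a `visit_table` (or any data.frame with `diagnosis_code`,
#'   `prior_year_visits` and `disposition` columns).
#' @param excluded_codes character vector of planned-return diagnosis codes.
#' @return the filtered table, with a named integer `removal_log` attribute
#'   (`planned_return`, `high_utilizer`, `disposition`).
#' @export
apply_eligibility_filters <- function(table, excluded_codes = character()) {
  need <- c("diagnosis_code", "prior_year_visits", "disposition")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("table lacks column(s): %s", paste(miss, collapse = ", "))

  log <- c(planned_return = 0L, high_utilizer = 0L, disposition = 0L)
  keep <- !(table$diagnosis_code %in% excluded_codes)
  log[["planned_return"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  keep <- table$prior_year_visits <= 5
  log[["high_utilizer"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  keep <- tolower(table$disposition) %in% c("home", "facility", "ama")
  log[["disposition"]] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  attr(table, "removal_log") <- log
  table
}
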