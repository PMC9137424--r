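#' Feature-channel listener parameters
#'
#' The simulated listener transmits each articulatory feature (voicing,
#' manner, place) independently with a condition-specific probability.
#' Probabilities live on the logit scale as
#' `baseline + condition effect + group offset + subject intercept`.
#' When all three features are transmitted the token is fully resolved and
#' the response equals the target; otherwise the response is drawn
#' uniformly from the consonants that match the target on every
#' transmitted feature. (Full resolution is needed because /h/ and the
#' postalveolar fricative share all three feature values, so features
#' alone cannot separate them.)
#'
#' @param baseline Named logits `c(voicing=, manner=, place=)` for the
#'   reference condition (no mask, AO).
#' @param effects Tibble with columns `mask`, `modality`, `feature`,
#'   `dlogit`: additive condition effects. Missing combinations default
#'   to 0.
#' @param group_offsets Named logit offsets per group.
#' @param subject_sd SD of the per-subject random intercept (logit scale).
#' @return A `masksim_listener` object.
#' @export
listener_params <- function(baseline = c(voicing = qlogis(0.95),
                                         manner = qlogis(0.90),
                                         place = qlogis(0.85)),
                            effects = default_condition_effects(),
                            group_offsets = c(CNH = 0, CHL = -0.8, ANH = 0.25),
                            subject_sd = 0.4) {
  stopifnot(all(feature_names() %in% names(baseline)), subject_sd >= 0)
  effects <- as_tibble(effects)
  stopifnot(all(c("mask", "modality", "feature", "dlogit") %in% names(effects)))
  structure(list(baseline = baseline, effects = effects,
                 group_offsets = group_offsets, subject_sd = subject_sd),
            class = "masksim_listener")
}

#' Default condition effects for the listener model
#'
#' A qualitative preset mirroring the expected ordering of mask effects:
#' auditory-only damage follows the high-frequency attenuation ranking
#' (hospital least, fabric most) and loads most on place; audiovisually,
#' conditions with a visible mouth (no mask and the transparent masks) gain
#' a large place bonus, which opaque masks remove; visual-only transmits
#' place far better than voicing or manner.
#'
#' @return A tibble with `mask`, `modality`, `feature`, `dlogit`.
#' @export
default_condition_effects <- function() {
  ao <- tidyr::expand_grid(
    mask = mask_levels(), modality = "AO", feature = feature_names())
  ao_mask <- c(none = 0, hospital = -0.35, communicator = -0.85,
               clearmask = -0.95, fabric = -1.25)
  ao$dlogit <- ao_mask[ao$mask] + ifelse(ao$feature == "place", -0.45, 0) *
    (ao$mask != "none")
  av <- ao
  av$modality <- "AV"
  mouth_visible <- c(none = TRUE, hospital = FALSE, fabric = FALSE,
                     communicator = TRUE, clearmask = TRUE)
  av$dlogit <- av$dlogit + 0.5 +
    ifelse(mouth_visible[av$mask] & av$feature == "place", 1.3, 0)
  vo <- tibble(mask = "none", modality = "VO", feature = feature_names(),
               dlogit = c(-3.2, -3.0, -0.8))  # rel. baseline: place survives
  bind_rows(ao, av, vo)
}

#' Resolve per-feature transmission probabilities for a condition
#'
#' @param params A [listener_params()].
#' @param mask,modality,group Condition labels.
#' @param subject_effect Subject random intercept (logit scale).
#' @return Named probability vector `c(voicing=, manner=, place=)`.
#' @export
feature_probs <- function(params, mask, modality, group = "CNH",
                          subject_effect = 0) {
  stopifnot(inherits(params, "masksim_listener"))
  eff <- params$effects
  sel <- eff$mask == mask & eff$modality == modality
  d <- setNames(rep(0, 3), feature_names())
  if (any(sel)) {
    got <- setNames(eff$dlogit[sel], eff$feature[sel])
    d[names(got)] <- got
  }
  g <- params$group_offsets[[group]] %||% 0
  plogis(params$baseline[feature_names()] + d[feature_names()] + g + subject_effect)
}

# candidate sets: for each target and transmitted-feature pattern, the
# consonants matching the target on every transmitted feature
candidate_sets <- function(scheme = feature_scheme()) {
  cons <- scheme$consonant
  lapply(setNames(cons, cons), function(t) {
    trow <- scheme[scheme$consonant == t, ]
    lapply(0:7, function(pat) {
      tv <- bitwAnd(pat, 1L) > 0
      tm <- bitwAnd(pat, 2L) > 0
      tp <- bitwAnd(pat, 4L) > 0
      if (tv && tm && tp) return(t)  # fully resolved
      keep <- rep(TRUE, nrow(scheme))
      if (tv) keep <- keep & scheme$voicing == trow$voicing
      if (tm) keep <- keep & scheme$manner == trow$manner
      if (tp) keep <- keep & scheme$place == trow$place
      cons[keep]
    })
  })
}

#' Simulate listener responses
#'
#' Draws one response per target under the feature-channel model. Each
#' feature is transmitted independently with its probability; the response
#' is the target if all three features are transmitted, else a uniform
#' draw from the consonants consistent with the transmitted features.
#' Operates on the current RNG state (wrap in [withr::with_seed()] or seed
#' upstream for reproducibility).
#'
#' @param targets Character vector of target consonants.
#' @param probs Either a named probability vector (`voicing`, `manner`,
#'   `place`) applied to all trials, or an `n x 3` matrix with those
#'   columns for per-trial probabilities.
#' @return Character vector of responses.
#' @export
simulate_listener <- function(targets, probs) {
  n <- length(targets)
  if (is.null(dim(probs))) {
    probs <- matrix(rep(probs[feature_names()], each = n), nrow = n,
                    dimnames = list(NULL, feature_names()))
  }
  stopifnot(nrow(probs) == n)
  sets <- candidate_sets()
  transmitted <- matrix(runif(3 * n), nrow = n) < probs
  pat <- transmitted[, "voicing"] * 1L + transmitted[, "manner"] * 2L +
    transmitted[, "place"] * 4L
  vapply(seq_len(n), function(i) {
    cand <- sets[[targets[i]]][[pat[i] + 1L]]
    if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
  }, character(1))
}

#' Expected rates of the feature-channel listener by exhaustive enumeration
#'
#' Enumerates targets (uniform) and transmission patterns to compute the
#' exact expected accuracy and per-feature transmission of the generative
#' listener model at the given probabilities.
#'
#' @param probs Named probability vector (`voicing`, `manner`, `place`).
#' @param scheme A [feature_scheme()].
#' @return A one-row tibble: `accuracy`, `voicing`, `manner`, `place`.
#' @export
listener_expected_rates <- function(probs, scheme = feature_scheme()) {
  probs <- probs[feature_names()]
  sets <- candidate_sets(scheme)
  cons <- scheme$consonant
  fval <- lapply(setNames(feature_names(), feature_names()), function(f) {
    setNames(scheme[[f]], cons)
  })
  acc <- 0
  trans <- setNames(rep(0, 3), feature_names())
  for (t in cons) {
    for (pat in 0:7) {
      bits <- c(voicing = bitwAnd(pat, 1L) > 0, manner = bitwAnd(pat, 2L) > 0,
                place = bitwAnd(pat, 4L) > 0)
      w <- prod(ifelse(bits, probs, 1 - probs))
      cand <- sets[[t]][[pat + 1L]]
      acc <- acc + w * mean(cand == t) / length(cons)
      for (f in feature_names()) {
        trans[f] <- trans[f] +
          w * mean(fval[[f]][cand] == fval[[f]][t]) / length(cons)
      }
    }
  }
  tibble(accuracy = acc, voicing = trans[["voicing"]],
         manner = trans[["manner"]], place = trans[["place"]])
}

#' Uniform transmission probability achieving a target accuracy
#'
#' Inverts the enumeration of [listener_expected_rates()] with all three
#' features at a common probability `q`, solving for the `q` whose expected
#' accuracy equals `accuracy`.
#'
#' @param accuracy Target expected proportion correct (must lie between
#'   chance, 1/12 + residual, and the model's ceiling).
#' @return The common transmission probability.
#' @export
calibrate_uniform_transmission <- function(accuracy) {
  rate_at <- function(q) {
    listener_expected_rates(setNames(rep(q, 3), feature_names()))$accuracy
  }
  lo <- rate_at(1e-6); hi <- rate_at(1 - 1e-6)
  if (accuracy <= lo || accuracy >= hi) {
    abort(sprintf("Accuracy %.3f outside the attainable range (%.3f, %.3f).",
                  accuracy, lo, hi))
  }
  stats::uniroot(function(q) rate_at(q) - accuracy, c(1e-6, 1 - 1e-6),
                 tol = 1e-9)$root
}

#' Cohort design
#'
#' Subjects per group, the condition set (by default the study-style 11
#' conditions: five masks in each of AO and AV, plus visual-only with no
#' mask), trials per block (12 consonants x 3 tokens = 36), runs per
#' condition, and the SNR assigned to each group.
#'
#' @param n_per_group Named subject counts.
#' @param conditions Tibble with `mask`, `modality` (default the 11).
#' @param trials_per_block Trials per run of one condition.
#' @param runs_per_condition Runs of each condition per subject.
#' @param snr_by_group Named SNR (dB) per group.
#' @return A `masksim_design` object.
#' @export
cohort_design <- function(n_per_group = c(CNH = 16, CHL = 18, ANH = 23),
                          conditions = NULL,
                          trials_per_block = 36, runs_per_condition = 2,
                          snr_by_group = c(CNH = 0, CHL = 0, ANH = 0)) {
  if (is.null(conditions)) {
    conditions <- bind_rows(
      tidyr::expand_grid(mask = mask_levels(), modality = c("AO", "AV")),
      tibble(mask = "none", modality = "VO")
    )
  }
  stopifnot(all(n_per_group > 0), trials_per_block > 0, runs_per_condition > 0,
            trials_per_block %% 12 == 0)
  structure(list(n_per_group = n_per_group, conditions = as_tibble(conditions),
                 trials_per_block = trials_per_block,
                 runs_per_condition = runs_per_condition,
                 snr_by_group = snr_by_group),
            class = "masksim_design")
}

group_age_profile <- function() {
  tibble(group = c("CNH", "CHL", "ANH"),
         age_mean = c(12.1, 12.7, 43), age_sd = c(3.5, 3, 4.3),
         age_min = c(7, 7, 30), age_max = c(20, 19, 55))
}

#' Simulate a full listener cohort
#'
#' Generates a complete trial table: per subject, a random intercept on
#' the logit scale, a randomized condition order, and for each run of each
#' condition a shuffled block of 12 consonants x 3 tokens scored through
#' the feature-channel listener.
#'
#' @param design A [cohort_design()].
#' @param params A [listener_params()].
#' @param seed Integer seed; the whole table is a pure function of
#'   (design, params, seed).
#' @return A trial tibble with columns `subject_id`, `group`, `age`,
#'   `modality`, `mask`, `snr_db`, `run`, `token`, `target`, `response`.
#' @export
simulate_cohort <- function(design = cohort_design(), params = listener_params(),
                            seed = 1) {
  stopifnot(inherits(design, "masksim_design"), inherits(params, "masksim_listener"))
  ages <- group_age_profile()
  n_tok <- design$trials_per_block / 12
  withr::with_seed(seed, {
    out <- purrr::map_dfr(names(design$n_per_group), function(g) {
      ga <- ages[ages$group == g, ]
      purrr::map_dfr(seq_len(design$n_per_group[[g]]), function(i) {
        sid <- sprintf("%s%02d", g, i)
        age <- round(pmin(pmax(rnorm(1, ga$age_mean, ga$age_sd),
                               ga$age_min), ga$age_max), 1)
        b <- rnorm(1, 0, params$subject_sd)
        cond <- design$conditions[sample.int(nrow(design$conditions)), ]
        purrr::map_dfr(seq_len(nrow(cond)), function(ci) {
          mk <- cond$mask[ci]; md <- cond$modality[ci]
          p <- feature_probs(params, mk, md, g, b)
          purrr::map_dfr(seq_len(design$runs_per_condition), function(r) {
            targets <- sample(rep(consonants(), n_tok))
            tokens <- as.integer(stats::ave(seq_along(targets), targets,
                                            FUN = seq_along))
            tibble(subject_id = sid, group = g, age = age,
                   modality = md, mask = mk,
                   snr_db = design$snr_by_group[[g]], run = r,
                   token = tokens, target = targets,
                   response = simulate_listener(targets, p))
          })
        })
      })
    })
    validate_trials(out)
  })
}

#' Simulate RAU score tables from the mixed model's generative form
#'
#' Draws per-subject-condition RAU scores directly from the linear
#' mixed-effects generative model:
#' `rau = mu + condition effect + group effect + subject intercept +
#' residual`, with Gaussian random intercepts and residuals. This is the
#' generator used to study estimator bias, interval coverage and type-I
#' error of the inference stage under known truth.
#'
#' @param n_per_group Named subject counts.
#' @param conditions Tibble with `mask`, `modality` (cells per subject).
#' @param effects Tibble with `mask`, `modality`, `effect_rau` (true fixed
#'   condition effects, 0 where missing).
#' @param group_effects Named true group offsets (RAU).
#' @param mu Grand intercept (RAU, default 70).
#' @param sd_subject,sd_resid Random-intercept and residual SDs (RAU).
#' @param seed Integer seed.
#' @return A score-table tibble: `subject_id`, `group`, `mask`,
#'   `modality`, `snr_db`, `rau`.
#' @export
simulate_rau_scores <- function(n_per_group = c(CNH = 20, CHL = 20, ANH = 20),
                                conditions = tibble(
                                  mask = rep(mask_levels(), 2),
                                  modality = rep(c("AO", "AV"), each = 5)),
                                effects = tibble(mask = character(),
                                                 modality = character(),
                                                 effect_rau = numeric()),
                                group_effects = c(CNH = 0, CHL = 0, ANH = 0),
                                mu = 70, sd_subject = 7, sd_resid = 7,
                                seed = 1) {
  conditions <- as_tibble(conditions)
  effects <- as_tibble(effects)
  withr::with_seed(seed, {
    purrr::map_dfr(names(n_per_group), function(g) {
      purrr::map_dfr(seq_len(n_per_group[[g]]), function(i) {
        b <- rnorm(1, 0, sd_subject)
        d <- conditions
        d$subject_id <- sprintf("%s%02d", g, i)
        d$group <- g
        d$snr_db <- 0
        eff <- rep(0, nrow(d))
        if (nrow(effects) > 0) {
          m <- match(paste(d$mask, d$modality),
                     paste(effects$mask, effects$modality))
          eff <- ifelse(is.na(m), 0, effects$effect_rau[m])
        }
        d$rau <- mu + eff + (group_effects[[g]] %||% 0) + b +
          rnorm(nrow(d), 0, sd_resid)
        d
      })
    })
  })
}
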