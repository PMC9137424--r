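#' The consonant set and its phonetic feature assignment
#'
#' The closed response set is 12 consonants presented in CV syllables with
#' the vowel /i/. The postalveolar fricative (IPA esh) is serialized as
#' `"sh"`. Each consonant carries one value per articulatory feature:
#' voicing (voiced/unvoiced), manner (stop/fricative/nasal) and place
#' (front/middle/back), with category sizes 6/6, 5/5/2 and 4/5/3.
#'
#' @return A tibble with columns `consonant`, `voicing`, `manner`, `place`.
#' @export
#' @examples
#' feature_scheme()
feature_scheme <- function() {
  tibble(
    consonant = c("b", "s", "d", "h", "k", "m", "n", "p", "sh", "t", "v", "z"),
    voicing = c("voiced", "unvoiced", "voiced", "unvoiced", "unvoiced", "voiced",
                "voiced", "unvoiced", "unvoiced", "unvoiced", "voiced", "voiced"),
    manner = c("stop", "fricative", "stop", "fricative", "stop", "nasal",
               "nasal", "stop", "fricative", "stop", "fricative", "fricative"),
    place = c("front", "middle", "middle", "back", "back", "front",
              "middle", "front", "back", "middle", "front", "middle")
  )
}

#' @rdname feature_scheme
#' @export
consonants <- function() feature_scheme()$consonant

feature_names <- function() c("voicing", "manner", "place")

mask_levels <- function() c("none", "hospital", "fabric", "communicator", "clearmask")
modality_levels <- function() c("AO", "AV", "VO")
group_levels <- function() c("CNH", "CHL", "ANH")

#' Validate a trial table
#'
#' A trial table holds one row per presentation with columns `subject_id`,
#' `group` (CNH/CHL/ANH), `modality` (AO/AV/VO), `mask` (none, hospital,
#' fabric, communicator, clearmask), `snr_db`, `run`, `token`, `target`,
#' `response`. Masks other than `none` are permitted in AO/AV only (the
#' study design's 11 conditions).
#'
#' @param trials A data frame of trials.
#' @return The validated tibble, or an error listing offending rows.
#' @export
validate_trials <- function(trials) {
  trials <- as_tibble(trials)
  need <- c("subject_id", "group", "modality", "mask", "target", "response")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trial table lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  cons <- consonants()
  problems <- character()
  bad <- function(col, ok) {
    rows <- which(!(trials[[col]] %in% ok))
    if (length(rows) > 0) {
      sprintf("invalid %s in row(s) %s", col,
              paste(head(rows, 5), collapse = ", "))
    } else character()
  }
  problems <- c(problems,
                bad("group", group_levels()),
                bad("modality", modality_levels()),
                bad("mask", mask_levels()),
                bad("target", cons),
                bad("response", cons))
  vo_mask <- which(trials$modality == "VO" & trials$mask != "none")
  if (length(vo_mask) > 0) {
    problems <- c(problems,
                  sprintf("visual-only trials with a mask other than 'none' in row(s) %s",
                          paste(head(vo_mask, 5), collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid trial table: ", paste(problems, collapse = "; "), "."))
  }
  trials
}

#' Tabulate confusion matrices
#'
#' Partitions trials by the grouping keys and builds a 12x12 consonant
#' confusion matrix (rows = target, columns = response) per cell.
#'
#' @param trials A validated trial table (see [validate_trials()]).
#' @param by Character vector of grouping columns (default none: one
#'   pooled matrix).
#' @return A tibble with the grouping columns plus a list-column `cm` of
#'   `masksim_confusion` matrices.
#' @export
tabulate_confusions <- function(trials, by = character()) {
  trials <- validate_trials(trials)
  cons <- consonants()
  make_cm <- function(d) {
    m <- table(factor(d$target, levels = cons), factor(d$response, levels = cons))
    structure(unclass(matrix(as.numeric(m), 12, 12, dimnames = list(cons, cons))),
              class = "masksim_confusion")
  }
  if (length(by) == 0) {
    return(tibble(cm = list(make_cm(trials))))
  }
  trials %>%
    group_by(across(all_of(by))) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(cm = purrr::map(.data$data, make_cm)) %>%
    select(-"data")
}

#' Accuracy and phonetic feature transmission from a confusion matrix
#'
#' Accuracy is the trace over the total count. Feature transmission is the
#' proportion of trials whose response shares the target's value on that
#' feature; a correct response transmits every feature, so each feature
#' transmission is at least the accuracy.
#'
#' @param cm A 12x12 confusion matrix (rows = target, columns = response)
#'   with consonant dimnames.
#' @param scheme A [feature_scheme()].
#' @return A one-row tibble: `n_trials`, `n_correct`, `accuracy`,
#'   `voicing`, `manner`, `place`.
#' @export
score_confusion <- function(cm, scheme = feature_scheme()) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == 12, ncol(cm) == 12, all(cm >= 0))
  total <- sum(cm)
  if (total == 0) abort("Confusion matrix is all zero; nothing to score.")
  ord <- match(scheme$consonant, rownames(cm))
  if (any(is.na(ord))) abort("Confusion matrix dimnames must be the 12 consonants.")
  cm <- cm[ord, ord]
  out <- tibble(n_trials = total, n_correct = sum(diag(cm)),
                accuracy = sum(diag(cm)) / total)
  for (f in feature_names()) {
    same <- outer(scheme[[f]], scheme[[f]], `==`)
    out[[f]] <- sum(cm[same]) / total
  }
  out
}

#' Rationalized arcsine transform of a proportion correct
#'
#' The rationalized arcsine unit (RAU) is the linearly rescaled two-term
#' arcsine transform: with X correct of N trials,
#' `theta = asin(sqrt(X/(N+1))) + asin(sqrt((X+1)/(N+1)))` and
#' `RAU = (146/pi) * theta - 23`. The transform stabilizes the variance of
#' proportions near the scale ends; 0 and 1 map to about -15.3 and 115.3
#' for N = 36, and `rau(X, N) + rau(N - X, N) = 100`.
#'
#' @param correct Number correct (vectorized).
#' @param total Number of trials.
#' @return RAU score(s).
#' @export
#' @examples
#' rau(18, 36)  # exactly 50
rau <- function(correct, total) {
  if (any(total <= 0) || any(correct < 0) || any(correct > total)) {
    abort("`correct` must lie in [0, total] with total > 0.")
  }
  theta <- asin(sqrt(correct / (total + 1))) + asin(sqrt((correct + 1) / (total + 1)))
  (146 / pi) * theta - 23
}

#' Chance levels for accuracy and feature transmission
#'
#' Expected scores for a uniform random responder under uniform targets:
#' accuracy 1/12, and per feature the sum over categories of
#' `(category size / 12)^2`.
#'
#' @param scheme A [feature_scheme()].
#' @return A one-row tibble: `accuracy`, `voicing`, `manner`, `place`.
#' @export
chance_levels <- function(scheme = feature_scheme()) {
  out <- tibble(accuracy = 1 / nrow(scheme))
  for (f in feature_names()) {
    sizes <- table(scheme[[f]])
    out[[f]] <- sum((sizes / nrow(scheme))^2)
  }
  out
}

#' Score a trial table per subject and condition
#'
#' Pools trials within each cell (summed counts across runs), then computes
#' proportion correct, its RAU transform, and per-feature transmission.
#'
#' @param trials A trial table.
#' @param by Grouping columns defining a cell (default subject x group x
#'   mask x modality x snr_db).
#' @param drop_incomplete Drop cells with fewer trials than
#'   `complete_n` (incomplete conditions; default `TRUE`).
#' @param complete_n Expected number of trials in a complete cell
#'   (default 36, i.e. one full block of 12 consonants x 3 tokens; use 72
#'   for two pooled runs).
#' @return A score table: one row per cell with `n_trials`, `n_correct`,
#'   `proportion`, `rau`, `voicing`, `manner`, `place`.
#' @export
score_trials <- function(trials,
                         by = c("subject_id", "group", "mask", "modality", "snr_db"),
                         drop_incomplete = TRUE, complete_n = 36) {
  trials <- validate_trials(trials)
  by <- intersect(by, names(trials))
  scheme <- feature_scheme()
  scored <- trials %>%
    group_by(across(all_of(by))) %>%
    summarise(
      n_trials = n(),
      n_correct = sum(.data$target == .data$response),
      voicing = feature_match_rate(.data$target, .data$response, scheme, "voicing"),
      manner = feature_match_rate(.data$target, .data$response, scheme, "manner"),
      place = feature_match_rate(.data$target, .data$response, scheme, "place"),
      .groups = "drop"
    ) %>%
    mutate(proportion = .data$n_correct / .data$n_trials,
           rau = rau(.data$n_correct, .data$n_trials)) %>%
    select(all_of(by), "n_trials", "n_correct", "proportion", "rau",
           "voicing", "manner", "place")
  if (drop_incomplete) scored <- scored[scored$n_trials >= complete_n, ]
  scored
}

feature_match_rate <- function(target, response, scheme, feature) {
  v <- setNames(scheme[[feature]], scheme$consonant)
  mean(v[target] == v[response])
}

#' Audiovisual benefit per subject and mask
#'
#' The difference between the audiovisual and auditory-only RAU scores in
#' matched cells (same subject, mask and SNR). Cells lacking either
#' modality are returned with `NA` benefit rather than silently dropped.
#'
#' @param scores A score table from [score_trials()] containing AO and AV
#'   rows.
#' @return A tibble with the matching keys, `rau_AO`, `rau_AV` and
#'   `benefit_rau = rau_AV - rau_AO`.
#' @export
audiovisual_benefit <- function(scores) {
  stopifnot(all(c("modality", "rau") %in% names(scores)))
  keys <- intersect(c("subject_id", "group", "mask", "snr_db"), names(scores))
  wide <- scores %>%
    filter(.data$modality %in% c("AO", "AV")) %>%
    select(all_of(keys), "modality", "rau") %>%
    tidyr::pivot_wider(names_from = "modality", values_from = "rau",
                       names_prefix = "rau_")
  if (!all(c("rau_AO", "rau_AV") %in% names(wide))) {
    abort("No matched AO/AV pairs: score table lacks one of the modalities.")
  }
  wide <- wide %>% mutate(benefit_rau = .data$rau_AV - .data$rau_AO)
  if (all(is.na(wide$benefit_rau))) {
    abort("No matched AO/AV pairs after alignment; check the grouping keys.")
  }
  wide
}
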