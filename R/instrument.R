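# ---- WHO-ASSIST 3.0 instrument model -------------------------------------
#
# Ten substance categories, per-substance items q2 (frequency of use in the
# past 3 months), q3-q5 (frequency of three harm domains) and q6-q7
# (concern expressed / failed attempts to cut down, each with a "prior to
# the past 3 months" level). Summed item weights give the substance-specific
# involvement (risk) score.

#' Substance categories of the WHO-ASSIST 3.0
#'
#' @return Character vector of the ten category codes, in instrument order.
#' @export
assist_substances <- function() {
  c("tobacco", "alcohol", "cannabis", "cocaine", "ats",
    "inhalants", "sedatives", "hallucinogens", "opioids", "other")
}

#' Illicit substance categories
#'
#' ATS, cannabis, cocaine, hallucinogens and opioids; the complement
#' (tobacco, alcohol, inhalants, sedatives, other) is treated as licit or
#' unclassified for prevalence reporting.
#'
#' @return Character vector of category codes.
#' @export
assist_illicit <- function() {
  c("ats", "cannabis", "cocaine", "hallucinogens", "opioids")
}

#' Canonical response levels for ASSIST items
#'
#' @param item One of `"q2"` to `"q7"`.
#' @return Character vector of legal ordinal levels, lowest first.
#' @export
assist_levels <- function(item) {
  item <- match.arg(item, c("q2", "q3", "q4", "q5", "q6", "q7"))
  if (item %in% c("q6", "q7")) {
    c("never", "yes_not_past_3mo", "yes_past_3mo")
  } else {
    c("never", "once_or_twice", "monthly", "weekly", "daily_or_almost_daily")
  }
}

#' Load an ASSIST item-weight table
#'
#' Reads the bundled WHO-ASSIST 3.0 weights (or a user-edited copy) from
#' YAML. The table maps each item's response level to its integer weight and
#' lists substances for which q5 is not administered.
#'
#' @param path YAML file; defaults to the bundled instrument weights.
#' @return A named list with elements `q2` ... `q7` (named integer vectors)
#'   and `q5_excluded_for` (character).
#' @export
assist_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "assist_weights.yaml", package = "assistnet")
  }
  w <- yaml::read_yaml(path)
  for (item in paste0("q", 2:7)) {
    if (is.null(w[[item]])) {
      stop("weight table is missing item '", item, "'")
    }
    w[[item]] <- unlist(w[[item]])
    lv <- assist_levels(item)
    if (!setequal(names(w[[item]]), lv)) {
      stop("weight table for '", item, "' must cover levels: ",
           paste(lv, collapse = ", "))
    }
    w[[item]] <- w[[item]][lv]
    if (any(w[[item]] < 0) || any(w[[item]] != round(w[[item]]))) {
      stop("weights for '", item, "' must be non-negative integers")
    }
  }
  if (is.null(w$q5_excluded_for)) w$q5_excluded_for <- character(0)
  w
}

#' Items contributing to a substance's involvement score
#'
#' @param substance Category code.
#' @param weights Weight table from [assist_weights()].
#' @return Character vector of item names (q5 dropped where not asked).
#' @export
assist_items <- function(substance, weights = assist_weights()) {
  items <- paste0("q", 2:7)
  if (substance %in% weights$q5_excluded_for) items <- setdiff(items, "q5")
  items
}

#' Maximum attainable involvement score
#'
#' @inheritParams assist_items
#' @return Integer upper bound of the summed item weights.
#' @export
assist_max_score <- function(substance, weights = assist_weights()) {
  sum(vapply(assist_items(substance, weights),
             function(it) max(weights[[it]]), numeric(1)))
}

item_weight <- function(level, item, weights, substance = "?", id = "?") {
  lv <- assist_levels(item)
  out <- rep(NA_real_, length(level))
  known <- is.na(level) | level %in% lv
  if (!all(known)) {
    bad <- which(!known)[1]
    stop(sprintf(
      "unknown response level '%s' (participant %s, substance %s, item %s)",
      level[bad], as.character(id)[min(bad, length(id))], substance, item))
  }
  idx <- match(level, lv)
  out[!is.na(idx)] <- weights[[item]][idx[!is.na(idx)]]
  out
}

#' Score substance-specific involvement
#'
#' Sums the configured WHO-ASSIST item weights over q2-q7 (q5 excluded where
#' not administered, e.g. tobacco). A missing item makes the whole score
#' missing: no partial sums are formed, mirroring conservative per-variable
#' missing-data accounting.
#'
#' @param resp Named list or one-row data frame with elements/columns
#'   `q2` ... `q7` holding canonical level strings (or `NA`). For cohort
#'   tables use [involvement_scores()].
#' @param substance Category code.
#' @param weights Weight table.
#' @return List with `substance`, `raw` (integer or `NA`) and `log_value`
#'   (`log(raw + 1)`).
#' @export
score_substance_involvement <- function(resp, substance,
                                        weights = assist_weights()) {
  items <- assist_items(substance, weights)
  vals <- vapply(items, function(it) {
    v <- resp[[it]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  w <- mapply(function(v, it) item_weight(v, it, weights, substance),
              vals, items)
  raw <- if (anyNA(w)) NA_real_ else sum(w)
  list(substance = substance, raw = raw, log_value = log(raw + 1))
}

#' Involvement scores for a whole cohort
#'
#' Vectorised scoring over a cohort table with columns
#' `<substance>_q2` ... `<substance>_q7`.
#'
#' @param cohort Cohort data frame (see [read_cohort()] or
#'   [generate_cohort()]).
#' @param weights Weight table.
#' @param substances Categories to score.
#' @return Data frame with columns `<substance>_score` (raw integer sum) and
#'   `<substance>_logscore` (`log(raw + 1)`), one row per participant.
#' @export
involvement_scores <- function(cohort, weights = assist_weights(),
                               substances = assist_substances()) {
  n <- nrow(cohort)
  ids <- if ("participant_id" %in% names(cohort)) cohort$participant_id else seq_len(n)
  out <- list()
  for (s in substances) {
    items <- assist_items(s, weights)
    total <- rep(0, n)
    miss <- rep(FALSE, n)
    for (it in items) {
      col <- paste0(s, "_", it)
      v <- if (col %in% names(cohort)) as.character(cohort[[col]]) else rep(NA_character_, n)
      lv <- assist_levels(it)
      bad <- !is.na(v) & !(v %in% lv)
      if (any(bad)) {
        b <- which(bad)[1]
        stop(sprintf(
          "unknown response level '%s' (participant %s, substance %s, item %s)",
          v[b], as.character(ids[b]), s, it))
      }
      w <- weights[[it]][match(v, lv)]
      miss <- miss | is.na(w)
      total <- total + ifelse(is.na(w), 0, w)
    }
    total[miss] <- NA_real_
    out[[paste0(s, "_score")]] <- total
    out[[paste0(s, "_logscore")]] <- log(total + 1)
  }
  as.data.frame(out)
}

#' Dichotomise ASSIST items into use and harm indicators
#'
#' Use in the past 3 months is `q2 != "never"`. Harm indicators are `TRUE`
#' when the harm occurred within the past 3 months: any non-"never" level
#' for q3-q5 (which are framed on the past 3 months) and only the
#' `"yes_past_3mo"` level for q6 and q7. Missing answers propagate as `NA`.
#' Any-substance aggregates are `TRUE` if the flag holds for at least one
#' substance, `FALSE` only when all contributing flags are observed `FALSE`.
#'
#' @param cohort Cohort data frame.
#' @param substances Categories to dichotomise.
#' @return Data frame of logical columns `<substance>_used`,
#'   `<substance>_urge` (q3), `<substance>_problems` (q4),
#'   `<substance>_failed_expect` (q5), `<substance>_concerns` (q6),
#'   `<substance>_cutdown_fail` (q7), plus aggregates `any_used`,
#'   `any_urge`, `any_problems`, `any_failed_expect`, `any_concerns`,
#'   `any_cutdown_fail`. The attribute `qc_harm_without_use` counts, per
#'   substance, harm flags raised with no recorded use (legal answers under
#'   the instrument's lifetime framing, surfaced for quality control).
#' @param weights Weight table (used to know which items a substance is
#'   administered; e.g. q5 is never asked for tobacco, so no
#'   `tobacco_failed_expect` flag is produced).
#' @export
dichotomize_items <- function(cohort, substances = assist_substances(),
                              weights = assist_weights()) {
  n <- nrow(cohort)
  harm_map <- c(urge = "q3", problems = "q4", failed_expect = "q5",
                concerns = "q6", cutdown_fail = "q7")
  get_col <- function(s, it) {
    col <- paste0(s, "_", it)
    if (col %in% names(cohort)) as.character(cohort[[col]]) else rep(NA_character_, n)
  }
  out <- list()
  qc <- integer(0)
  for (s in substances) {
    q2 <- get_col(s, "q2")
    used <- ifelse(is.na(q2), NA, q2 != "never")
    out[[paste0(s, "_used")]] <- used
    items_s <- assist_items(s, weights)
    for (h in names(harm_map)) {
      it <- harm_map[[h]]
      if (!(it %in% items_s)) next
      v <- get_col(s, it)
      flag <- if (it %in% c("q6", "q7")) {
        ifelse(is.na(v), NA, v == "yes_past_3mo")
      } else {
        ifelse(is.na(v), NA, v != "never")
      }
      out[[paste0(s, "_", h)]] <- flag
      qc[paste0(s, "_", h)] <-
        sum(flag & !is.na(flag) & !is.na(used) & !used)
    }
  }
  agg <- function(cols) {
    m <- do.call(cbind, out[intersect(cols, names(out))])
    any_true <- rowSums(m, na.rm = TRUE) > 0
    any_na <- rowSums(is.na(m)) > 0
    ifelse(any_true, TRUE, ifelse(any_na, NA, FALSE))
  }
  for (h in c("used", names(harm_map))) {
    out[[paste0("any_", h)]] <- agg(paste0(substances, "_", h))
  }
  res <- as.data.frame(out)
  attr(res, "qc_harm_without_use") <- qc
  res
}

#' Classify polysubstance use
#'
#' Counts distinct substances used in the past 3 months, including or
#' excluding tobacco and alcohol.
#'
#' @param indicators Output of [dichotomize_items()].
#' @param include_tobacco_alcohol Count tobacco and alcohol?
#' @param substances Categories counted (before the tobacco/alcohol
#'   restriction).
#' @return Factor with levels `none`, `one_only`, `polydrug`; `NA` when the
#'   observed flags cannot pin the category down (at least two observed
#'   uses always yields `polydrug` regardless of missing flags).
#' @export
classify_polysubstance <- function(indicators, include_tobacco_alcohol = TRUE,
                                   substances = assist_substances()) {
  counted <- if (include_tobacco_alcohol) substances else
    setdiff(substances, c("tobacco", "alcohol"))
  m <- as.matrix(indicators[, paste0(counted, "_used"), drop = FALSE])
  n_true <- rowSums(m, na.rm = TRUE)
  n_na <- rowSums(is.na(m))
  cat_ <- ifelse(n_true >= 2, "polydrug",
                 ifelse(n_na > 0, NA,
                        ifelse(n_true == 1, "one_only", "none")))
  factor(cat_, levels = c("none", "one_only", "polydrug"))
}

#' Assign the high-centrality substance-use group
#'
#' Four mutually exclusive groups anchored on the high-centrality
#' substances: `ats` (ATS use, possibly with anything else),
#' `cannabis_no_ats` (cannabis without ATS), `alcohol_tobacco_other` (any
#' other substance without cannabis or ATS) and `none` (no recent use).
#' Missing ATS or cannabis flags make the group missing unless a positive
#' flag higher in the hierarchy overrides them.
#'
#' @param indicators Output of [dichotomize_items()].
#' @param substances Categories considered.
#' @return Factor with levels `none`, `alcohol_tobacco_other`,
#'   `cannabis_no_ats`, `ats`.
#' @export
assign_group <- function(indicators, substances = assist_substances()) {
  ats <- indicators$ats_used
  can <- indicators$cannabis_used
  others <- setdiff(substances, c("ats", "cannabis"))
  m <- as.matrix(indicators[, paste0(others, "_used"), drop = FALSE])
  other_true <- rowSums(m, na.rm = TRUE) > 0
  other_na <- rowSums(is.na(m)) > 0
  grp <- rep(NA_character_, length(ats))
  grp[!is.na(ats) & ats] <- "ats"
  idx <- is.na(grp) & !is.na(ats) & !ats
  grp[idx & !is.na(can) & can] <- "cannabis_no_ats"
  idx2 <- idx & !is.na(can) & !can
  grp[idx2 & other_true] <- "alcohol_tobacco_other"
  grp[idx2 & !other_true & !other_na] <- "none"
  # cannabis missing but some other substance used cannot be resolved
  # (could be cannabis_no_ats or alcohol_tobacco_other) -> stays NA
  factor(grp, levels = c("none", "alcohol_tobacco_other",
                         "cannabis_no_ats", "ats"))
}
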