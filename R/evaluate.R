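#' Read a gold-standard annotation table
#'
#' @param path CSV with columns `patient_id`, `note_id`, `llt_code`,
#'   `drug_id`, `serious` (0/1); `llt_code`/`drug_id` may be empty for
#'   note-level gold.
#' @return A validated gold tibble.
#' @export
read_gold <- function(path) {
  gold_table(readr::read_csv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE))
}

#' Validate an in-memory gold table
#'
#' @param df Data frame with the gold schema (see [read_gold()]).
#' @return A validated gold tibble.
#' @export
gold_table <- function(df) {
  require_columns(df, c("patient_id", "note_id"), "gold table")
  out <- as_tibble(df)
  for (col in c("llt_code", "drug_id")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  if (!"serious" %in% names(out)) out$serious <- 0
  out <- out |>
    mutate(
      patient_id = as.character(.data$patient_id),
      note_id = as.character(.data$note_id),
      llt_code = dplyr::na_if(as.character(.data$llt_code), ""),
      drug_id = dplyr::na_if(as.character(.data$drug_id), ""),
      serious = parse_flag(.data$serious)
    )
  key <- paste(out$patient_id, out$note_id, out$llt_code, out$drug_id)
  if (anyDuplicated(key) > 0) {
    abort_schema(sprintf("gold table: duplicate annotation key(s): %s",
                         paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  out
}

#' Compare alerts against a gold standard
#'
#' Note level — an alert is a true positive if its `note_id` appears in the
#' gold standard, with each gold note counted once and false positives
#' counted as distinct non-gold alert notes (the evaluation unit is the EHR
#' note). Mention level — a match requires agreement on
#' `(note_id, llt_code, drug_id)`.
#'
#' @param alerts Alerts tibble.
#' @param gold Gold tibble from [gold_table()].
#' @param level `"note"` (default) or `"mention"`.
#' @return A one-row tibble with `tp`, `fp`, `fn`.
#' @export
match_to_gold <- function(alerts, gold, level = c("note", "mention")) {
  level <- match.arg(level)
  if (level == "note") {
    gold_notes <- unique(gold$note_id)
    alert_notes <- unique(alerts$note_id)
    tp <- sum(gold_notes %in% alert_notes)
    fp <- sum(!(alert_notes %in% gold_notes))
    fn <- sum(!(gold_notes %in% alert_notes))
  } else {
    gkey <- paste(gold$note_id, gold$llt_code, gold$drug_id)
    akey <- unique(paste(alerts$note_id, alerts$llt_code, alerts$drug_id))
    tp <- sum(gkey %in% akey)
    fp <- sum(!(akey %in% gkey))
    fn <- sum(!(gkey %in% akey))
  }
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Compute sensitivity, PPV, and F-measure from confusion counts
#'
#' Sensitivity = TP / (TP + FN); PPV = TP / (TP + FP); F-measure is the
#' harmonic mean of the two. A zero denominator yields 0 with a warning, so
#' batch evaluations never abort. Rounded display values (`*_pct` to the
#' nearest integer percent, F to two decimals) accompany the raw values.
#'
#' @param counts One-row tibble (or list) with `tp`, `fp`, `fn`.
#' @return A one-row tibble: counts, raw `sensitivity`, `ppv`, `f_measure`,
#'   plus `sensitivity_pct`, `ppv_pct`, `f_measure_2dp`.
#' @examples
#' compute_metrics(list(tp = 280, fp = 2495, fn = 46))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s denominator is zero; reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  ppv <- safe_div(tp, tp + fp, "PPV")
  f <- if (sens + ppv == 0) 0 else 2 * ppv * sens / (ppv + sens)
  tibble(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    sensitivity = sens, ppv = ppv, f_measure = f,
    sensitivity_pct = round(100 * sens), ppv_pct = round(100 * ppv),
    f_measure_2dp = round(f, 2)
  )
}

#' Metrics for a gold-standard stratum
#'
#' `stratum = "serious"` restricts the gold standard to potentially serious
#' ADRs and, for PPV, the alerts to serious-flagged ones. The serious
#' stratum's headline number is its sensitivity; the serious-stratum PPV is
#' an extension of the note-level report and is labeled as such.
#'
#' @param alerts Alerts tibble with a `serious` column.
#' @param gold Gold tibble with a `serious` column.
#' @param stratum `"all"` or `"serious"`.
#' @param level Evaluation level, see [match_to_gold()].
#' @return One-row metrics tibble (see [compute_metrics()]) with a
#'   `stratum` column.
#' @export
stratified_metrics <- function(alerts, gold, stratum = c("all", "serious"),
                               level = c("note", "mention")) {
  stratum <- match.arg(stratum)
  level <- match.arg(level)
  if (stratum == "serious") {
    gold <- filter(gold, .data$serious)
    if (nrow(gold) == 0) {
      warning("serious stratum is empty in the gold standard", call. = FALSE)
    }
    if (!"serious" %in% names(alerts)) alerts$serious <- FALSE
    alerts <- filter(alerts, .data$serious)
  }
  out <- compute_metrics(match_to_gold(alerts, gold, level))
  mutate(out, stratum = stratum, .before = 1)
}

#' Evaluate pipeline alerts against a gold standard
#'
#' Computes confusion counts and metrics for the full gold standard and the
#' potentially-serious stratum. Returns an `adr_eval` object with
#' [tidy()], [glance()], and [autoplot()] methods.
#'
#' @inheritParams stratified_metrics
#' @return An `adr_eval` object.
#' @export
evaluate_alerts <- function(alerts, gold, level = c("note", "mention")) {
  level <- match.arg(level)
  metrics <- bind_rows(
    stratified_metrics(alerts, gold, "all", level),
    if (any(gold$serious)) {
      stratified_metrics(alerts, gold, "serious", level)
    }
  )
  structure(
    list(metrics = metrics, level = level,
         n_alerts = nrow(alerts), n_gold = nrow(gold)),
    class = "adr_eval"
  )
}

#' @export
print.adr_eval <- function(x, ...) {
  cat(sprintf("<adr_eval> %s-level evaluation: %d alerts vs %d gold rows\n",
              x$level, x$n_alerts, x$n_gold))
  for (i in seq_len(nrow(x$metrics))) {
    m <- x$metrics[i, ]
    cat(sprintf(
      "  %-7s tp=%d fp=%d fn=%d  sensitivity %d%%  PPV %d%%  F %.2f\n",
      m$stratum, m$tp, m$fp, m$fn, m$sensitivity_pct, m$ppv_pct,
      m$f_measure_2dp
    ))
  }
  invisible(x)
}

#' @export
tidy.adr_eval <- function(x, ...) {
  mutate(x$metrics, level = x$level, .before = 1)
}

#' @export
glance.adr_eval <- function(x, ...) {
  all_row <- filter(x$metrics, .data$stratum == "all")
  serious <- filter(x$metrics, .data$stratum == "serious")
  tibble(
    level = x$level, n_alerts = x$n_alerts, n_gold = x$n_gold,
    sensitivity = all_row$sensitivity, ppv = all_row$ppv,
    f_measure = all_row$f_measure,
    serious_sensitivity = if (nrow(serious) > 0) serious$sensitivity else NA_real_
  )
}

#' @export
autoplot.adr_eval <- function(object, ...) {
  df <- object$metrics |>
    select(dplyr::all_of(c("stratum", "sensitivity", "ppv", "f_measure"))) |>
    tidyr::pivot_longer(-"stratum", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("ADR pipeline performance (%s level)", object$level)
    ) +
    ggplot2::theme_minimal()
}
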