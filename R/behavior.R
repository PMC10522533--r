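#' Signal-detection sensitivity (d-prime)
#'
#' d' = qnorm(H) - qnorm(F) from hit and false-alarm counts under the
#' equal-variance Gaussian model. Extreme rates (0 or 1) are adjusted by
#' the 1/(2N) rule: a rate of 0 becomes 1/(2N) and a rate of 1 becomes
#' 1 - 1/(2N), with N the number of trials behind that rate.
#'
#' @param hits,misses Counts on target-present trials.
#' @param fas,crs False alarms and correct rejections on target-absent
#'   trials.
#' @param correction `"loglinear"` is reserved for future use; the default
#'   `"half"` applies the 1/(2N) clamping rule.
#' @return d' (numeric scalar).
#' @export
dprime <- function(hits, misses, fas, crs, correction = c("half", "none")) {
  correction <- match.arg(correction)
  n_sig <- hits + misses
  n_noise <- fas + crs
  if (n_sig <= 0 || n_noise <= 0)
    stop("need at least one target-present and one target-absent trial")
  h <- hits / n_sig
  f <- fas / n_noise
  if (correction == "half") {
    h <- min(max(h, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig))
    f <- min(max(f, 1 / (2 * n_noise)), 1 - 1 / (2 * n_noise))
  } else if (h %in% c(0, 1) || f %in% c(0, 1)) {
    stop("extreme rate with correction = 'none': d' undefined")
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Score a detection-task behavioral table
#'
#' Tabulates hits/misses/false alarms/correct rejections from a table with
#' logical `target_present` and `response` ("yes"/"no") columns and returns
#' the d' per participant.
#'
#' @param table Behavioral `data.frame` (see [simulate_behavior()]).
#' @return Data frame with one row per participant: counts and `dprime`.
#' @export
score_detection <- function(table) {
  stopifnot(all(c("participant", "target_present", "response") %in%
                  names(table)))
  out <- lapply(split(table, table$participant), function(tb) {
    yes <- tb$response == "yes"
    data.frame(participant = tb$participant[1],
               hits = sum(tb$target_present & yes),
               misses = sum(tb$target_present & !yes),
               fas = sum(!tb$target_present & yes),
               crs = sum(!tb$target_present & !yes))
  })
  out <- do.call(rbind, out)
  out$dprime <- mapply(dprime, out$hits, out$misses, out$fas, out$crs)
  rownames(out) <- NULL
  out
}

#' Group-level test of sensitivity above chance
#'
#' One-sample one-tailed t-test of the participants' d' values against 0,
#' with Cohen's d = mean / SD. When several category tests form a family,
#' correct the returned p-values with [bh_fdr()] across the family.
#'
#' @param dprimes Numeric vector, one d' per participant.
#' @return A list with `t`, `df`, `p` (one-tailed, d' > 0), `cohen_d`,
#'   `mean` and `sd`.
#' @export
group_test <- function(dprimes) {
  if (length(dprimes) < 2) stop("need at least 2 participants")
  s <- stats::sd(dprimes)
  if (s == 0) {
    if (all(dprimes == 0))
      return(list(t = 0, df = length(dprimes) - 1L, p = 0.5, cohen_d = 0,
                  mean = 0, sd = 0))
    stop("zero variance with nonzero mean: t undefined")
  }
  tt <- stats::t.test(dprimes, mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohen_d = mean(dprimes) / s, mean = mean(dprimes), sd = s)
}

#' Confusion matrix for the five-alternative categorization task
#'
#' Row-normalized confusion matrix of true category x response category,
#' per-category accuracy, and the chance level (1 / number of
#' alternatives).
#'
#' @param table Data frame with `true_category` and `response` columns,
#'   both taking values in [emotion_categories()].
#' @param categories Category set (default the five emotions).
#' @return A list with `matrix` (row-normalized), `counts`, `accuracy`
#'   (named per-category vector) and `chance`.
#' @export
categorization_matrix <- function(table, categories = emotion_categories()) {
  stopifnot(all(c("true_category", "response") %in% names(table)))
  bad <- setdiff(unique(c(table$true_category, table$response)), categories)
  if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(table$true_category, categories),
                  factor(table$response, categories))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  mat <- counts / ifelse(rs == 0, 1, rs)
  list(matrix = mat, counts = counts,
       accuracy = diag(mat), chance = 1 / length(categories))
}

#' One-vs-rest d' per category for the isolation task
#'
#' Treats each category in turn as the signal: hits are correct
#' identifications of that category, false alarms are responses naming it
#' on stimuli of other categories.
#'
#' @param table Data frame with `participant`, `true_category`, `response`.
#' @param categories Category set (default the five emotions).
#' @return Data frame: `participant`, `category`, `dprime`.
#' @export
categorization_dprime <- function(table, categories = emotion_categories()) {
  stopifnot(all(c("participant", "true_category", "response") %in% names(table)))
  rows <- list()
  for (pid in unique(table$participant)) {
    tb <- table[table$participant == pid, ]
    for (cat in categories) {
      is_sig <- tb$true_category == cat
      said <- tb$response == cat
      if (!any(is_sig) || all(is_sig)) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, category = cat,
        dprime = dprime(sum(is_sig & said), sum(is_sig & !said),
                        sum(!is_sig & said), sum(!is_sig & !said)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Descriptive summary of valence/arousal ratings
#'
#' Means and SDs per category; inferential comparison of ratings is out of
#' the package's scope.
#'
#' @param table Data frame with `true_category` and a numeric `rating`
#'   column (1-5).
#' @param rating Column name to summarize (default `"valence"`).
#' @return Data frame: `category`, `mean`, `sd`, `n`.
#' @export
rating_summary <- function(table, rating = "valence") {
  stopifnot(rating %in% names(table))
  v <- table[[rating]]
  if (any(v < 1 | v > 5, na.rm = TRUE)) stop("ratings must lie in [1, 5]")
  out <- lapply(split(v, table$true_category), function(x)
    data.frame(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
               n = sum(!is.na(x))))
  cbind(data.frame(category = names(out), stringsAsFactors = FALSE),
        do.call(rbind, out), row.names = NULL)
}
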