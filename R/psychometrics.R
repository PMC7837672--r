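#' Principal components with varimax rotation
#'
#' PCA on the correlation matrix (items standardized internally), retaining
#' `n_components` components ordered by descending eigenvalue, followed by
#' Kaiser-normalized varimax rotation (deterministic identity
#' initialization, tolerance 1e-6).  Column signs are fixed so each
#' component's largest-magnitude loading is positive.  Rotation
#' redistributes, but preserves, the total explained variance of the
#' retained components.
#'
#' @param data Respondents x items numeric matrix or data frame.
#' @param n_components Components to retain (default 6).
#' @return A `pca_result` list: `loadings` (rotated, sign-fixed),
#'   `explained_per_component` (%), `total_explained` (%), `eigenvalues`
#'   (all), `n_components`.
#' @export
pca_varimax <- function(data, n_components = 6L) {
  X <- as.matrix(data)
  if (nrow(X) <= ncol(X))
    stop("need more respondents than items", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  q <- n_components
  raw <- p$rotation[, seq_len(q), drop = FALSE] %*% diag(p$sdev[seq_len(q)], q, q)
  rot <- if (q > 1) unclass(stats::varimax(raw, normalize = TRUE, eps = 1e-6)$loadings)
         else raw
  for (j in seq_len(q)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  ss <- colSums(rot^2)
  ord <- order(ss, decreasing = TRUE)
  rot <- rot[, ord, drop = FALSE]
  ss <- ss[ord]
  colnames(rot) <- paste0("RC", seq_len(q))
  structure(list(loadings = rot,
                 explained_per_component = 100 * ss / ncol(X),
                 total_explained = 100 * sum(ss) / ncol(X),
                 eigenvalues = p$sdev^2,
                 n_components = q),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$loadings), " items, ", x$n_components,
      " rotated components; explained ",
      paste(sprintf("%.1f", x$explained_per_component), collapse = " + "),
      " = ", sprintf("%.1f%%", x$total_explained), "\n", sep = "")
  invisible(x)
}

#' Match recovered components to a reference loading matrix
#'
#' Maps each recovered component to the reference component with the
#' largest absolute Tucker congruence, and counts items whose
#' dominant recovered component agrees with their dominant reference
#' component under that mapping.
#'
#' @param result A `pca_result` (or loading matrix).
#' @param reference Reference loading matrix with the same items.
#' @return List: `mapping` (recovered -> reference column), `congruence`
#'   (per recovered component), `n_matched` (items), `item_match` (logical).
#' @export
factor_congruence <- function(result, reference) {
  R <- if (inherits(result, "pca_result")) result$loadings else as.matrix(result)
  L <- as.matrix(reference)
  stopifnot(nrow(R) == nrow(L))
  cong <- crossprod(L, R) /
    outer(sqrt(colSums(L^2)), sqrt(colSums(R^2)))
  mapping <- apply(abs(cong), 2, which.max)
  dom_ref <- apply(abs(L), 1, which.max)
  dom_rec <- apply(abs(R), 1, which.max)
  item_match <- mapping[dom_rec] == dom_ref
  list(mapping = mapping,
       congruence = vapply(seq_along(mapping),
                           function(j) abs(cong[mapping[j], j]), numeric(1)),
       n_matched = sum(item_match), item_match = item_match)
}

cor_cell <- function(x, y) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Convergent-validity correlation table
#'
#' Pearson correlations (with two-sided p from the t transform, on
#' pairwise-complete observations) between factor scores and external
#' questionnaire scales, participant-aligned by row name/order.
#'
#' @param factor_scores Participants x factors data frame or matrix.
#' @param external_scales Participants x scales data frame or matrix, same
#'   row order.
#' @return Tibble: `scale, factor, r, p, n` (cells with n < 3 are `NA` with
#'   their pair count).
#' @export
validity_table <- function(factor_scores, external_scales) {
  fs <- as.data.frame(factor_scores)
  es <- as.data.frame(external_scales)
  if (nrow(fs) != nrow(es))
    stop("factor scores and scales must cover the same participants",
         call. = FALSE)
  out <- list()
  for (sc in names(es)) for (fa in names(fs)) {
    cell <- cor_cell(es[[sc]], fs[[fa]])
    out[[length(out) + 1L]] <- dplyr::mutate(cell, scale = sc, factor = fa,
                                             .before = 1)
  }
  dplyr::bind_rows(out)
}

# Person-level occasion summaries of the state items: baseline value,
# morning mean, evening mean, day-21 value per (participant, item).
occasion_summaries <- function(dataset, items) {
  sd <- dataset$sd[dataset$sd$item_index %in% items, ]
  agg <- function(slot_name) {
    sub <- sd[sd$slot == slot_name, ]
    out <- stats::aggregate(value ~ participant_id + item_index, sub, mean)
    names(out)[3] <- slot_name
    out
  }
  m <- Reduce(function(a, b) merge(a, b, by = c("participant_id", "item_index"),
                                   all = TRUE),
              lapply(intersect(c("baseline", "morning", "evening", "day21"),
                               unique(sd$slot)), agg))
  tibble::as_tibble(m)
}

#' Test-retest contrasts between occasions
#'
#' For each state item, morning and evening responses are first aggregated
#' to person-level means; then for each occasion pair the Pearson
#' correlation and the paired t statistic (listwise within each pair, so
#' `df = n - 1`) are computed, shaping the standard
#' baseline/morning/evening test-retest table.
#'
#' @param dataset A `study_dataset` (or any list with an `sd` tibble).
#' @param items Item indices (default the 10-item state set).
#' @param pairs List of 2-vectors of occasion names among `"baseline"`,
#'   `"morning"`, `"evening"`.
#' @return Tibble: `item_index, pair, r, t, df, p, n`.
#' @export
test_retest_contrasts <- function(dataset, items = sd_state_items(),
                                  pairs = list(c("baseline", "morning"),
                                               c("baseline", "evening"),
                                               c("morning", "evening"))) {
  summ <- occasion_summaries(dataset, items)
  out <- list()
  for (it in items) for (pr in pairs) {
    sub <- summ[summ$item_index == it, ]
    x <- sub[[pr[1]]]; y <- sub[[pr[2]]]
    if (is.null(x) || is.null(y)) next
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) stop("no overlapping participants for items/occasions",
                    call. = FALSE)
    r <- suppressWarnings(cor(x[ok], y[ok]))
    d <- x[ok] - y[ok]
    if (sd(d) == 0) {
      # degenerate pair: identical conditions give t = 0 by convention
      tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pval <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(x[ok], y[ok], paired = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      item_index = it, pair = paste(pr, collapse = "_vs_"),
      r = r, t = tval, df = n - 1, p = pval, n = n)
  }
  dplyr::bind_rows(out)
}

#' Mood-state correlation table
#'
#' Pearson correlations between person-level means of each state item and
#' each affect metric (valence, arousal, positive, negative), separately
#' for morning and evening slots — the layout of the published mood-state
#' table.
#'
#' @param dataset A `study_dataset` with `sd` and `pam` tibbles.
#' @param items Item indices (default the 10-item state set).
#' @return Tibble: `item_index, metric, slot, r, p, n`.
#' @export
mood_state_table <- function(dataset, items = sd_state_items()) {
  if (is.null(dataset$pam) || !nrow(dataset$pam))
    stop("dataset has no affect-meter stream", call. = FALSE)
  metrics <- c("valence", "arousal", "positive", "negative")
  out <- list()
  for (slot_name in c("morning", "evening")) {
    sd <- dataset$sd[dataset$sd$slot == slot_name &
                       dataset$sd$item_index %in% items, ]
    pam <- dataset$pam[dataset$pam$slot == slot_name, ]
    if (!nrow(pam) || !nrow(sd)) next
    pam_mean <- stats::aggregate(as.data.frame(pam[metrics]),
                                 as.data.frame(pam["participant_id"]), mean)
    for (it in items) {
      sub <- sd[sd$item_index == it, ]
      it_mean <- stats::aggregate(value ~ participant_id, sub, mean)
      joined <- merge(it_mean, pam_mean, by = "participant_id")
      for (mt in metrics) {
        cell <- cor_cell(joined$value, joined[[mt]])
        out[[length(out) + 1L]] <- dplyr::mutate(
          cell, item_index = it, metric = mt, slot = slot_name, .before = 1)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Baseline factor scores for every participant
#'
#' Scores the baseline (or day-21) trait form of each participant in a
#' study dataset into the six semantic-differential factors.
#'
#' @param dataset A `study_dataset`.
#' @param slot `"baseline"` or `"day21"`.
#' @return Tibble: participant_id plus one column per factor.
#' @export
study_factor_scores <- function(dataset, slot = "baseline") {
  sd <- dataset$sd[dataset$sd$slot == slot, ]
  parts <- split(sd, sd$participant_id)
  rows <- lapply(parts, function(g) {
    fs <- score_semantic_differential(
      tibble::tibble(item_index = g$item_index, value = g$value))
    tibble::tibble(participant_id = g$participant_id[1],
                   !!!stats::setNames(as.list(fs$score), fs$factor))
  })
  dplyr::bind_rows(rows)
}
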