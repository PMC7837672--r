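#' Semantic-differential item bank
#'
#' The 20 bipolar adjective pairs of the impulsivity semantic-differential
#' instrument, with each item's factor assignment and the sign of its
#' assigned loading in the published six-factor solution (see
#' [sd_loadings()]).  The 10-item momentary state subset is flagged in the
#' `state` column.
#'
#' @return Tibble: `index, left_anchor, right_anchor, factor, sign, state`.
#' @export
sd_items <- function() {
  tibble::as_tibble(utils::read.csv(path_extdata("sd_items.csv"),
                                    stringsAsFactors = FALSE))
}

#' Published six-factor loading matrix
#'
#' The rotated 20 x 6 principal-component loading matrix of the baseline
#' semantic-differential responses (factors: inefficient, negative, calm,
#' unhealthy, thrill, intentional), shipped as a versioned CSV fixture.
#'
#' @return Numeric 20 x 6 matrix with item indices as row names.
#' @export
sd_loadings <- function() {
  df <- utils::read.csv(path_extdata("sd_loadings.csv"))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$index
  m
}

#' Item indices of the 10-item momentary state form
#' @return Integer vector.
#' @export
sd_state_items <- function() c(4L, 5L, 7L, 8L, 11L, 12L, 15L, 17L, 19L, 20L)

#' Factor names of the six-factor solution
#' @return Character vector.
#' @export
sd_factor_names <- function()
  c("inefficient", "negative", "calm", "unhealthy", "thrill", "intentional")

#' Score semantic-differential responses into factor scores
#'
#' Each response is midpoint-centered and half-range normalized to
#' `[-1, 1]` (so the result does not depend on whether a 0-100 slider or a
#' 1-7 scale encoded the same positions), multiplied by the item's assigned
#' loading sign, and averaged within factors (unit-weighted signed means;
#' set `weighted = TRUE` for loading-magnitude weights).  A positive score
#' means the respondent leans toward the pole that loads positively on that
#' factor.
#'
#' @param responses Tibble with columns `item_index`, `value`.  Duplicate
#'   items are rejected; values outside `scale` are an error.
#' @param items Item bank, defaults to [sd_items()].
#' @param scale Numeric `c(lo, hi)` response bounds (default 0-100 slider,
#'   left anchor at `lo`).
#' @param form `"trait"` (all 20 items) or `"state"` (the 10-item subset).
#' @param weighted Weight items by the magnitude of their assigned loading.
#' @return Tibble: `factor, score, n_items, completeness` (fraction of the
#'   factor's items answered; factors with no items get `NA` score).
#' @export
score_semantic_differential <- function(responses, items = sd_items(),
                                        scale = c(0, 100),
                                        form = c("trait", "state"),
                                        weighted = FALSE) {
  form <- match.arg(form)
  stopifnot(all(c("item_index", "value") %in% names(responses)))
  if (anyDuplicated(responses$item_index))
    stop("duplicate item_index in responses", call. = FALSE)
  if (any(responses$value < scale[1] | responses$value > scale[2]))
    stop("response value outside the scale bounds", call. = FALSE)
  if (form == "state") items <- items[items$state, ]
  mid <- mean(scale); half <- diff(scale) / 2
  df <- merge(items, responses, by.x = "index", by.y = "item_index")
  df$z <- df$sign * (df$value - mid) / half
  w <- if (weighted) {
    L <- sd_loadings()
    abs(L[cbind(match(df$index, as.integer(rownames(L))),
                match(df$factor, sd_factor_names()))])
  } else rep(1, nrow(df))
  df$w <- w
  out <- lapply(sd_factor_names(), function(f) {
    it_all <- items[items$factor == f, ]
    sub <- df[df$factor == f, ]
    tibble::tibble(
      factor = f,
      score = if (nrow(sub)) sum(sub$w * sub$z) / sum(sub$w) else NA_real_,
      n_items = nrow(sub),
      completeness = if (nrow(it_all)) nrow(sub) / nrow(it_all) else NA_real_)
  })
  dplyr::bind_rows(out)
}

#' Explained variance implied by a loading matrix
#'
#' For component loadings on standardized items, each component's explained
#' variance is its column sum of squared loadings over the number of items.
#'
#' @param loadings Items x components numeric matrix (|loading| <= 1).
#' @return List: `per_factor` (named percentages) and `total`.
#' @examples
#' ev <- explained_variance_from_loadings(sd_loadings())
#' round(ev$per_factor)   # 20 18 13  9  7  7
#' round(ev$total)        # 74
#' @export
explained_variance_from_loadings <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (any(abs(loadings) > 1 + 1e-8))
    stop("|loading| must not exceed 1", call. = FALSE)
  per <- 100 * colSums(loadings^2) / nrow(loadings)
  list(per_factor = per, total = sum(per))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`.
#'
#' @param item_matrix Respondents x items numeric matrix (>= 2 of each).
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 2)
    stop("need at least 2 items and 2 respondents", call. = FALSE)
  total_var <- var(rowSums(m))
  if (total_var <= 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Score a photographic affect meter selection
#'
#' The affect meter shows a 4 x 4 photo grid indexed row-major from the top
#' left; the column encodes valence (left to right = 1..4) and the row
#' encodes arousal (bottom to top = 1..4).  Positive and negative affect
#' use a linear circumplex map — a documented, configurable stand-in for
#' the instrument's validated photo-to-affect calibration, which is not in
#' the public record:
#' `positive = ((valence-1) + (arousal-1)) / 6`,
#' `negative = ((4-valence) + (arousal-1)) / 6`.
#'
#' @param pam_index Integer 1..16 (vectorized).
#' @param positive_map,negative_map Optional functions
#'   `(valence, arousal) -> score` replacing the defaults.
#' @return Tibble: `pam_index, valence, arousal, positive, negative`.
#' @examples
#' pam_score(13)  # bottom-left: valence 1, arousal 1
#' pam_score(4)   # top-right:   valence 4, arousal 4
#' @export
pam_score <- function(pam_index, positive_map = NULL, negative_map = NULL) {
  pam_index <- as.integer(pam_index)
  if (any(pam_index < 1 | pam_index > 16))
    stop("pam_index must lie in 1..16", call. = FALSE)
  row <- (pam_index - 1L) %/% 4L + 1L        # 1 = top row
  valence <- (pam_index - 1L) %% 4L + 1L
  arousal <- 5L - row                        # bottom row -> arousal 1
  pos <- if (is.null(positive_map)) ((valence - 1) + (arousal - 1)) / 6
         else positive_map(valence, arousal)
  neg <- if (is.null(negative_map)) ((4 - valence) + (arousal - 1)) / 6
         else negative_map(valence, arousal)
  tibble::tibble(pam_index = pam_index, valence = valence, arousal = arousal,
                 positive = pos, negative = neg)
}
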