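#' Per-rat strategy profiles from fuzzy cluster models
#'
#' Each session is hard-assigned to its maximum-membership cluster (ties to
#' the lowest index); per rat and feature, the profile is the vector of
#' session-in-cluster probabilities (sessions in cluster / total sessions for
#' that rat). Profiles across features are concatenated in the fixed order of
#' `models`; a rat with no sessions in a feature's point set has that feature
#' omitted (recorded in `features_present`), never zero-filled.
#'
#' @param models Named list of `fcm_fit` models, one per feature.
#' @param keys Named list (same names) of tibbles with one row per session in
#'   the order the model saw them: columns `rat_id` (and anything else).
#' @param assignments Optional named list of hard assignments overriding each
#'   model's own (used for projecting condition data onto baseline clusters).
#' @param soft Use mean memberships instead of hard-assignment counts.
#' @return A tibble: `rat_id`, `feature`, `cluster`, `probability`,
#'   `n_sessions`; plus attribute `profile_order` (feature, cluster order of
#'   the concatenated vector).
#' @export
strategy_profiles <- function(models, keys, assignments = NULL, soft = FALSE) {
  stopifnot(is.list(models), identical(names(models), names(keys)))
  rows <- purrr::imap(models, function(model, feat) {
    key <- keys[[feat]]
    stopifnot(nrow(key) == nrow(model$membership) ||
                !is.null(assignments[[feat]]))
    if (soft) {
      U <- model$membership
      df <- tibble::as_tibble(as.data.frame(U))
      names(df) <- as.character(seq_len(ncol(U)))
      dplyr::bind_cols(key["rat_id"], df) |>
        tidyr::pivot_longer(-"rat_id", names_to = "cluster",
                            values_to = "w") |>
        dplyr::group_by(.data$rat_id, cluster = as.integer(.data$cluster)) |>
        dplyr::summarise(w = sum(.data$w), .groups = "drop_last") |>
        dplyr::mutate(probability = .data$w / sum(.data$w),
                      n_sessions = sum(.data$w), feature = feat) |>
        dplyr::ungroup() |>
        dplyr::select("rat_id", "feature", "cluster", "probability",
                      "n_sessions")
    } else {
      cl <- assignments[[feat]] %||% model$cluster
      stopifnot(length(cl) == nrow(key))
      tibble::tibble(rat_id = key$rat_id, cluster = cl) |>
        dplyr::count(.data$rat_id, .data$cluster) |>
        tidyr::complete(rat_id = unique(key$rat_id),
                        cluster = seq_len(model$c), fill = list(n = 0L)) |>
        dplyr::group_by(.data$rat_id) |>
        dplyr::mutate(probability = .data$n / sum(.data$n),
                      n_sessions = sum(.data$n), feature = feat) |>
        dplyr::ungroup() |>
        dplyr::select("rat_id", "feature", "cluster", "probability",
                      "n_sessions")
    }
  })
  out <- dplyr::bind_rows(rows)
  order_tbl <- out |>
    dplyr::distinct(.data$feature, .data$cluster) |>
    dplyr::arrange(match(.data$feature, names(models)), .data$cluster)
  structure(out, profile_order = order_tbl,
            class = c("strategy_profiles", class(out)))
}

profile_vector <- function(profiles, rat, order_tbl = NULL) {
  order_tbl <- order_tbl %||% attr(profiles, "profile_order")
  df <- dplyr::filter(profiles, .data$rat_id == rat)
  merged <- dplyr::left_join(order_tbl, df, by = c("feature", "cluster"))
  # features absent for this rat are omitted, not zero-filled
  keep <- merged |>
    dplyr::group_by(.data$feature) |>
    dplyr::filter(!all(is.na(.data$probability))) |>
    dplyr::ungroup()
  setNames(keep$probability, paste0(keep$feature, ".", keep$cluster))
}

#' Euclidean distance between two strategy profiles
#'
#' The l2 norm of the difference of the concatenated cluster-probability
#' vectors. Only features present in both profiles (identical cluster
#' alignment) are compared; a mismatch in alignment is an error.
#'
#' @param profile_a,profile_b Named numeric vectors ([profile_vector()]
#'   output) or `strategy_profiles` tibbles for a single rat.
#' @return Non-negative distance.
#' @export
euclidean_shift <- function(profile_a, profile_b) {
  a <- if (is.numeric(profile_a)) profile_a else
    profile_vector(profile_a, unique(profile_a$rat_id))
  b <- if (is.numeric(profile_b)) profile_b else
    profile_vector(profile_b, unique(profile_b$rat_id))
  common <- intersect(names(a), names(b))
  if (!length(common)) stopf("profiles share no feature/cluster components")
  if (!setequal(names(a), names(b))) {
    feats_a <- unique(sub("\\..*$", "", names(a)))
    feats_b <- unique(sub("\\..*$", "", names(b)))
    both <- intersect(feats_a, feats_b)
    common <- common[sub("\\..*$", "", common) %in% both]
  }
  sqrt(sum((a[common] - b[common])^2))
}

#' Population-level strategy-shift test (two-sample KS)
#'
#' Compares the distributions of per-rat profile shift distances between two
#' conditions with the exact two-sample Kolmogorov-Smirnov statistic. The
#' p-value uses the exact distribution (via [stats::psmirnov()]) for small
#' tie-free samples and the asymptotic Kolmogorov series otherwise.
#'
#' @param distances_a,distances_b Numeric vectors of per-rat distances.
#' @param exact `NULL` (auto: exact when `n*m <= 10000` and no ties), or
#'   logical.
#' @return A tibble: `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
population_shift_test <- function(distances_a, distances_b, exact = NULL) {
  x <- sort(distances_a[is.finite(distances_a)])
  y <- sort(distances_b[is.finite(distances_b)])
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stopf("both samples must be non-empty")
  # exact ECDF max-difference statistic
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(all_v, function(v) mean(y <= v), numeric(1))
  D <- max(abs(Fx - Fy))
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (as.double(n) * m <= 10000) && !ties
  if (exact) {
    p <- 1 - psmirnov(D, sizes = c(n, m), two.sided = TRUE)
    method <- "exact"
  } else {
    ne <- n * m / (n + m)
    lambda <- sqrt(ne) * D
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
    method <- "asymptotic"
  }
  tibble::tibble(statistic = D, p_value = p, n_a = n, n_b = m,
                 method = method)
}

#' Per-cluster session-count migration tests (chi-squared)
#'
#' For each cluster k, a 2x2 chi-squared test (no Yates correction by
#' default) of (in cluster k vs not) x (condition A vs condition B) on raw
#' session counts; raw and multiplicity-adjusted p-values are reported.
#'
#' @param counts_a,counts_b Integer vectors of sessions per cluster (same
#'   length and cluster order).
#' @param correct Yates continuity correction (default `FALSE`).
#' @param p_adjust_method Passed to [stats::p.adjust()] (default "holm").
#' @return A tibble: `cluster`, `a_in`, `a_out`, `b_in`, `b_out`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
cluster_migration_test <- function(counts_a, counts_b, correct = FALSE,
                                   p_adjust_method = "holm") {
  stopifnot(length(counts_a) == length(counts_b))
  if (any(counts_a < 0 | counts_b < 0) ||
      any(counts_a != round(counts_a)) || any(counts_b != round(counts_b))) {
    stopf("counts must be non-negative integers (raw session counts)")
  }
  tot_a <- sum(counts_a); tot_b <- sum(counts_b)
  res <- purrr::map(seq_along(counts_a), function(k) {
    tab <- rbind(c(counts_a[k], tot_a - counts_a[k]),
                 c(counts_b[k], tot_b - counts_b[k]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(tibble::tibble(cluster = k, a_in = counts_a[k],
                            a_out = tot_a - counts_a[k], b_in = counts_b[k],
                            b_out = tot_b - counts_b[k],
                            statistic = 0, p_value = 1))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    tibble::tibble(cluster = k, a_in = counts_a[k],
                   a_out = tot_a - counts_a[k], b_in = counts_b[k],
                   b_out = tot_b - counts_b[k],
                   statistic = unname(ct$statistic),
                   p_value = unname(ct$p.value))
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- p.adjust(out$p_value, method = p_adjust_method)
  out
}

#' Per-cluster mean psychometric curves
#'
#' Averages the member sessions' psychometric curves within each
#' hard-assigned cluster, pointwise over the shared x levels, with the
#' standard error of the mean.
#'
#' @param model An `fcm_fit` (or any hard assignment vector).
#' @param curves List of `psych_curve` tibbles, one per clustered session, in
#'   model row order.
#' @return A tibble: `cluster`, `x`, `y_mean`, `y_sem`, `n_sessions`.
#' @export
cluster_mean_curves <- function(model, curves) {
  cl <- if (inherits(model, "fcm_fit")) model$cluster else model
  stopifnot(length(cl) == length(curves))
  df <- purrr::imap(curves, function(cv, i) {
    tibble::tibble(cluster = cl[[i]], x = cv$x, y = cv$y)
  }) |> dplyr::bind_rows()
  df |>
    dplyr::group_by(.data$cluster, .data$x) |>
    dplyr::summarise(
      y_mean = mean(.data$y),
      y_sem = if (dplyr::n() > 1) sd(.data$y) / sqrt(dplyr::n()) else 0,
      n_sessions = dplyr::n(), .groups = "drop"
    )
}
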